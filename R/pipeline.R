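# djb2-style hash of a serialized R object, as provenance fingerprint
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Collects every parameter of an end-to-end run: cohort size, protocol
#' counts, the planted effect, preprocessing parameters, searchlight
#' windows, RSA and bootstrap parameters, and the master seed.  Defaults
#' describe a desk-scale synthetic study: 5 subjects, 33 conditions,
#' with the object-shape categorical model planted in a centro-parietal
#' channel neighborhood in the lower beta band.
#'
#' @param n_subjects cohort size (default 5; the full-study value is 31).
#' @param n_conditions,n_repetitions protocol counts (defaults 33 and 8).
#' @param seed master seed; every random stage derives its seed from it.
#' @param effect_channel_nb,effect_freq_nb planted searchlight cell
#'   (defaults: the neighborhood with centroid CP3, and the 14-16 Hz
#'   band).
#' @param effect_model scheme of the planted model RDM
#'   (`"object_shape"`, `"grasp_type"`, `"thumb_position"` or `"none"`).
#' @param effect_size,noise_sd planted effect magnitude and background
#'   noise amplitude.
#' @param windows number of consecutive 500-ms analysis windows from
#'   movement onset (default 3).
#' @param baseline_window fixation interval (s, trial-relative) defining
#'   the ERD/S baseline (default 1-3 s).
#' @param reject_rules rejection thresholds, see [reject_trials()].
#' @param n_boot,alpha bootstrap iterations and CI level.
#' @param region optional explicit region of interest: 2-column matrix of
#'   (channel neighborhood, frequency neighborhood) indices; default the
#'   planted cell and its overlapping neighbors.
#' @param candidates candidate representations to map.
#' @param onset_jitter_sd accelerometer onset jitter (s).
#' @param kin_noise_sd angular noise SD (radians).
#' @return a `grasp_config` list with a provenance hash.
#' @export
grasp_config <- function(n_subjects = 5, n_conditions = 33,
                         n_repetitions = 8, seed = 1,
                         effect_channel_nb = NULL, effect_freq_nb = 10,
                         effect_model = "object_shape", effect_size = 1,
                         noise_sd = 0.5, windows = 3,
                         baseline_window = c(1, 3),
                         reject_rules = list(obs_accel_sd = 5,
                                             joint_jump_rad = pi / 3),
                         n_boot = 500, alpha = 0.05, region = NULL,
                         candidates = c("emg", "kinematics", "grasp_type",
                                        "thumb_position", "object_shape"),
                         onset_jitter_sd = 0.05, kin_noise_sd = 0.02) {
  cfg <- list(n_subjects = n_subjects, n_conditions = n_conditions,
              n_repetitions = n_repetitions, seed = seed,
              effect_channel_nb = effect_channel_nb,
              effect_freq_nb = effect_freq_nb,
              effect_model = effect_model, effect_size = effect_size,
              noise_sd = noise_sd, windows = windows,
              baseline_window = baseline_window,
              reject_rules = reject_rules, n_boot = n_boot, alpha = alpha,
              region = region, candidates = candidates,
              onset_jitter_sd = onset_jitter_sd,
              kin_noise_sd = kin_noise_sd)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "grasp_config"
  cfg
}

# searchlight cells overlapping (sharing channels and frequency bins with)
# a given cell, as a logical matrix over the grid
overlapping_cells <- function(layout, channel_nb, freq_nb) {
  cnb <- layout$channel_neighborhoods
  fnb <- layout$frequency_neighborhoods
  ch_ov <- vapply(cnb, function(x)
    length(intersect(x, cnb[[channel_nb]])) > 0, logical(1))
  fq_ov <- vapply(fnb, function(x)
    length(intersect(x, fnb[[freq_nb]])) > 0, logical(1))
  outer(ch_ov, fq_ov, `&`)
}

# per-subject feature extraction: ERD/S array, EMG envelopes, kinematic
# synergy scores, all aligned to the detected movement onset
subject_features <- function(kept, layout, baseline_window, n_windows,
                             n_conditions) {
  fs_eeg <- kept$fs$eeg
  fs_emg <- kept$fs$emg
  exec_cue <- phase_times(kept$protocol)[3]
  freqs <- layout$freqs
  n_ch <- length(layout$channels)
  n_fq <- length(freqs)
  exec_len <- round(n_windows * 0.5 * fs_eeg)
  exec_len_emg <- round(n_windows * 0.5 * fs_emg)
  base_idx <- (round(baseline_window[1] * fs_eeg) + 1):
    round(baseline_window[2] * fs_eeg)

  p_base <- matrix(0, n_ch, n_fq)
  p_move <- array(0, c(n_ch, n_fq, exec_len, n_conditions))
  n_trials_used <- 0L
  counts <- integer(n_conditions)
  emg_sum <- vector("list", n_conditions)
  kin_reps <- vector("list", n_conditions)
  kin_concat <- list()

  for (e in kept$epochs) {
    es <- round((exec_cue + e$onset_s) * fs_eeg)
    keep_idx <- c(base_idx, es + seq_len(exec_len))
    pw <- morlet_tfr(e$eeg, fs_eeg, freqs, keep = keep_idx)
    nb <- length(base_idx)
    p_base <- p_base + rowMeans(pw[, , seq_len(nb), drop = FALSE], dims = 2)
    n_trials_used <- n_trials_used + 1L
    cond <- e$condition
    counts[cond] <- counts[cond] + 1L
    p_move[, , , cond] <- p_move[, , , cond] +
      pw[, , nb + seq_len(exec_len), drop = FALSE]

    env <- emg_envelope(e$emg)
    esm <- round((exec_cue + e$onset_s) * fs_emg)
    env_w <- env[, esm + seq_len(exec_len_emg), drop = FALSE]
    emg_sum[[cond]] <- if (is.null(emg_sum[[cond]])) env_w
    else emg_sum[[cond]] + env_w

    jw <- e$joints[, es + seq_len(exec_len), drop = FALSE]
    kin_reps[[cond]] <- c(kin_reps[[cond]], list(jw))
    kin_concat[[length(kin_concat) + 1]] <- jw
  }
  if (n_trials_used == 0) stopf("no usable trials for this subject")
  p_base <- p_base / n_trials_used

  erds <- array(NA_real_, c(n_ch, n_fq, exec_len, n_conditions),
                dimnames = list(layout$channels, NULL, NULL, NULL))
  for (cond in which(counts > 0)) {
    pm <- p_move[, , , cond] / counts[cond]
    erds[, , , cond] <- (pm - c(p_base)) / c(p_base) * 100
  }
  emg_env <- lapply(seq_len(n_conditions), function(cond)
    if (counts[cond] > 0) emg_sum[[cond]] / counts[cond] else NULL)

  pca <- kinematic_pca(do.call(cbind, kin_concat), n_components = 5)
  kin_scores <- lapply(seq_len(n_conditions), function(cond) {
    if (counts[cond] == 0) return(NULL)
    avg <- circular_mean_arrays(kin_reps[[cond]])
    t(pca$components) %*% (avg - pca$center)
  })
  list(erds = erds, baseline = p_base, emg = emg_env,
       kin_scores = kin_scores, pca = pca, counts = counts)
}

# greedy alignment of one subject's kinematic components to a reference
# basis: maximal-absolute-correlation matching with sign flipping
align_components <- function(ref, comps) {
  k <- ncol(ref)
  cc <- stats::cor(ref, comps)
  perm <- integer(k); sgn <- numeric(k)
  avail <- rep(TRUE, k)
  for (i in order(-apply(abs(cc), 1, max))) {
    j <- which.max(abs(cc[i, ]) * avail)
    perm[i] <- j; sgn[i] <- sign(cc[i, j]); avail[j] <- FALSE
  }
  sgn[sgn == 0] <- 1
  list(perm = perm, sign = sgn)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthesis-to-RSA pipeline
#'
#' Executes generation, preprocessing, searchlight feature extraction,
#' first-level RSA, bootstrap and second-level RSA for a synthetic cohort
#' described by a [grasp_config()].  Re-running with an identical config
#' reproduces all outputs bitwise.
#'
#' @param config a `grasp_config`.
#' @param layout optional pre-built [searchlight_layout()]; validated
#'   before any generation.
#' @param taxonomy optional taxonomy; default the shipped table, truncated
#'   to `n_conditions`.
#' @param verbose print per-stage progress.
#' @return object of class `grasp_rsa_result` (the result bundle):
#'   reference RDMs per window and cell, candidate RDMs, RSA maps,
#'   bootstrap results, second-level RDMs, QC report, ground truth and
#'   provenance.
#' @export
run_pipeline <- function(config = grasp_config(), layout = NULL,
                         taxonomy = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  layout <- run_stage("layout", {
    l <- layout %||% searchlight_layout()
    validate_layout(l)
    l
  })
  taxonomy <- run_stage("taxonomy", {
    tx <- taxonomy %||% default_taxonomy()
    tx <- tx[tx$condition <= config$n_conditions, , drop = FALSE]
    validate_taxonomy(tx, config$n_conditions)
    tx
  })
  model <- if (identical(config$effect_model, "none")) NULL
  else categorical_rdm(taxonomy, config$effect_model)
  ch_nb <- config$effect_channel_nb %||%
    which(names(layout$channel_neighborhoods) == "CP3")[1]
  eff <- effect_spec(ch_nb, config$effect_freq_nb, model = model,
                     effect_size = config$effect_size,
                     noise_sd = config$noise_sd)

  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max %/% 2,
                                config$n_subjects + 1))
  shared <- with_seed(seeds[config$n_subjects + 1], list(
    emg_weights = matrix(abs(rnorm(8 * 3)), 8, 3),
    emg_activations = matrix(abs(rnorm(config$n_conditions * 3)),
                             config$n_conditions, 3),
    kin_basis = qr.Q(qr(matrix(rnorm(19 * 5), 19, 5))) * 0.4,
    kin_scores = matrix(rnorm(config$n_conditions * 5),
                        config$n_conditions, 5)))

  n_w <- config$windows
  region <- config$region %||% as.matrix(expand.grid(
    channel_nb = intersect(eff$channel_nb + (-1:1),
                           seq_along(layout$channel_neighborhoods)),
    freq_nb = intersect(eff$freq_nb + (-1:1),
                        seq_along(layout$frequency_neighborhoods))))
  region <- as.matrix(region)

  erds_sum <- NULL
  erds_n <- NULL
  emg_group <- vector("list", config$n_conditions)
  kin_group <- vector("list", config$n_conditions)
  kin_ref <- NULL
  reports <- list()
  win_idx_eeg <- lapply(seq_len(n_w), function(w) (w - 1) * 50 + 1:50)
  win_idx_emg <- lapply(seq_len(n_w), function(w) (w - 1) * 100 + 1:100)
  region_cells <- apply(region, 1, function(r) cell_name(r[1], r[2]))
  region_patterns <- lapply(seq_len(n_w), function(w) {
    p <- vector("list", nrow(region)); names(p) <- region_cells; p
  })

  for (s in seq_len(config$n_subjects)) {
    say("subject %d/%d", s, config$n_subjects)
    subj <- run_stage(sprintf("subject %d", s), {
      protocol <- generate_protocol(config$n_conditions,
                                    config$n_repetitions, seed = seeds[s])
      rec <- synthesize_session(protocol, layout, eff, taxonomy = taxonomy,
                                emg_weights = shared$emg_weights,
                                emg_activations = shared$emg_activations,
                                kin_basis = shared$kin_basis,
                                kin_scores = shared$kin_scores,
                                onset_jitter_sd = config$onset_jitter_sd,
                                kin_noise_sd = config$kin_noise_sd,
                                seed = seeds[s])
      ep <- epoch_trials(rec)
      ep <- detect_onsets(ep)
      rj <- reject_trials(ep, config$reject_rules)
      list(report = rj$report,
           feats = subject_features(rj$epochs, layout,
                                    config$baseline_window, n_w,
                                    config$n_conditions))
    })
    reports[[s]] <- subj$report
    feats <- subj$feats
    present <- feats$counts > 0
    w_mask <- array(rep(as.numeric(present), each = prod(dim(feats$erds)[1:3])),
                    dim(feats$erds))
    e0 <- feats$erds
    e0[is.na(e0)] <- 0
    if (is.null(erds_sum)) {
      erds_sum <- e0
      erds_n <- as.numeric(present)
    } else {
      erds_sum <- erds_sum + e0
      erds_n <- erds_n + as.numeric(present)
    }
    for (cond in which(present)) {
      emg_group[[cond]] <- c(emg_group[[cond]], list(feats$emg[[cond]]))
    }
    if (is.null(kin_ref)) {
      kin_ref <- feats$pca$components
      al <- list(perm = seq_len(ncol(kin_ref)), sign = rep(1, ncol(kin_ref)))
    } else {
      al <- align_components(kin_ref, feats$pca$components)
    }
    for (cond in which(present)) {
      ks <- feats$kin_scores[[cond]][al$perm, , drop = FALSE] * al$sign
      kin_group[[cond]] <- c(kin_group[[cond]], list(ks))
    }
    for (w in seq_len(n_w)) {
      tw <- win_idx_eeg[[w]]
      for (ri in seq_len(nrow(region))) {
        chs <- match(layout$channel_neighborhoods[[region[ri, 1]]],
                     layout$channels)
        fqs <- layout$frequency_neighborhoods[[region[ri, 2]]]
        pat <- t(matrix(feats$erds[chs, fqs, tw, ],
                        length(chs) * length(fqs) * length(tw),
                        config$n_conditions))
        rownames(pat) <- seq_len(config$n_conditions)
        region_patterns[[w]][[ri]] <-
          c(region_patterns[[w]][[ri]], list(pat))
      }
    }
  }

  say("group-level RDMs")
  bundle <- run_stage("group-level", {
    if (any(erds_n == 0))
      stopf("condition(s) %s unusable in every subject",
            paste(which(erds_n == 0), collapse = ", "))
    erds_group <- sweep(erds_sum, 4, erds_n, "/")
    emg_g <- lapply(emg_group, function(l) Reduce(`+`, l) / length(l))
    kin_g <- lapply(kin_group, function(l) Reduce(`+`, l) / length(l))

    cond_names <- seq_len(config$n_conditions)
    cat_rdms <- list(grasp_type = categorical_rdm(taxonomy, "grasp_type"),
                     thumb_position = categorical_rdm(taxonomy,
                                                      "thumb_position"),
                     object_shape = categorical_rdm(taxonomy, "object_shape"))
    n_cnb <- length(layout$channel_neighborhoods)
    n_fnb <- length(layout$frequency_neighborhoods)
    reference <- vector("list", n_w)
    candidate <- vector("list", n_w)
    maps <- vector("list", n_w)
    second <- vector("list", n_w)
    boots <- vector("list", n_w)
    for (w in seq_len(n_w)) {
      tw <- win_idx_eeg[[w]]
      refs <- vector("list", n_cnb * n_fnb)
      nm <- character(n_cnb * n_fnb)
      k <- 1L
      for (fi in seq_len(n_fnb)) {
        fqs <- layout$frequency_neighborhoods[[fi]]
        for (ci in seq_len(n_cnb)) {
          chs <- match(layout$channel_neighborhoods[[ci]], layout$channels)
          pat <- t(matrix(erds_group[chs, fqs, tw, ],
                          length(chs) * length(fqs) * length(tw),
                          config$n_conditions))
          rownames(pat) <- cond_names
          refs[[k]] <- compute_rdm(pat, source = cell_name(ci, fi),
                                   window = w)
          nm[k] <- cell_name(ci, fi)
          k <- k + 1L
        }
      }
      names(refs) <- nm
      reference[[w]] <- refs

      emg_pat <- t(vapply(emg_g, function(m)
        as.vector(m[, win_idx_emg[[w]], drop = FALSE]),
        numeric(8 * length(win_idx_emg[[w]]))))
      rownames(emg_pat) <- cond_names
      kin_pat <- t(vapply(kin_g, function(m)
        as.vector(m[, tw, drop = FALSE]),
        numeric(nrow(kin_g[[1]]) * length(tw))))
      rownames(kin_pat) <- cond_names
      cands <- list(emg = compute_rdm(emg_pat, source = "emg", window = w),
                    kinematics = compute_rdm(kin_pat, source = "kinematics",
                                             window = w))
      cands <- c(cands, cat_rdms)
      candidate[[w]] <- cands[config$candidates]

      maps[[w]] <- lapply(candidate[[w]], function(cd)
        searchlight_rsa(refs, cd, n_cnb, n_fnb,
                        candidate_id = attr(cd, "source"), region = region))

      rmeans <- vapply(maps[[w]], `[[`, numeric(1), "region_mean")
      best <- names(which.min(rmeans))
      boots[[w]] <- if (config$n_boot >= 1) list(
        candidate = best,
        result = bootstrap_effect(region_patterns[[w]],
                                  candidate[[w]][[best]],
                                  n_iter = config$n_boot,
                                  alpha = config$alpha,
                                  seed = seeds[1] %% 100000 + w))
      else list(candidate = best, result = NULL)

      region_rdm <- Reduce(`+`, lapply(region_cells, function(cn)
        unclass(refs[[cn]]))) / length(region_cells)
      region_rdm <- structure(region_rdm, class = c("rdm", "matrix"),
                              raw = region_rdm, source = "eeg_region",
                              window = w, scaling = "rank")
      second[[w]] <- second_level_rdm(c(list(eeg_region = region_rdm),
                                        candidate[[w]]))
    }
    list(reference_rdms = reference, candidate_rdms = candidate,
         rsa_maps = maps, bootstrap = boots, second_level = second)
  })

  qc <- do.call(rbind, lapply(seq_along(reports), function(s)
    cbind(subject = s, reports[[s]])))
  structure(c(bundle, list(
    config = config, layout = layout, taxonomy = taxonomy, region = region,
    qc = qc,
    truth = list(effect = eff,
                 planted_cell = c(channel_nb = eff$channel_nb,
                                  freq_nb = eff$freq_nb)),
    provenance = list(hash = config$hash, seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("grasprsa")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))),
    class = "grasp_rsa_result")
}

#' @export
print.grasp_rsa_result <- function(x, ...) {
  cat(sprintf("grasp RSA result: %d windows x %d reference RDMs, %d candidates\n",
              length(x$reference_rdms), length(x$reference_rdms[[1]]),
              length(x$candidate_rdms[[1]])))
  cat(sprintf("config %s, seed %s, %.1f s\n", x$provenance$hash,
              x$config$seed, x$provenance$elapsed_s))
  invisible(x)
}

#' Summarize a pipeline result bundle
#'
#' Produces the human-readable report: per-window best-matching candidate
#' at the region of interest and at the map arg-min, bootstrap confidence
#' intervals, trial-rejection counts, a localized-structure check (are
#' the cells overlapping the arg-min systematically closer than the
#' rest?), and the planted-effect recovery verdict when ground truth is
#' present.
#'
#' @param object a `grasp_rsa_result`.
#' @param localization_alpha significance level of the rank-sum
#'   localized-structure check (default 0.01).
#' @param ... unused.
#' @return object of class `grasp_rsa_summary`.
#' @export
summary.grasp_rsa_result <- function(object, localization_alpha = 0.01,
                                     ...) {
  need <- c("reference_rdms", "candidate_rdms", "rsa_maps", "bootstrap",
            "second_level", "qc")
  miss <- need[vapply(need, function(f)
    is.null(object[[f]]) || length(object[[f]]) == 0, logical(1))]
  if (length(miss))
    stopf("incomplete result bundle: missing %s", paste(miss, collapse = ", "))
  n_w <- length(object$rsa_maps)
  rows <- lapply(seq_len(n_w), function(w) {
    maps <- object$rsa_maps[[w]]
    rmeans <- vapply(maps, `[[`, numeric(1), "region_mean")
    best_region <- names(which.min(rmeans))
    mins <- vapply(maps, function(m) min(m$distances), numeric(1))
    best_global <- names(which.min(mins))
    am <- maps[[best_global]]$argmin
    bt <- object$bootstrap[[w]]$result
    data.frame(window = w, best_candidate_region = best_region,
               region_mean = min(rmeans),
               best_candidate_global = best_global,
               argmin_channel_nb = am[1], argmin_freq_nb = am[2],
               min_distance = mins[best_global],
               boot_candidate = object$bootstrap[[w]]$candidate,
               boot_observed = if (is.null(bt)) NA_real_ else bt$observed,
               ci_low = if (is.null(bt)) NA_real_ else bt$ci_low,
               ci_high = if (is.null(bt)) NA_real_ else bt$ci_high)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # localized-structure check on the window-1 best map: cells overlapping
  # the arg-min (excluding it) vs all remaining cells
  m1 <- object$rsa_maps[[1]][[tab$best_candidate_global[1]]]
  ov <- overlapping_cells(object$layout, tab$argmin_channel_nb[1],
                          tab$argmin_freq_nb[1])
  sel <- ov
  sel[tab$argmin_channel_nb[1], tab$argmin_freq_nb[1]] <- FALSE
  pw <- stats::wilcox.test(m1$distances[sel], m1$distances[!ov],
                           alternative = "less", exact = FALSE)$p.value
  localized <- pw < localization_alpha

  recovery <- NULL
  if (!is.null(object$truth$planted_cell) &&
      !identical(object$config$effect_model, "none") &&
      object$config$effect_size > 0) {
    pc <- object$truth$planted_cell
    ovp <- overlapping_cells(object$layout, pc[1], pc[2])
    hit <- ovp[tab$argmin_channel_nb[1], tab$argmin_freq_nb[1]]
    recovery <- list(planted = pc, hit = unname(hit),
                     planted_model = object$config$effect_model,
                     model_recovered =
                       tab$best_candidate_region[1] ==
                         object$config$effect_model)
  }
  structure(list(windows = tab,
                 localized = localized, localization_p = pw,
                 recovery = recovery,
                 n_trials = nrow(object$qc) / length(unique(object$qc$subject)),
                 rejections = table(object$qc$reason[object$qc$rejected]),
                 n_rejected = sum(object$qc$rejected)),
            class = "grasp_rsa_summary")
}

#' @export
print.grasp_rsa_summary <- function(x, ...) {
  cat("Per-window RSA summary\n")
  print(x$windows, digits = 3)
  cat(sprintf("\nTrials rejected: %d", x$n_rejected))
  if (x$n_rejected > 0)
    cat(" (", paste(names(x$rejections), x$rejections, sep = ": ",
                    collapse = ", "), ")", sep = "")
  cat("\n")
  if (x$localized)
    cat(sprintf("Localized representational structure at the window-1 arg-min (rank-sum p = %.2g)\n",
                x$localization_p))
  else
    cat("No localized structure: window-1 map spread is consistent across cells\n")
  if (!is.null(x$recovery)) {
    cat(sprintf("Planted-effect recovery: arg-min %s the planted cell/neighbors; best model %s (planted %s)\n",
                if (x$recovery$hit) "hits" else "misses",
                x$windows$best_candidate_region[1],
                x$recovery$planted_model))
  }
  invisible(x)
}
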