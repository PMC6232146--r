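#' Specify a planted condition effect for EEG synthesis
#'
#' Describes where and how strongly a condition-similarity structure is
#' planted in synthetic EEG: the target searchlight cell (one channel
#' neighborhood, one frequency neighborhood), the model RDM the planted
#' pattern dissimilarities should follow, and the effect magnitude.
#'
#' @param channel_nb index of the target channel neighborhood in the layout.
#' @param freq_nb index of the target frequency neighborhood.
#' @param model `n_conditions` x `n_conditions` model dissimilarity matrix
#'   (e.g. a categorical RDM), or `NULL` for no structure.
#' @param effect_size non-negative scaling of the between- vs
#'   within-category pattern difference; at 0 all conditions are
#'   exchangeable.
#' @param noise_sd amplitude of the background EEG activity.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(channel_nb, freq_nb, model = NULL, effect_size = 1,
                        noise_sd = 0.5) {
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (!is.null(model)) {
    model <- unclass(as.matrix(model))
    if (nrow(model) != ncol(model)) stopf("model RDM must be square")
  }
  structure(list(channel_nb = channel_nb, freq_nb = freq_nb, model = model,
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "effect_spec")
}

# Map a model RDM to per-condition amplitude gains over the target
# channels: classical MDS embeds the conditions so that embedding distances
# follow the model, each embedding axis drives the execution-phase
# oscillatory gain of one target channel.  Deterministic given the model.
condition_gains <- function(model, n_conditions, n_channels, effect_size) {
  G <- matrix(1, n_conditions, n_channels)
  if (is.null(model) || effect_size == 0) return(G)
  if (nrow(model) != n_conditions)
    stopf("model RDM has %d conditions, protocol has %d", nrow(model),
          n_conditions)
  k <- min(n_channels, n_conditions - 1)
  # degenerate models (few categories) have fewer positive eigenvalues
  # than k; cmdscale then returns fewer columns, padded below
  Y <- suppressWarnings(stats::cmdscale(stats::as.dist(model), k = k))
  if (ncol(Y) < n_channels)
    Y <- cbind(Y, matrix(0, n_conditions, n_channels - ncol(Y)))
  Z <- Y / max(abs(Y))
  depth <- pmin(pmax(effect_size * (0.45 + 0.35 * Z), 0), 0.95)
  1 - depth
}

# sin/cos oscillator with piecewise-constant per-trial phase, vectorized
trial_phase_osc <- function(sin_t, cos_t, phases, samples_per_trial) {
  cp <- rep(cos(phases), each = samples_per_trial)
  sp <- rep(sin(phases), each = samples_per_trial)
  sin_t * cp + cos_t * sp
}

#' Synthesize a session of EEG with a planted condition effect
#'
#' Generates a continuous multichannel EEG stream for a whole session.
#' Background activity is broadband noise with a 1/f-weighted component
#' plus ongoing alpha (10 Hz) and beta (20 Hz) oscillators.  An additional
#' oscillator at the center frequency of the target frequency neighborhood
#' is present in all channels; during movement execution (from movement
#' onset to the end of the execution phase) its amplitude is suppressed —
#' an event-related desynchronization.  In the five channels of the target
#' neighborhood the suppression gain is condition specific, derived from
#' the planted model RDM, so that condition-pattern dissimilarities in the
#' target searchlight cell correlate with the model, increasingly so with
#' `effect_size`.  In all other channels the suppression is a fixed,
#' condition-independent gain.
#'
#' @param protocol a [generate_protocol()] object.
#' @param effect an [effect_spec()].
#' @param layout a [searchlight_layout()]; the effect's target
#'   neighborhoods must exist in it.
#' @param onsets_s per-trial movement-onset latencies in seconds after the
#'   execution cue (default 0.3 s for every trial).
#' @param fs sampling rate in Hz (default: the protocol EEG rate).
#' @param seed integer seed.
#' @return channels x time matrix with channel rownames; attributes
#'   `"gains"` (condition x target-channel amplitude gain matrix),
#'   `"target_channels"` and `"f_target"` record the planted ground truth.
#' @export
synthesize_eeg <- function(protocol, effect, layout, onsets_s = NULL,
                           fs = NULL, seed = NULL) {
  fs <- fs %||% protocol$fs$eeg %||% 100
  n_cnb <- length(layout$channel_neighborhoods)
  n_fnb <- length(layout$frequency_neighborhoods)
  if (effect$channel_nb < 1 || effect$channel_nb > n_cnb)
    stopf("unknown channel neighborhood id %s (layout has %d)",
          effect$channel_nb, n_cnb)
  if (effect$freq_nb < 1 || effect$freq_nb > n_fnb)
    stopf("unknown frequency neighborhood id %s (layout has %d)",
          effect$freq_nb, n_fnb)
  channels <- layout$channels
  target_ch <- layout$channel_neighborhoods[[effect$channel_nb]]
  f_target <- mean(layout$freqs[layout$frequency_neighborhoods[[effect$freq_nb]]])

  trials <- protocol$trials
  n_trials <- nrow(trials)
  spt <- round(protocol$trial_duration * fs)
  n <- n_trials * spt
  tt <- (seq_len(n) - 1) / fs
  ph <- phase_times(protocol)           # fixation/obs/exec/relax starts, end
  if (is.null(onsets_s)) onsets_s <- rep(0.3, n_trials)
  onsets_s <- rep_len(onsets_s, n_trials)

  G <- condition_gains(effect$model, protocol$n_conditions, length(target_ch),
                       effect$effect_size)
  # per-trial suppression interval (movement onset .. end of execution)
  i0 <- round((trials$start_s + ph[3] + onsets_s) * fs) + 1L
  i1 <- round((trials$start_s + ph[4]) * fs)

  with_seed(seed, {
    s10 <- sin(2 * pi * 10 * tt); c10 <- cos(2 * pi * 10 * tt)
    s20 <- sin(2 * pi * 20 * tt); c20 <- cos(2 * pi * 20 * tt)
    sT <- sin(2 * pi * f_target * tt); cT <- cos(2 * pi * f_target * tt)
    eeg <- matrix(0, length(channels), n,
                  dimnames = list(channels, NULL))
    for (ci in seq_along(channels)) {
      bg <- effect$noise_sd *
        (0.8 * rnorm(n) +
           0.6 * as.numeric(stats::filter(rnorm(n), 0.97, "recursive")) * 0.17)
      phases <- matrix(runif(3 * n_trials, 0, 2 * pi), n_trials, 3)
      osc <- 0.45 * trial_phase_osc(s10, c10, phases[, 1], spt) +
             0.30 * trial_phase_osc(s20, c20, phases[, 2], spt)
      tosc <- trial_phase_osc(sT, cT, phases[, 3], spt)
      gain <- rep(1, n)
      tpos <- match(channels[ci], target_ch)
      for (tr in seq_len(n_trials)) {
        g <- if (!is.na(tpos)) G[trials$condition[tr], tpos] else 0.7
        gain[i0[tr]:i1[tr]] <- g
      }
      eeg[ci, ] <- bg + osc + 1.1 * gain * tosc
    }
    attr(eeg, "gains") <- G
    attr(eeg, "target_channels") <- target_ch
    attr(eeg, "f_target") <- f_target
    attr(eeg, "onsets_s") <- onsets_s
    eeg
  })
}

#' Synthesize synergy-driven EMG
#'
#' Eight-channel EMG in which the execution-phase activation amplitude of
#' each channel is a non-negative mixture `weights %*% activation` of a few
#' muscle synergies; channel signals are amplitude-modulated carriers so
#' the Hilbert envelope recovers the activation profile.  Rest phases
#' carry only a small tonic amplitude plus noise, and the condition
#' similarity of the envelopes follows the similarity of the per-condition
#' activation vectors.
#'
#' @param protocol a [generate_protocol()] object.
#' @param synergy_weights channels x synergies (8 x S) non-negative mixing
#'   matrix; default a seeded random 8 x 3 matrix.
#' @param condition_activations conditions x synergies matrix of
#'   non-negative synergy activations; default seeded random.
#' @param noise_sd additive noise SD (default 0.05).
#' @param onsets_s per-trial onset latencies after the execution cue (s).
#' @param fs sampling rate (default 200 Hz).
#' @param seed integer seed.
#' @return channels x time matrix; attribute `"amplitudes"` holds the
#'   channels x conditions execution amplitudes.
#' @export
synthesize_emg <- function(protocol, synergy_weights = NULL,
                           condition_activations = NULL, noise_sd = 0.05,
                           onsets_s = NULL, fs = NULL, seed = NULL) {
  fs <- fs %||% protocol$fs$emg %||% 200
  n_emg <- 8L
  with_seed(seed, {
    if (is.null(synergy_weights))
      synergy_weights <- matrix(abs(rnorm(n_emg * 3)), n_emg, 3)
    if (is.null(condition_activations))
      condition_activations <- matrix(abs(rnorm(protocol$n_conditions *
                                                  ncol(synergy_weights))),
                                      protocol$n_conditions,
                                      ncol(synergy_weights))
    if (ncol(synergy_weights) < 1) stopf("need at least one synergy")
    if (ncol(condition_activations) != ncol(synergy_weights))
      stopf("condition_activations has %d synergies, weights have %d",
            ncol(condition_activations), ncol(synergy_weights))
    if (nrow(condition_activations) != protocol$n_conditions)
      stopf("condition_activations must have one row per condition")
    if (any(condition_activations < 0)) stopf("activations must be non-negative")

    trials <- protocol$trials
    n_trials <- nrow(trials)
    spt <- round(protocol$trial_duration * fs)
    n <- n_trials * spt
    tt <- (seq_len(n) - 1) / fs
    ph <- phase_times(protocol)
    if (is.null(onsets_s)) onsets_s <- rep(0.3, n_trials)
    onsets_s <- rep_len(onsets_s, n_trials)

    amp <- synergy_weights %*% t(condition_activations)   # ch x cond
    if (max(amp) > 0) amp <- amp / max(amp)

    env <- numeric(n)
    for (tr in seq_len(n_trials)) {
      t_on <- trials$start_s[tr] + ph[3] + onsets_s[tr]
      t_off <- trials$start_s[tr] + ph[4]
      idx <- which(tt >= t_on & tt < t_off + 0.3)
      e <- pmin(1, (tt[idx] - t_on) / 0.2)
      e <- e * pmin(1, pmax(0, (t_off + 0.3 - tt[idx]) / 0.3))
      env[idx] <- e
    }
    cond_amp_t <- amp[, trials$condition, drop = FALSE]  # ch x trial
    emg <- matrix(0, n_emg, n)
    trial_of_sample <- rep(seq_len(n_trials), each = spt)
    for (ch in seq_len(n_emg)) {
      fc <- 25 + 6 * ch
      phases <- runif(n_trials, 0, 2 * pi)
      carrier <- sin(2 * pi * fc * tt + rep(phases, each = spt))
      a <- 0.15 + cond_amp_t[ch, trial_of_sample] * env
      emg[ch, ] <- a * carrier + noise_sd * rnorm(n)
    }
    rownames(emg) <- paste0("EMG", seq_len(n_emg))
    attr(emg, "amplitudes") <- amp
    attr(emg, "envelope") <- env
    emg
  })
}

#' Synthesize synergy-driven joint-angle kinematics
#'
#' Nineteen joint-angle traces generated from a low-dimensional synergy
#' basis: `angles(t) = rest + basis %*% (scores[condition] * m(t)) + noise`,
#' where `m(t)` is a smooth movement profile rising at movement onset,
#' holding through execution and decaying in relaxation.  Samples are drawn
#' at a jittered, variable rate so that the instantaneous rate stays within
#' `rate_range` (emulating an optical tracker); angles are wrapped to
#' `(-pi, pi]`.
#'
#' @param protocol a [generate_protocol()] object.
#' @param synergy_basis 19 x K full-column-rank basis; default a seeded
#'   random orthonormal 19 x 5 basis scaled to 0.4 rad.
#' @param condition_scores conditions x K synergy score matrix; default
#'   seeded random.
#' @param noise_sd SD of additive angular noise in radians (default 0).
#' @param onsets_s per-trial onset latencies after the execution cue (s).
#' @param rate_range sampling-rate range in Hz (default 80-120).
#' @param seed integer seed.
#' @return list with `time` (timestamps, s) and `angles` (19 x n matrix);
#'   attribute `"scores"` keeps the condition scores.
#' @export
synthesize_kinematics <- function(protocol, synergy_basis = NULL,
                                  condition_scores = NULL, noise_sd = 0,
                                  onsets_s = NULL, rate_range = c(80, 120),
                                  seed = NULL) {
  n_joints <- 19L
  with_seed(seed, {
    if (is.null(synergy_basis))
      synergy_basis <- qr.Q(qr(matrix(rnorm(n_joints * 5), n_joints, 5))) * 0.4
    if (qr(synergy_basis)$rank < ncol(synergy_basis))
      stopf("synergy_basis is rank deficient")
    K <- ncol(synergy_basis)
    if (is.null(condition_scores))
      condition_scores <- matrix(rnorm(protocol$n_conditions * K),
                                 protocol$n_conditions, K)
    if (ncol(condition_scores) != K)
      stopf("condition_scores must have %d columns", K)
    if (nrow(condition_scores) != protocol$n_conditions)
      stopf("condition_scores must have one row per condition")

    trials <- protocol$trials
    dur <- nrow(trials) * protocol$trial_duration
    ph <- phase_times(protocol)
    if (is.null(onsets_s)) onsets_s <- rep(0.3, nrow(trials))
    onsets_s <- rep_len(onsets_s, nrow(trials))

    n_est <- ceiling(dur * rate_range[2]) + 16
    dts <- runif(n_est, 1 / rate_range[2], 1 / rate_range[1])
    ts <- cumsum(dts)
    ts <- c(0, ts[ts < dur - 1e-9])

    tr_idx <- pmin(nrow(trials), floor(ts / protocol$trial_duration) + 1)
    rel <- ts - trials$start_s[tr_idx]
    t_on <- ph[3] + onsets_s[tr_idx]
    m <- pmin(1, pmax(0, (rel - t_on) / 0.5)) *
      pmin(1, pmax(0, (ph[5] - 0.5 - rel) / 0.5 + 1))
    m[rel < t_on] <- 0
    sc <- condition_scores[trials$condition[tr_idx], , drop = FALSE] * m
    rest <- seq(0.05, 0.25, length.out = n_joints)
    angles <- synergy_basis %*% t(sc) + rest
    if (noise_sd > 0)
      angles <- angles + noise_sd * rnorm(length(angles))
    angles <- wrap_angle(angles)
    rownames(angles) <- paste0("joint", seq_len(n_joints))
    out <- list(time = ts, angles = angles)
    attr(out, "scores") <- condition_scores
    attr(out, "basis") <- synergy_basis
    out
  })
}

#' Synthesize the movement accelerometer stream
#'
#' Three-axis accelerometer that is quiescent except during movement: at
#' each trial's true movement onset (a fixed latency after the execution
#' cue plus Gaussian jitter, clipped into the first second and flagged) the
#' signal changes abruptly in both mean and slope and stays active until
#' the end of the execution phase.
#'
#' @param protocol a [generate_protocol()] object.
#' @param onset_jitter_sd SD of the onset latency jitter in seconds.
#' @param amplitude movement amplitude in g (0 disables the onset step).
#' @param noise_sd baseline noise SD in g.
#' @param base_latency mean onset latency after the execution cue (s).
#' @param onsets_s optional per-trial latencies overriding the draw.
#' @param fs sampling rate (default 50 Hz).
#' @param seed integer seed.
#' @return list with `signal` (3 x time matrix) and `truth`, a data frame
#'   of per-trial ground-truth onsets (`trial`, `condition`, `onset_s`
#'   relative to the execution cue, `onset_sample` at the accelerometer
#'   rate, `clipped`).
#' @export
synthesize_accelerometer <- function(protocol, onset_jitter_sd = 0.05,
                                     amplitude = 0.35, noise_sd = 0.02,
                                     base_latency = 0.3, onsets_s = NULL,
                                     fs = NULL, seed = NULL) {
  fs <- fs %||% protocol$fs$accel %||% 50
  if (onset_jitter_sd < 0) stopf("onset_jitter_sd must be >= 0")
  trials <- protocol$trials
  n_trials <- nrow(trials)
  spt <- round(protocol$trial_duration * fs)
  n <- n_trials * spt
  ph <- phase_times(protocol)
  with_seed(seed, {
    clipped <- logical(n_trials)
    if (is.null(onsets_s)) {
      onsets_s <- base_latency + rnorm(n_trials, 0, onset_jitter_sd)
      clipped <- onsets_s < 1 / fs | onsets_s > 1 - 1 / fs
      onsets_s <- pmin(pmax(onsets_s, 1 / fs), 1 - 1 / fs)
    }
    onsets_s <- rep_len(onsets_s, n_trials)
    # snap to the sampling grid so ground truth is exact
    onset_sample <- as.integer(round(onsets_s * fs))
    onsets_s <- onset_sample / fs
    sig <- matrix(rnorm(3 * n, 0, noise_sd), 3, n)
    tt <- (seq_len(n) - 1) / fs
    for (tr in seq_len(n_trials)) {
      t_on <- trials$start_s[tr] + ph[3] + onsets_s[tr]
      t_off <- trials$start_s[tr] + ph[4]
      idx <- which(tt >= t_on - 1e-9 & tt < t_off)
      if (!length(idx) || amplitude == 0) next
      rel <- tt[idx] - t_on
      sig[1, idx] <- sig[1, idx] + amplitude
      sig[2, idx] <- sig[2, idx] + amplitude * pmin(1.5, 2.5 * rel)
      sig[3, idx] <- sig[3, idx] +
        0.4 * amplitude * sin(2 * pi * 3 * rel)
    }
    rownames(sig) <- c("accX", "accY", "accZ")
    list(signal = sig,
         truth = data.frame(trial = trials$trial,
                            condition = trials$condition,
                            onset_s = onsets_s,
                            onset_sample = onset_sample,
                            clipped = clipped))
  })
}

#' Synthesize a complete multimodal grasping session
#'
#' Assembles one subject's synchronized raw streams — EEG (+ low-amplitude
#' EOG), EMG, joint angles, accelerometer — and the event list, sharing a
#' single set of true movement onsets across modalities.  Synergy weights,
#' condition activations, the kinematic basis and condition scores may be
#' passed in so that a cohort of subjects shares the same condition
#' structure (as the group-level analysis assumes).
#'
#' @param protocol a [generate_protocol()] object.
#' @param layout a [searchlight_layout()].
#' @param effect an [effect_spec()] for the EEG generator.
#' @param taxonomy optional taxonomy data frame, stored for downstream use.
#' @param emg_weights,emg_activations,kin_basis,kin_scores optional shared
#'   condition structure (see [synthesize_emg()], [synthesize_kinematics()]).
#' @param onset_jitter_sd,accel_amplitude accelerometer parameters.
#' @param kin_noise_sd angular noise SD (radians).
#' @param seed integer seed for the whole session.
#' @return object of class `grasp_recording`.
#' @export
synthesize_session <- function(protocol, layout, effect,
                               taxonomy = NULL,
                               emg_weights = NULL, emg_activations = NULL,
                               kin_basis = NULL, kin_scores = NULL,
                               onset_jitter_sd = 0.05, accel_amplitude = 0.35,
                               kin_noise_sd = 0.02, seed = NULL) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, 5))
  acc <- synthesize_accelerometer(protocol, onset_jitter_sd = onset_jitter_sd,
                                  amplitude = accel_amplitude,
                                  seed = seeds[1])
  onsets <- acc$truth$onset_s
  eeg <- synthesize_eeg(protocol, effect, layout, onsets_s = onsets,
                        seed = seeds[2])
  emg <- synthesize_emg(protocol, synergy_weights = emg_weights,
                        condition_activations = emg_activations,
                        onsets_s = onsets, seed = seeds[3])
  kin <- synthesize_kinematics(protocol, synergy_basis = kin_basis,
                               condition_scores = kin_scores,
                               noise_sd = kin_noise_sd,
                               onsets_s = onsets, seed = seeds[4])
  eog <- with_seed(seeds[5],
                   matrix(rnorm(3 * ncol(eeg), 0, 0.2), 3, ncol(eeg),
                          dimnames = list(c("EOGL", "EOGR", "EOGU"), NULL)))
  ph <- phase_times(protocol)
  trials <- protocol$trials
  fs_eeg <- protocol$fs$eeg %||% 100
  events <- do.call(rbind, lapply(seq_len(nrow(trials)), function(tr) {
    data.frame(trial = trials$trial[tr], condition = trials$condition[tr],
               repetition = trials$repetition[tr],
               label = c("trial_start", "observe", "execute", "relax"),
               time_s = trials$start_s[tr] + ph[1:4],
               sample = round((trials$start_s[tr] + ph[1:4]) * fs_eeg) + 1L)
  }))
  structure(list(
    eeg = eeg, eog = eog, emg = emg, joints = kin, accel = acc$signal,
    events = events,
    fs = list(eeg = fs_eeg, emg = protocol$fs$emg %||% 200,
              accel = protocol$fs$accel %||% 50),
    protocol = protocol, taxonomy = taxonomy, layout = layout,
    truth = list(onsets = acc$truth, effect = effect,
                 gains = attr(eeg, "gains"),
                 target_channels = attr(eeg, "target_channels"),
                 f_target = attr(eeg, "f_target"),
                 emg_amplitudes = attr(emg, "amplitudes"),
                 kin_scores = attr(kin, "scores")),
    seed = seed), class = "grasp_recording")
}

#' @export
print.grasp_recording <- function(x, ...) {
  cat(sprintf("Multimodal grasping recording: %d trials (%d conditions x %d reps)\n",
              nrow(x$protocol$trials), x$protocol$n_conditions,
              x$protocol$n_repetitions))
  cat(sprintf("EEG %d ch @%g Hz | EMG %d ch @%g Hz | %d joints (variable rate) | accel 3 ch @%g Hz\n",
              nrow(x$eeg), x$fs$eeg, nrow(x$emg), x$fs$emg,
              nrow(x$joints$angles), x$fs$accel))
  invisible(x)
}

#' Inject artifactual trials into a recording
#'
#' Corrupts selected trials so the rejection rules fire: kind
#' `"movement_during_observation"` adds an accelerometer and EMG burst in
#' the middle of the observation phase (the task executed too early);
#' `"tracking_glitch"` injects a large joint-angle discontinuity, like a
#' finger swap in optical tracking.  A trial listed twice is corrupted
#' once, with a warning.
#'
#' @param recording a `grasp_recording`.
#' @param bad_trials data frame with columns `trial` and `kind`.
#' @param seed integer seed (burst noise).
#' @return the modified recording; attribute `"injected"` records what was
#'   done.
#' @export
inject_artifact_trials <- function(recording, bad_trials, seed = NULL) {
  if (is.null(bad_trials) || nrow(bad_trials) == 0) return(recording)
  if (anyDuplicated(bad_trials$trial)) {
    warnf("trial(s) listed more than once; injecting each once")
    bad_trials <- bad_trials[!duplicated(bad_trials$trial), , drop = FALSE]
  }
  trials <- recording$protocol$trials
  if (!all(bad_trials$trial %in% trials$trial))
    stopf("unknown trial id(s): %s",
          paste(setdiff(bad_trials$trial, trials$trial), collapse = ", "))
  kinds <- c("movement_during_observation", "tracking_glitch")
  if (!all(bad_trials$kind %in% kinds))
    stopf("unknown artifact kind(s): %s",
          paste(setdiff(bad_trials$kind, kinds), collapse = ", "))
  ph <- phase_times(recording$protocol)
  fs_acc <- recording$fs$accel
  fs_emg <- recording$fs$emg
  with_seed(seed, {
    for (i in seq_len(nrow(bad_trials))) {
      tr <- bad_trials$trial[i]
      start <- trials$start_s[trials$trial == tr]
      if (bad_trials$kind[i] == "movement_during_observation") {
        t0 <- start + ph[2] + 1       # 1 s into observation
        ia <- round(t0 * fs_acc) + seq_len(round(0.5 * fs_acc))
        recording$accel[, ia] <- recording$accel[, ia] + 0.5
        ie <- round(t0 * fs_emg) + seq_len(round(0.5 * fs_emg))
        recording$emg[, ie] <- recording$emg[, ie] +
          0.8 * sin(2 * pi * 40 * seq_along(ie) / fs_emg)
      } else {
        t0 <- start + ph[3] + 1       # 1 s into execution
        idx <- which(recording$joints$time >= t0 &
                       recording$joints$time < t0 + 0.2)
        if (length(idx))
          recording$joints$angles[2, idx] <-
            wrap_angle(recording$joints$angles[2, idx] + 2.2)
      }
    }
    attr(recording, "injected") <- bad_trials
    recording
  })
}
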