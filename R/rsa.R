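# rank off-diagonal dissimilarities (average ties) and min-max scale to [0,1]
rank_scale_offdiag <- function(d) {
  lo <- lower.tri(d)
  v <- d[lo]
  r <- rank(v)                       # average ranks on ties
  sc <- if (max(r) == min(r)) rep(0.5, length(r))
        else (r - min(r)) / (max(r) - min(r))
  out <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  out[lo] <- sc
  out + t(out)
}

#' Representational dissimilarity matrix of condition patterns
#'
#' Pairwise dissimilarity `1 - r` (Pearson correlation) between the
#' activity patterns of all conditions, with the off-diagonal entries then
#' replaced by their average ranks and min-max scaled to `[0, 1]`.  The
#' raw (unranked) distance matrix is retained in the `"raw"` attribute.
#'
#' @param patterns conditions x features matrix, one pattern vector per
#'   condition (rownames are condition ids).
#' @param source label of the pattern source (searchlight cell id, "emg",
#'   "kinematics", ...).
#' @param window window id, if any.
#' @return object of class `rdm`: a symmetric, zero-diagonal,
#'   rank-scaled matrix with metadata attributes.
#' @export
compute_rdm <- function(patterns, source = NULL, window = NULL) {
  patterns <- as.matrix(patterns)
  n <- nrow(patterns)
  if (n < 3) stopf("need at least 3 condition patterns, got %d", n)
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0)) {
    who <- rownames(patterns)[sds == 0] %||% which(sds == 0)
    stopf("zero-variance pattern for condition(s): %s",
          paste(who, collapse = ", "))
  }
  if (is.null(rownames(patterns))) rownames(patterns) <- seq_len(n)
  raw <- 1 - stats::cor(t(patterns))
  diag(raw) <- 0
  m <- rank_scale_offdiag(raw)
  structure(m, class = c("rdm", "matrix"), raw = raw, source = source,
            window = window, scaling = "rank")
}

#' Binary categorical model RDM
#'
#' Model dissimilarity matrix for a labelling scheme: 0 for pairs of
#' conditions in the same category, 1 for pairs in different categories.
#'
#' @param taxonomy taxonomy data frame (see [default_taxonomy()]).
#' @param scheme one of `"grasp_type"`, `"thumb_position"`,
#'   `"object_shape"` (or any column of the taxonomy).
#' @return object of class `rdm` (binary, zero diagonal).
#' @export
categorical_rdm <- function(taxonomy, scheme) {
  if (!scheme %in% names(taxonomy))
    stopf("scheme %s not present in taxonomy", scheme)
  lab <- taxonomy[[scheme]]
  if (anyNA(lab)) stopf("condition(s) missing a %s label", scheme)
  m <- 1 - outer(lab, lab, `==`)
  mode(m) <- "numeric"
  dimnames(m) <- list(taxonomy$condition, taxonomy$condition)
  structure(m, class = c("rdm", "matrix"), raw = m, source = scheme,
            window = NULL, scaling = "categorical")
}

#' Distance between two RDMs
#'
#' `1 - Spearman rank correlation` over the lower-triangle entries of the
#' two matrices.  Because Spearman re-ranks internally, the distance is
#' invariant to any monotone transform of either RDM, so rank-scaled and
#' binary categorical RDMs are directly comparable.  Condition sets must
#' match in identity and order; there is no silent reindexing.
#'
#' @param reference,candidate `rdm` objects (or plain symmetric matrices)
#'   on the same condition set and ordering.
#' @return distance in `[0, 2]`.
#' @export
compare_rdms <- function(reference, candidate) {
  if (!all(dim(reference) == dim(candidate)))
    stopf("RDMs have different sizes: %d vs %d", nrow(reference),
          nrow(candidate))
  rn <- rownames(reference); cn <- rownames(candidate)
  if (!is.null(rn) && !is.null(cn) && !identical(as.character(rn),
                                                 as.character(cn)))
    stopf("condition ordering mismatch between RDMs")
  a <- reference[lower.tri(reference)]
  b <- candidate[lower.tri(candidate)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("constant RDM: Spearman distance undefined")
    return(NA_real_)
  }
  1 - stats::cor(a, b, method = "spearman")
}

cell_name <- function(ci, fi) sprintf("c%02d_f%02d", ci, fi)

#' Searchlight RSA map
#'
#' Compares one candidate RDM against the complete grid of reference RDMs
#' (one per searchlight cell) of a window, yielding a channel-centroid x
#' frequency-centroid map of `1 - Spearman` distances, its arg-min cell
#' and, optionally, the mean over a declared region of interest.
#'
#' @param reference_rdms named list of reference `rdm`s covering every
#'   cell, names as produced by the pipeline (`"c01_f01"`, ...).
#' @param n_channel_nb,n_freq_nb grid dimensions (31 and 26 by default).
#' @param candidate candidate `rdm`.
#' @param candidate_id label stored in the result.
#' @param region optional 2-column matrix/data frame of (channel centroid,
#'   frequency centroid) indices defining the region of interest.
#' @return object of class `rsa_map`: list with `distances`
#'   (matrix, channel x frequency centroids), `argmin` (indices), and
#'   `region_mean` when a region was given.
#' @export
searchlight_rsa <- function(reference_rdms, candidate,
                            n_channel_nb = 31, n_freq_nb = 26,
                            candidate_id = attr(candidate, "source") %||%
                              "candidate",
                            region = NULL) {
  wanted <- as.vector(outer(seq_len(n_channel_nb), seq_len(n_freq_nb),
                            cell_name))
  missing_cells <- setdiff(wanted, names(reference_rdms))
  if (length(missing_cells))
    stopf("reference set incomplete; missing cell(s): %s%s",
          paste(utils::head(missing_cells, 5), collapse = ", "),
          if (length(missing_cells) > 5) ", ..." else "")
  d <- matrix(NA_real_, n_channel_nb, n_freq_nb)
  for (fi in seq_len(n_freq_nb))
    for (ci in seq_len(n_channel_nb))
      d[ci, fi] <- compare_rdms(reference_rdms[[cell_name(ci, fi)]],
                                candidate)
  am <- which(d == min(d), arr.ind = TRUE)[1, ]
  out <- list(distances = d, candidate = candidate_id,
              argmin = c(channel_nb = unname(am[1]),
                         freq_nb = unname(am[2])))
  if (!is.null(region)) {
    region <- as.matrix(region)
    out$region <- region
    out$region_mean <- mean(d[region])
  }
  structure(out, class = "rsa_map")
}

#' @export
print.rsa_map <- function(x, ...) {
  cat(sprintf("RSA map vs %s: %d x %d cells, min %.3f at (channel nb %d, freq nb %d)\n",
              x$candidate, nrow(x$distances), ncol(x$distances),
              min(x$distances), x$argmin[1], x$argmin[2]))
  if (!is.null(x$region_mean))
    cat(sprintf("Region mean distance: %.3f over %d cells\n", x$region_mean,
                nrow(x$region)))
  invisible(x)
}

#' @export
plot.rsa_map <- function(x, main = NULL, ...) {
  graphics::image(seq_len(ncol(x$distances)), seq_len(nrow(x$distances)),
                  t(x$distances), col = grDevices::hcl.colors(64, "viridis",
                                                              rev = TRUE),
                  xlab = "frequency neighborhood",
                  ylab = "channel neighborhood",
                  main = main %||% paste("RSA distance vs", x$candidate), ...)
  graphics::box()
  invisible(x)
}

#' Subject-level bootstrap of an RSA effect
#'
#' Resamples subjects with replacement; in each iteration the group-level
#' condition patterns are recomputed from the resampled subjects, turned
#' into RDMs and compared with the candidate, and the mean distance over
#' the region cells is recorded.  The confidence interval is the
#' percentile interval of the replicates.
#'
#' @param cell_patterns list over region cells; each element is a list
#'   over subjects of conditions x features pattern matrices.
#' @param candidate candidate `rdm`.
#' @param n_iter bootstrap iterations (default 500).
#' @param alpha two-sided CI level (default 0.05 for a 95% CI).
#' @param seed integer seed.
#' @return object of class `bootstrap_result` with fields `observed`,
#'   `ci_low`, `ci_high`, `replicates`, `n_iterations`, `alpha`, `seed`
#'   and `ci_contains_observed` (violations are reported, not hidden).
#' @export
bootstrap_effect <- function(cell_patterns, candidate, n_iter = 500,
                             alpha = 0.05, seed = NULL) {
  if (n_iter < 1) stopf("n_iter must be >= 1")
  n_subj <- length(cell_patterns[[1]])
  if (n_subj < 2) stopf("need at least 2 subjects")
  dims <- lapply(cell_patterns, function(cell) dim(cell[[1]]))
  flat <- lapply(cell_patterns, function(cell)
    vapply(cell, as.vector, numeric(length(cell[[1]]))))
  rn <- rownames(cell_patterns[[1]][[1]])
  stat <- function(w) {
    mean(vapply(seq_along(flat), function(i) {
      g <- matrix(flat[[i]] %*% w / sum(w), dims[[i]][1], dims[[i]][2])
      rownames(g) <- rn
      compare_rdms(compute_rdm(g), candidate)
    }, numeric(1)))
  }
  observed <- stat(rep(1, n_subj))
  reps <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      stat(tabulate(sample.int(n_subj, n_subj, replace = TRUE), n_subj))
    }, numeric(1))
  })
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2)))
  structure(list(observed = observed, ci_low = ci[1], ci_high = ci[2],
                 replicates = reps, n_iterations = n_iter, alpha = alpha,
                 seed = seed,
                 ci_contains_observed = observed >= ci[1] &&
                   observed <= ci[2]),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%d iterations): observed %.3f, %d%% CI [%.3f, %.3f]\n",
              x$n_iterations, x$observed, round(100 * (1 - x$alpha)),
              x$ci_low, x$ci_high))
  if (!x$ci_contains_observed)
    cat("note: observed effect lies outside the percentile CI\n")
  invisible(x)
}

#' Second-level RDM among representations
#'
#' Assembles all pairwise comparisons between a set of RDMs (reference
#' cells, behavioral candidates, categorical models) into a dissimilarity
#' matrix of RDMs, using rank correlation (`1 - Spearman`) as the
#' dissimilarity measure.
#'
#' @param rdms list of `rdm` objects on the same condition set.
#' @param labels names for the rows/columns (default: list names).
#' @return K x K symmetric, zero-diagonal matrix.
#' @export
second_level_rdm <- function(rdms, labels = names(rdms)) {
  K <- length(rdms)
  if (K < 2) stopf("need at least 2 RDMs")
  ns <- vapply(rdms, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stopf("heterogeneous condition sets: sizes %s",
          paste(unique(ns), collapse = ", "))
  out <- matrix(0, K, K, dimnames = list(labels, labels))
  for (i in seq_len(K - 1))
    for (j in (i + 1):K)
      out[i, j] <- out[j, i] <- compare_rdms(rdms[[i]], rdms[[j]])
  out
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d conditions, %s scaling%s%s\n", nrow(x),
              attr(x, "scaling") %||% "raw",
              if (!is.null(attr(x, "source")))
                paste0(", source ", attr(x, "source")) else "",
              if (!is.null(attr(x, "window")))
                paste0(", window ", attr(x, "window")) else ""))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))],
              3))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = NULL, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "condition", ylab = "condition", axes = FALSE,
                  main = main %||% paste("RDM", attr(x, "source") %||% ""),
                  ...)
  graphics::axis(1, at = pretty(seq_len(n)))
  graphics::axis(2, at = pretty(seq_len(n)), labels = rev(pretty(seq_len(n))))
  graphics::box()
  invisible(x)
}
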