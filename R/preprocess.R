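#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase, no group delay).  The signal is reflection-padded at both
#' ends before filtering to suppress edge transients.
#'
#' @param x channels x time matrix (or a vector).
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4; the forward-backward pass doubles
#'   the effective attenuation).
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, fs, order = 4) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stopf("need 0 < low_hz < high_hz < fs/2 (= %g)", fs / 2)
  n <- ncol(x)
  pad <- 3 * (2 * order + 1)
  if (n <= pad)
    stopf("signal length %d too short for filter padding (%d)", n, pad)
  # cascade of high-pass and low-pass halves: numerically stabler than one
  # band-pass when the low edge is far below Nyquist
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  filt1 <- function(y) {
    # odd reflection padding
    yp <- c(2 * y[1] - rev(y[2:(pad + 1)]), y,
            2 * y[n] - rev(y[(n - pad):(n - 1)]))
    z <- signal::filtfilt(hp, yp)
    z <- signal::filtfilt(lp, z)
    z[(pad + 1):(pad + n)]
  }
  out <- t(apply(x, 1, filt1))
  dimnames(out) <- dimnames(x)
  if (vec) out <- drop(out)
  out
}

#' Downsample a regularly sampled signal
#'
#' Integer-ratio downsampling with internal anti-alias filtering: a
#' zero-phase symmetric FIR low-pass (cutoff at 80% of the target
#' Nyquist, unit DC gain, reflection-padded edges) followed by
#' subsampling.  For irregularly sampled traces (optical tracking) use
#' [interpolate_kinematics()] instead.
#'
#' @param x channels x time matrix (or vector).
#' @param from_hz original sampling rate.
#' @param to_hz target rate (default 100); must divide `from_hz`.
#' @return downsampled matrix with `ceiling(n * to_hz / from_hz)` columns.
#' @export
downsample <- function(x, from_hz, to_hz = 100) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  q <- from_hz / to_hz
  if (abs(q - round(q)) > 1e-9)
    stopf("from_hz must be an integer multiple of to_hz")
  q <- round(q)
  if (q == 1) return(if (vec) drop(x) else x)
  n <- ncol(x)
  ord <- 10 * q
  w <- signal::fir1(ord, 0.8 / q)
  w <- w / sum(w)                       # exact unit DC gain
  h <- ord / 2
  pad <- min(n - 1, ord)
  out <- t(apply(x, 1, function(y) {
    yp <- c(2 * y[1] - rev(y[2:(pad + 1)]), y,
            2 * y[n] - rev(y[(n - pad):(n - 1)]))
    f <- stats::filter(yp, w, sides = 2)
    f[pad + seq.int(1, n, by = q)]
  }))
  dimnames(out) <- list(rownames(x), NULL)
  if (vec) out <- drop(out)
  out
}

#' Epoch a recording into 15-s trials
#'
#' Cuts every modality into fifteen-second segments time-locked to the
#' trial-start events, interpolates the irregularly sampled joint angles
#' to a fixed 100-Hz grid per trial, and reorders the epochs to a common
#' order of grasping conditions (ascending condition id, then repetition).
#' Trials whose streams do not cover the full window are flagged rejected
#' with reason `"incomplete"`.
#'
#' @param recording a `grasp_recording`.
#' @param duration_s epoch duration in seconds (default 15).
#' @return object of class `grasp_epochs`: list with `epochs` (one entry
#'   per trial, each holding `eeg`, `emg`, `joints`, `accel`, condition and
#'   repetition, onset fields filled by [detect_movement_onset()]) plus
#'   session metadata.
#' @export
epoch_trials <- function(recording, duration_s = 15) {
  ev <- recording$events[recording$events$label == "trial_start", ]
  if (nrow(ev) == 0) stopf("recording has no trial_start events")
  fs <- recording$fs
  kin_t <- recording$joints$time
  epochs <- lapply(seq_len(nrow(ev)), function(i) {
    start <- ev$time_s[i]
    idx_of <- function(rate) round(start * rate) + seq_len(round(duration_s * rate))
    e <- list(trial = ev$trial[i], condition = ev$condition[i],
              repetition = ev$repetition[i],
              onset_sample = NA_integer_, onset_s = NA_real_,
              rejected = FALSE, reason = NA_character_)
    ie <- idx_of(fs$eeg); im <- idx_of(fs$emg); ia <- idx_of(fs$accel)
    kin_idx <- which(kin_t >= start & kin_t < start + duration_s)
    if (max(ie) > ncol(recording$eeg) || max(im) > ncol(recording$emg) ||
        max(ia) > ncol(recording$accel) || length(kin_idx) < 4) {
      e$rejected <- TRUE
      e$reason <- "incomplete"
      return(e)
    }
    e$eeg <- recording$eeg[, ie, drop = FALSE]
    e$emg <- recording$emg[, im, drop = FALSE]
    e$accel <- recording$accel[, ia, drop = FALSE]
    e$joints <- interpolate_kinematics(kin_t[kin_idx] - start,
                                       recording$joints$angles[, kin_idx,
                                                               drop = FALSE],
                                       target_hz = 100,
                                       t_range = c(0, duration_s - 1 / 100))
    e
  })
  ord <- order(ev$condition, ev$repetition)
  structure(list(epochs = epochs[ord], fs = fs,
                 protocol = recording$protocol,
                 taxonomy = recording$taxonomy,
                 layout = recording$layout,
                 truth = recording$truth),
            class = "grasp_epochs")
}

#' @export
print.grasp_epochs <- function(x, ...) {
  rej <- sum(vapply(x$epochs, `[[`, logical(1), "rejected"))
  cat(sprintf("Grasp epochs: %d trials (%d flagged rejected)\n",
              length(x$epochs), rej))
  invisible(x)
}

# SSE of the least-squares line over every prefix/suffix, via cumulants
segment_sse <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  sse_lin <- function(Sx, Sy, Sxx, Sxy, Syy, m) {
    vy <- Syy - Sy^2 / m
    vx <- Sxx - Sx^2 / m
    cv <- Sxy - Sx * Sy / m
    r <- vy - ifelse(vx > 0, cv^2 / vx, 0)
    pmax(r, 0)
  }
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cxy <- cumsum(x * y); cyy <- cumsum(y^2)
  m <- seq_len(n)
  pre <- sse_lin(cx, cy, cxx, cxy, cyy, m)
  tot <- c(cx[n], cy[n], cxx[n], cxy[n], cyy[n])
  suf <- sse_lin(tot[1] - c(0, cx[-n]), tot[2] - c(0, cy[-n]),
                 tot[3] - c(0, cxx[-n]), tot[4] - c(0, cxy[-n]),
                 tot[5] - c(0, cyy[-n]), n - m + 1)
  list(prefix = pre, suffix = suf)
}

#' Single change-point detection by piecewise linear fitting
#'
#' Finds the split that minimizes the total squared residual of two
#' least-squares line segments (local mean and slope) fitted before and
#' after the split.  The split is accepted only if it improves the
#' residual of the single-line fit by at least `min_improvement`
#' (relative); otherwise no change point is reported.
#'
#' @param y numeric signal.
#' @param min_seg minimum samples per segment (default 5).
#' @param min_improvement minimum relative SSE improvement over the
#'   no-split fit (default 0.1).
#' @return the number of samples before the change (the changed sample is
#'   `y[tau + 1]`), or `NA` if no acceptable change point exists.
#' @export
detect_changepoint <- function(y, min_seg = 5, min_improvement = 0.1) {
  n <- length(y)
  if (n < 2 * min_seg)
    stopf("window of %d samples shorter than 2 x minimum segment length (%d)",
          n, min_seg)
  s <- segment_sse(y)
  sse0 <- s$prefix[n]
  taus <- seq.int(min_seg, n - min_seg)
  total <- s$prefix[taus] + s$suffix[taus + 1]
  # ties (e.g. a continuous slope break fits either side exactly) resolve
  # to the earliest split within numerical tolerance of the minimum
  best <- which(total <= min(total) + 1e-10 * (sse0 + 1))[1]
  # a single line already fits (relative to the signal's own scale)
  scale <- sum((y - mean(y))^2)
  if (scale == 0 || sse0 <= 1e-10 * scale) return(NA_integer_)
  if ((sse0 - total[best]) / sse0 < min_improvement) return(NA_integer_)
  as.integer(taus[best])
}

#' Detect the movement onset from the trial accelerometer
#'
#' Combines the three accelerometer axes into the Euclidean magnitude and
#' searches the first second after the execution cue for the first abrupt
#' change in mean and slope, using [detect_changepoint()].
#'
#' @param accel_trial 3 x time accelerometer epoch.
#' @param fs sampling rate (default 50 Hz).
#' @param exec_cue_s execution-cue time within the trial (default 7 s).
#' @param search_s length of the searched window (default 1 s).
#' @param min_seg,min_improvement passed to [detect_changepoint()].
#' @return list with `onset_sample` (samples after the cue; the first
#'   moved sample is `onset_sample + 1`) and `onset_s`, or both `NA` if no
#'   onset is found.
#' @export
detect_movement_onset <- function(accel_trial, fs = 50, exec_cue_s = 7,
                                  search_s = 1, min_seg = 5,
                                  min_improvement = 0.1) {
  if (!is.matrix(accel_trial)) accel_trial <- matrix(accel_trial, nrow = 1)
  mag <- sqrt(colSums(accel_trial^2))
  idx <- round(exec_cue_s * fs) + seq_len(round(search_s * fs))
  if (max(idx) > length(mag) || min(idx) < 1)
    stopf("search window lies outside the trial")
  tau <- detect_changepoint(mag[idx], min_seg, min_improvement)
  list(onset_sample = tau, onset_s = if (is.na(tau)) NA_real_ else tau / fs)
}

# fill onset fields of all epochs in place
detect_onsets <- function(epochs, ...) {
  fs <- epochs$fs$accel
  exec_cue <- phase_times(epochs$protocol)[3]
  epochs$epochs <- lapply(epochs$epochs, function(e) {
    if (e$rejected) return(e)
    o <- detect_movement_onset(e$accel, fs = fs, exec_cue_s = exec_cue, ...)
    e$onset_sample <- o$onset_sample
    e$onset_s <- o$onset_s
    e
  })
  epochs
}

#' Reject incorrectly executed or badly tracked trials
#'
#' Applies the rejection rules to every epoch and removes rejected trials
#' from all modalities.  A trial is rejected when (a) the smoothed
#' accelerometer magnitude during the observation phase deviates from the
#' fixation baseline by more than `obs_accel_sd` baseline SDs (the task
#' was executed too early; reason `"movement"`), or (b) any joint angle
#' jumps by more than `joint_jump_rad` between consecutive samples (bad
#' optical tracking; reason `"tracking"`).  Epochs already flagged
#' (`"incomplete"`) stay rejected.  A trial with no detected movement
#' onset is rejected with reason `"no_onset"`.
#'
#' @param epochs a `grasp_epochs` object with onsets detected.
#' @param rules list with `obs_accel_sd` (default 5) and `joint_jump_rad`
#'   (default `pi/3`, i.e. 60 degrees).
#' @return list with `epochs` (kept trials only, a `grasp_epochs`),
#'   `report` (data frame trial/condition/repetition/rejected/reason) and
#'   `unusable_conditions` (conditions that lost all trials).
#' @export
reject_trials <- function(epochs,
                          rules = list(obs_accel_sd = 5,
                                       joint_jump_rad = pi / 3)) {
  ph <- phase_times(epochs$protocol)
  fs_acc <- epochs$fs$accel
  smooth5 <- function(v) as.numeric(stats::filter(v, rep(1 / 5, 5)))
  checked <- lapply(epochs$epochs, function(e) {
    if (e$rejected) return(e)
    mag <- sqrt(colSums(e$accel^2))
    fix <- mag[seq_len(round(ph[2] * fs_acc))]
    obs <- smooth5(mag[(round(ph[2] * fs_acc) + 1):round(ph[3] * fs_acc)])
    obs <- obs[!is.na(obs)]
    if (max(abs(obs - mean(fix))) > rules$obs_accel_sd * stats::sd(fix)) {
      e$rejected <- TRUE; e$reason <- "movement"; return(e)
    }
    jump <- max(abs(wrap_angle(t(diff(t(e$joints))))))
    if (jump > rules$joint_jump_rad) {
      e$rejected <- TRUE; e$reason <- "tracking"; return(e)
    }
    if (is.na(e$onset_sample)) {
      e$rejected <- TRUE; e$reason <- "no_onset"; return(e)
    }
    e
  })
  report <- data.frame(
    trial = vapply(checked, `[[`, numeric(1), "trial"),
    condition = vapply(checked, `[[`, numeric(1), "condition"),
    repetition = vapply(checked, `[[`, numeric(1), "repetition"),
    rejected = vapply(checked, `[[`, logical(1), "rejected"),
    reason = vapply(checked, `[[`, character(1), "reason"))
  kept <- checked[!report$rejected]
  counts <- table(factor(report$condition[!report$rejected],
                         levels = seq_len(epochs$protocol$n_conditions)))
  unusable <- as.integer(names(counts))[counts == 0]
  if (length(unusable))
    warnf("condition(s) %s lost all trials and are unusable",
          paste(unusable, collapse = ", "))
  out <- epochs
  out$epochs <- kept
  list(epochs = out, report = report, unusable_conditions = unusable)
}

#' EMG envelope via the analytic signal
#'
#' Standardizes each channel to zero mean and unit variance, then takes
#' the magnitude of the analytic signal (Hilbert transform) as the
#' envelope.  The order of operations (standardize, then analytic-signal
#' magnitude) is recorded in the `"processing"` attribute.
#'
#' @param emg_trial channels x time matrix (or vector).
#' @return envelope matrix of the same shape, non-negative.
#' @export
emg_envelope <- function(emg_trial) {
  vec <- !is.matrix(emg_trial)
  if (vec) emg_trial <- matrix(emg_trial, nrow = 1)
  sds <- apply(emg_trial, 1, stats::sd)
  if (any(sds == 0))
    stopf("constant EMG channel(s): %s",
          paste(which(sds == 0), collapse = ", "))
  n <- ncol(emg_trial)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  out <- t(apply(emg_trial, 1, function(y) {
    z <- (y - mean(y)) / stats::sd(y)
    Mod(stats::fft(stats::fft(z) * h, inverse = TRUE) / n)
  }))
  dimnames(out) <- dimnames(emg_trial)
  attr(out, "processing") <- "z-score, then analytic-signal magnitude"
  if (vec) out <- drop(out)
  out
}

#' Interpolate irregularly sampled joint angles to a fixed rate
#'
#' Cubic-spline interpolation of each angle trace onto a uniform grid
#' (default 100 Hz).  Angles are unwrapped before interpolation and
#' re-wrapped to `(-pi, pi]` afterwards, so traces crossing the +/-180
#' degree boundary interpolate smoothly.
#'
#' @param time strictly increasing sample timestamps (s).
#' @param angles traces x samples matrix of angles in radians.
#' @param target_hz output rate (default 100).
#' @param t_range optional `c(t0, t1)` limits of the output grid; default
#'   the observed time span.
#' @return traces x time matrix on the uniform grid; attribute `"time"`
#'   holds the grid.
#' @export
interpolate_kinematics <- function(time, angles, target_hz = 100,
                                   t_range = NULL) {
  if (!is.matrix(angles)) angles <- matrix(angles, nrow = 1)
  if (length(time) != ncol(angles))
    stopf("time and angles disagree: %d vs %d samples", length(time),
          ncol(angles))
  if (length(time) < 4) stopf("need at least 4 samples per trace")
  d <- diff(time)
  if (any(d == 0)) stopf("duplicate timestamps")
  if (any(d < 0)) stopf("timestamps must be strictly increasing")
  t_range <- t_range %||% range(time)
  grid <- seq(t_range[1], t_range[2], by = 1 / target_hz)
  out <- t(apply(angles, 1, function(y) {
    f <- stats::splinefun(time, unwrap_angle(y), method = "fmm")
    wrap_angle(f(grid))
  }))
  dimnames(out) <- list(rownames(angles), NULL)
  attr(out, "time") <- grid
  out
}

#' Circular mean of angles
#'
#' Mean direction `atan2(mean(sin), mean(cos))`, in `(-pi, pi]`.  Robust
#' to wraparound: the circular mean of 179 and -179 degrees is 180
#' degrees, not 0.  Errors when the resultant length is below `tol`
#' (near-uniform angles have no defined mean direction).
#'
#' @param angles numeric vector of angles in radians (non-empty).
#' @param tol minimum resultant length (default 1e-8).
#' @return mean direction in radians.
#' @export
circular_mean <- function(angles, tol = 1e-8) {
  if (!length(angles)) stopf("empty angle set")
  s <- mean(sin(angles)); c <- mean(cos(angles))
  if (sqrt(s^2 + c^2) < tol)
    stopf("circular mean undefined: resultant length below %g", tol)
  wrap_angle(atan2(s, c))
}

# elementwise circular mean across a list of equal-shaped arrays
circular_mean_arrays <- function(lst) {
  s <- Reduce(`+`, lapply(lst, sin)) / length(lst)
  c <- Reduce(`+`, lapply(lst, cos)) / length(lst)
  wrap_angle(atan2(s, c))
}

#' Principal-component synergies of joint-angle data
#'
#' PCA of a subject's joint-angle traces (traces x time), returning the
#' leading components ("kinematic synergies"), their score trajectories
#' and the variance fraction of every component.  Five components are
#' retained by default.
#'
#' @param joints traces x time matrix.
#' @param n_components components to retain (default 5).
#' @return list with `components` (traces x k loadings), `scores`
#'   (k x time trajectories), `var_explained` (fractions, all
#'   components), `center` (per-trace means) and `retained`.
#' @export
kinematic_pca <- function(joints, n_components = 5) {
  if (ncol(joints) <= nrow(joints))
    stopf("need more time samples than traces")
  p <- stats::prcomp(t(joints), center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  nz <- sum(p$sdev > max(p$sdev) * 1e-10)
  k <- min(n_components, nz)
  if (k < n_components)
    warnf("only %d nonzero-variance directions available (requested %d)",
          nz, n_components)
  list(components = p$rotation[, seq_len(k), drop = FALSE],
       scores = t(p$x[, seq_len(k), drop = FALSE]),
       var_explained = vf,
       center = p$center,
       retained = k)
}

#' Average repetition patterns to group-level condition patterns
#'
#' Arithmetic (or circular, for raw joint angles) averaging of
#' per-repetition patterns: first within subject across repetitions, then
#' across subjects, one group-level pattern per condition.  A subject with
#' no surviving repetition of a condition is excluded from that
#' condition's group mean and logged in the `"exclusions"` attribute.
#'
#' @param subject_patterns list over subjects; each subject is a list over
#'   conditions whose elements are repetitions x D matrices (or vectors
#'   for a single repetition, or `NULL` when no repetition survived).
#' @param circular use the circular mean (for angular data).
#' @return list over conditions of group-level pattern vectors.
#' @export
average_condition_patterns <- function(subject_patterns, circular = FALSE) {
  n_cond <- max(vapply(subject_patterns, length, integer(1)))
  excl <- NULL
  avg_reps <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    if (nrow(m) == 0) return(NULL)
    if (circular) apply(m, 2, function(a) circular_mean(a))
    else colMeans(m)
  }
  out <- lapply(seq_len(n_cond), function(cond) {
    per_subj <- lapply(subject_patterns, function(s)
      avg_reps(if (cond <= length(s)) s[[cond]] else NULL))
    have <- !vapply(per_subj, is.null, logical(1))
    if (!any(have))
      stopf("condition %d has no surviving repetitions in any subject", cond)
    if (!all(have))
      excl <<- rbind(excl, data.frame(condition = cond,
                                      subject = which(!have)))
    kept <- per_subj[have]
    if (circular) circular_mean_arrays(kept)
    else Reduce(`+`, kept) / length(kept)
  })
  attr(out, "exclusions") <- excl
  out
}
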