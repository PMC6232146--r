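#' Morlet time-frequency power
#'
#' Time-frequency decomposition of a multichannel epoch with complex Morlet
#' wavelets, on a frequency grid with 0.5-Hz resolution over 0.1-40 Hz by
#' default.  Power is the squared magnitude of the complex wavelet
#' coefficients; wavelets are scaled so a unit-amplitude sinusoid at the
#' bin frequency yields power close to 1.
#'
#' The wavelet width defaults to a linearly increasing 3-8 cycles from the
#' lowest to the highest grid frequency.  Bins whose wavelet support
#' (+/- 3 temporal SDs) exceeds the epoch length are computed with a
#' truncated wavelet and flagged invalid in the `"valid"` attribute rather
#' than silently zero padded.
#'
#' @param x channels x time matrix (rownames used as channel names).
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz; default [erds_freq_grid()].
#' @param n_cycles cycles per frequency; scalar, vector, or `NULL` for the
#'   3-8 linear default.
#' @param keep integer time indices at which to return power (default all);
#'   restricting `keep` saves most of the memory for long epochs.
#' @return array channels x frequencies x time(kept) of power, with a
#'   logical `"valid"` attribute per frequency bin.
#' @export
morlet_tfr <- function(x, fs, freqs = erds_freq_grid(), n_cycles = NULL,
                       keep = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (length(freqs) == 0) stopf("empty frequency grid")
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stopf("frequencies must lie in (0, fs/2)")
  n <- ncol(x)
  if (is.null(n_cycles)) {
    n_cycles <- if (length(freqs) == 1) 7
    else 3 + 5 * (freqs - min(freqs)) / (max(freqs) - min(freqs))
  }
  n_cycles <- rep_len(n_cycles, length(freqs))
  if (is.null(keep)) keep <- seq_len(n)
  keep <- as.integer(keep)
  if (any(keep < 1) || any(keep > n)) stopf("keep indices out of range")
  half <- ceiling(3 * n_cycles / (2 * pi * freqs) * fs)
  valid <- (2 * half + 1) <= n
  out <- morlet_power_cpp(t(x), fs, freqs, n_cycles, keep)
  out <- aperm(out, c(2, 3, 1))  # -> channel x freq x time
  dimnames(out) <- list(rownames(x), format(freqs, trim = TRUE), NULL)
  attr(out, "freqs") <- freqs
  attr(out, "valid") <- valid
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Event-related desynchronization/synchronization map
#'
#' Percent power change of the movement period relative to a baseline:
#' `ERD/S = (P_movement - P_baseline) / P_baseline * 100`.  The baseline
#' is the subject-specific mean power over the fixation interval of all
#' trials, per channel and frequency bin.  Values are not clipped; ERD/S
#' is bounded below by -100% because power is non-negative.
#'
#' @param power_movement channels x frequencies x time power array.
#' @param baseline_power channels x frequencies matrix of baseline power,
#'   strictly positive.
#' @return object of class `erds_map`: channels x frequencies x time array
#'   of percent change, with the baseline in attribute `"baseline"`.
#' @export
compute_erds <- function(power_movement, baseline_power) {
  d <- dim(power_movement)
  if (length(d) != 3) stopf("power_movement must be channels x freqs x time")
  if (!all(dim(baseline_power) == d[1:2]))
    stopf("baseline_power must be %d x %d", d[1], d[2])
  bad <- which(baseline_power <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ch <- rownames(baseline_power)[bad[1, 1]] %||% bad[1, 1]
    stopf("non-positive baseline power at channel %s, frequency bin %d",
          ch, bad[1, 2])
  }
  out <- (power_movement - c(baseline_power)) / c(baseline_power) * 100
  dimnames(out) <- dimnames(power_movement)
  attr(out, "baseline") <- baseline_power
  attr(out, "freqs") <- attr(power_movement, "freqs")
  class(out) <- c("erds_map", class(out))
  out
}
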