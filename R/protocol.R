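#' Generate a block-randomized grasping protocol
#'
#' Builds the session schedule of a grasping experiment: `n_conditions`
#' grasp types, each presented as a block of `n_repetitions` consecutive
#' 15-s trials.  Every trial runs through four phases: fixation (3 s),
#' observation (4 s), execution (4 s) and relaxation (4 s).  The order of
#' the condition blocks is randomized per seed; repetitions of a condition
#' are always consecutive.
#'
#' @param n_conditions number of grasp conditions (default 33).
#' @param n_repetitions trials per condition block (default 8).
#' @param seed integer seed controlling the block order; `NULL` uses the
#'   current RNG state.
#' @param phase_durations named numeric vector of phase lengths in seconds,
#'   in order fixation, observation, execution, relaxation.
#' @param fs named list of sampling rates per modality (Hz).  `joints` is a
#'   length-2 range because the optical tracker samples at a variable rate.
#' @return an object of class `grasp_protocol`: a list with the counts, the
#'   phase durations, the randomized `block_order`, per-modality sampling
#'   rates and a `trials` data frame (`trial`, `condition`, `repetition`,
#'   `start_s`) in presentation order.
#' @examples
#' p <- generate_protocol(33, 8, seed = 1)
#' nrow(p$trials)  # 264
#' @export
generate_protocol <- function(n_conditions = 33, n_repetitions = 8,
                              seed = NULL,
                              phase_durations = c(fixation = 3, observation = 4,
                                                  execution = 4, relaxation = 4),
                              fs = list(eeg = 100, emg = 200, accel = 50,
                                        joints = c(80, 120))) {
  if (length(n_conditions) != 1 || n_conditions < 2 ||
      n_conditions != round(n_conditions))
    stopf("n_conditions must be an integer >= 2")
  if (length(n_repetitions) != 1 || n_repetitions < 1 ||
      n_repetitions != round(n_repetitions))
    stopf("n_repetitions must be an integer >= 1")
  if (length(phase_durations) != 4 || any(phase_durations <= 0))
    stopf("phase_durations must be 4 positive values")
  trial_s <- sum(phase_durations)
  block_order <- with_seed(seed, sample.int(n_conditions))
  trials <- data.frame(
    trial = seq_len(n_conditions * n_repetitions),
    condition = rep(block_order, each = n_repetitions),
    repetition = rep(seq_len(n_repetitions), times = n_conditions))
  trials$start_s <- (trials$trial - 1) * trial_s
  structure(list(
    n_conditions = as.integer(n_conditions),
    n_repetitions = as.integer(n_repetitions),
    phase_durations = phase_durations,
    trial_duration = trial_s,
    block_order = block_order,
    fs = fs,
    trials = trials,
    seed = seed), class = "grasp_protocol")
}

#' @export
print.grasp_protocol <- function(x, ...) {
  cat(sprintf("Grasping protocol: %d conditions x %d repetitions = %d trials\n",
              x$n_conditions, x$n_repetitions, nrow(x$trials)))
  cat(sprintf("Trial: %s s (%s)\n", x$trial_duration,
              paste(sprintf("%s %g", names(x$phase_durations),
                            x$phase_durations), collapse = ", ")))
  cat("Block order:", paste(utils::head(x$block_order, 12), collapse = " "),
      if (x$n_conditions > 12) "..." else "", "\n")
  invisible(x)
}

# phase boundary times (s) within a trial: fixation start, observation start,
# execution start, relaxation start, trial end
phase_times <- function(protocol) {
  cumsum(c(0, protocol$phase_durations))
}

#' Default grasp taxonomy
#'
#' Loads the categorical labelling of the grasp conditions under three
#' schemes: `grasp_type` (power / precision / intermediate),
#' `thumb_position` (abducted / adducted) and `object_shape` (large bar,
#' small bar, large sphere, small sphere, disk, card, scissors).  The
#' shipped table is a synthetic but plausible assignment for a 33-grasp
#' repertoire; treat it as configuration data, not ground truth, and
#' substitute your own table for real recordings.
#'
#' @param file path to a TSV with columns `condition`, `grasp_type`,
#'   `thumb_position`, `object_shape`; defaults to the shipped table.
#' @return data frame with one row per condition, validated.
#' @export
default_taxonomy <- function(file = system.file("extdata",
                                                "taxonomy_default_synthetic.tsv",
                                                package = "grasprsa")) {
  tax <- utils::read.delim(file, stringsAsFactors = FALSE)
  validate_taxonomy(tax)
  tax
}

#' Validate a grasp taxonomy table
#'
#' Checks that every condition carries exactly one label under each scheme
#' and that the label inventories respect the scheme cardinalities
#' (at most 3 grasp types, 2 thumb positions, 7 object shapes).
#'
#' @param taxonomy data frame as returned by [default_taxonomy()].
#' @param n_conditions expected number of conditions (default: rows present).
#' @return the taxonomy, invisibly; errors on violation.
#' @export
validate_taxonomy <- function(taxonomy, n_conditions = nrow(taxonomy)) {
  need <- c("condition", "grasp_type", "thumb_position", "object_shape")
  miss <- setdiff(need, names(taxonomy))
  if (length(miss)) stopf("taxonomy missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(taxonomy$condition))
    stopf("taxonomy has duplicated condition ids")
  if (nrow(taxonomy) != n_conditions)
    stopf("taxonomy has %d conditions, expected %d", nrow(taxonomy),
          n_conditions)
  if (anyNA(taxonomy[need])) stopf("taxonomy contains missing labels")
  lim <- c(grasp_type = 3, thumb_position = 2, object_shape = 7)
  for (s in names(lim)) {
    k <- length(unique(taxonomy[[s]]))
    if (k > lim[[s]])
      stopf("scheme %s has %d labels, at most %d allowed", s, k, lim[[s]])
  }
  invisible(taxonomy)
}
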