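#' Write a session to a plain-text directory container
#'
#' Serializes a `grasp_recording` as one TSV per stream (`eeg.tsv`,
#' `eog.tsv`, `emg.tsv`, `accel.tsv`, `joints.tsv` with its timestamp
#' column, `events.tsv`, `truth_onsets.tsv`) plus a JSON manifest holding
#' the sampling rates and protocol counts.  Text-based on purpose: the
#' files are diffable and readable by any tool.
#'
#' @param recording a `grasp_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    t(m), file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = rownames(m) %||% paste0("ch", seq_len(nrow(m))))
  wm(recording$eeg, "eeg.tsv")
  wm(recording$eog, "eog.tsv")
  wm(recording$emg, "emg.tsv")
  wm(recording$accel, "accel.tsv")
  joints <- cbind(time = recording$joints$time, t(recording$joints$angles))
  utils::write.table(joints, file.path(dir, "joints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(recording$events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(recording$truth$onsets, file.path(dir,
                                                       "truth_onsets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(fs = recording$fs,
                   n_conditions = recording$protocol$n_conditions,
                   n_repetitions = recording$protocol$n_repetitions,
                   phase_durations = as.list(recording$protocol$phase_durations),
                   block_order = recording$protocol$block_order,
                   seed = recording$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing the session files.
#' @param layout,taxonomy optional layout and taxonomy to attach.
#' @return a `grasp_recording`.
#' @export
read_session <- function(dir, layout = NULL, taxonomy = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rm_ <- function(f) t(as.matrix(utils::read.delim(file.path(dir, f))))
  joints <- utils::read.delim(file.path(dir, "joints.tsv"))
  protocol <- generate_protocol(manifest$n_conditions,
                                manifest$n_repetitions, seed = NULL)
  # restore the recorded block order and schedule
  protocol$block_order <- manifest$block_order
  protocol$trials$condition <- rep(manifest$block_order,
                                   each = manifest$n_repetitions)
  truth <- utils::read.delim(file.path(dir, "truth_onsets.tsv"))
  structure(list(
    eeg = rm_("eeg.tsv"), eog = rm_("eog.tsv"), emg = rm_("emg.tsv"),
    joints = list(time = joints$time, angles = t(as.matrix(joints[-1]))),
    accel = rm_("accel.tsv"),
    events = utils::read.delim(file.path(dir, "events.tsv")),
    fs = manifest$fs, protocol = protocol, taxonomy = taxonomy,
    layout = layout,
    truth = list(onsets = truth), seed = manifest$seed),
    class = "grasp_recording")
}

#' Write an RDM as TSV with a JSON metadata sidecar
#'
#' @param rdm an `rdm` object.
#' @param file output TSV path; the sidecar is `<file>.json`.
#' @return `file`, invisibly.
#' @export
write_rdm <- function(rdm, file) {
  utils::write.table(unclass(rdm), file, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  jsonlite::write_json(list(source = attr(rdm, "source"),
                            window = attr(rdm, "window"),
                            scaling = attr(rdm, "scaling"),
                            n_conditions = nrow(rdm)),
                       paste0(file, ".json"), auto_unbox = TRUE, null = "null")
  invisible(file)
}

#' Write the per-trial QC report
#'
#' @param report rejection report data frame (see [reject_trials()]).
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
write_qc_report <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
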