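# Plain-text array container: a directory holding /eeg (CSV matrix),
# /envelope (CSV vector) and /meta (JSON), mirroring the usual
# one-group-per-signal layout of binary scientific containers while staying
# text-only and diff-able.

#' Write an EEG recording (and optional envelope) to a directory container
#'
#' @param eeg [eeg_recording()].
#' @param path directory to create.
#' @param envelope optional [speech_envelope()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_recording <- function(eeg, path, envelope = NULL) {
  stopifnot(inherits(eeg, "eeg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(t(eeg$data)), file.path(path, "eeg.csv"),
                   row.names = FALSE)
  meta <- list(sample_rate = eeg$sample_rate,
               channel_labels = eeg$channel_labels,
               subject_id = eeg$subject_id, age_group = eeg$age_group)
  if (!is.null(envelope)) {
    utils::write.csv(data.frame(envelope = envelope$samples),
                     file.path(path, "envelope.csv"), row.names = FALSE)
    meta$envelope_rate <- envelope$sample_rate
    meta$stimulus_id <- envelope$stimulus_id
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read an EEG recording container written by [write_recording()]
#'
#' @param path container directory.
#' @return list with `eeg` ([eeg_recording()]) and `envelope`
#'   ([speech_envelope()] or NULL).
#' @export
read_recording <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  dat <- t(as.matrix(utils::read.csv(file.path(path, "eeg.csv"))))
  eeg <- eeg_recording(dat, meta$sample_rate,
                       channel_labels = meta$channel_labels,
                       subject_id = meta$subject_id,
                       age_group = meta$age_group)
  env <- NULL
  env_path <- file.path(path, "envelope.csv")
  if (file.exists(env_path)) {
    env <- speech_envelope(utils::read.csv(env_path)$envelope,
                           meta$envelope_rate,
                           stimulus_id = meta$stimulus_id)
  }
  list(eeg = eeg, envelope = env)
}
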