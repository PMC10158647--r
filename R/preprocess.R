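#' Standard 28-channel montage labels
#'
#' The electrode subset common to both recording systems in the study design
#' this package supports.
#' @export
NTRACK_CHANNELS <- c("FP1", "FP2", "Fz", "F3", "F4", "F7", "F8",
                     "FC1", "FC2", "FC5", "FC6", "Cz", "C3", "C4",
                     "T7", "T8", "CP1", "CP2", "CP5", "CP6",
                     "Pz", "P3", "P4", "P7", "P8", "Oz", "O1", "O2")

#' Multichannel EEG recording container
#'
#' @param data channel x sample numeric matrix in microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels unique channel labels; defaults to the first
#'   `nrow(data)` entries of [NTRACK_CHANNELS].
#' @param subject_id,age_group optional metadata.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate,
                          channel_labels = NTRACK_CHANNELS[seq_len(nrow(data))],
                          subject_id = NA_character_, age_group = NA_character_) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stopf("EEG data must be finite")
  assert_scalar_num(sample_rate, "sample_rate", lower = 1e-9)
  if (length(channel_labels) != nrow(data)) stopf("one label per channel required")
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate = sample_rate,
                 channel_labels = channel_labels,
                 subject_id = subject_id, age_group = age_group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  invisible(x)
}

#' Zero-phase band-pass filter an EEG recording
#'
#' High-pass and low-pass are applied per channel as zero-phase 4th-order
#' Butterworth responses (frequency-domain realization, see
#' [fft_butterworth()]).
#'
#' @param eeg [eeg_recording()].
#' @param hp high-pass cutoff in Hz (default 0.1).
#' @param lp low-pass cutoff in Hz (default 45).
#' @return filtered [eeg_recording()].
#' @export
bandpass <- function(eeg, hp = 0.1, lp = 45) {
  stopifnot(inherits(eeg, "eeg_recording"))
  nyq <- eeg$sample_rate / 2
  if (lp >= nyq) stopf("low-pass cutoff must be below Nyquist (%g Hz)", nyq)
  if (hp <= 0 || hp >= lp) stopf("need 0 < hp < lp")
  out <- t(apply(eeg$data, 1, function(ch) {
    fft_butterworth(fft_butterworth(ch, eeg$sample_rate, lp, "low"),
                    eeg$sample_rate, hp, "high")
  }))
  eeg$data <- out
  rownames(eeg$data) <- eeg$channel_labels
  eeg
}

#' Cut paired EEG/envelope epochs with a sliding window
#'
#' Windows tile each contiguous valid span of the aligned envelope track
#' independently (no epoch crosses a presentation boundary), anchored at the
#' span start, with step `window_s * (1 - overlap)`. A span of duration `T`
#' seconds yields `floor((T - window_s) / step) + 1` epochs.
#'
#' @param eeg [eeg_recording()].
#' @param env_track aligned track from [align_envelope()].
#' @param window_s epoch length in seconds (default 3).
#' @param overlap fractional overlap between successive windows (default 2/3).
#' @return object of class `epoch_set`: `eeg_epochs` (epoch x channel x
#'   sample), `env_epochs` (epoch x sample), `keep_mask`, `start_sample`,
#'   metadata.
#' @export
make_epochs <- function(eeg, env_track, window_s = 3, overlap = 2 / 3) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(env_track, "envelope_track"))
  fs <- eeg$sample_rate
  win <- round(window_s * fs)
  step <- round(window_s * (1 - overlap) * fs)
  if (step < 1) stopf("overlap too close to 1 for this sampling rate")
  spans <- env_track$spans
  starts <- integer(0)
  for (i in seq_len(nrow(spans))) {
    span_len <- spans[i, "end"] - spans[i, "start"] + 1L
    if (span_len < win) {
      warning(sprintf("span %d (%.2f s) shorter than the %g s window; skipped",
                      i, span_len / fs, window_s))
      next
    }
    k <- floor((span_len - win) / step) + 1L
    starts <- c(starts, spans[i, "start"] + step * (seq_len(k) - 1L))
  }
  n_ep <- length(starts)
  if (n_ep == 0L) stopf("no span long enough for a single epoch")
  n_ch <- nrow(eeg$data)
  eeg_epochs <- array(NA_real_, c(n_ep, n_ch, win))
  env_epochs <- matrix(NA_real_, n_ep, win)
  for (e in seq_len(n_ep)) {
    idx <- starts[e]:(starts[e] + win - 1L)
    eeg_epochs[e, , ] <- eeg$data[, idx]
    env_epochs[e, ] <- env_track$track[idx]
  }
  structure(list(eeg_epochs = eeg_epochs, env_epochs = env_epochs,
                 sample_rate = fs, window_s = window_s, step_s = step / fs,
                 keep_mask = rep(TRUE, n_ep), start_sample = starts,
                 channel_labels = eeg$channel_labels,
                 subject_id = eeg$subject_id, age_group = eeg$age_group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set %s: %d epochs (%d kept) x %d ch x %g s @ %g Hz>\n",
              x$subject_id, length(x$keep_mask), sum(x$keep_mask),
              dim(x$eeg_epochs)[2], x$window_s, x$sample_rate))
  invisible(x)
}

#' Amplitude-based automatic artifact rejection
#'
#' Epochs are demeaned per epoch and channel, then an epoch is dropped iff
#' any channel sample exceeds the threshold. Under the default `"absolute"`
#' rule the criterion is absolute demeaned amplitude > `threshold`; the
#' `"peak_to_peak"` alternative drops epochs whose within-epoch range on any
#' channel exceeds `2 * threshold`.
#'
#' @param epochs [make_epochs()] output.
#' @param threshold amplitude criterion in microvolts (default 150).
#' @param rule rejection convention (see above).
#' @param demean store the demeaned epochs (default TRUE; demeaning precedes
#'   thresholding either way).
#' @return `epoch_set` with `keep_mask` updated (epochs are retained in the
#'   object).
#' @export
reject_artifacts <- function(epochs, threshold = 150,
                             rule = c("absolute", "peak_to_peak"),
                             demean = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  rule <- match.arg(rule)
  n_ep <- dim(epochs$eeg_epochs)[1]
  keep <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    x <- epochs$eeg_epochs[e, , , drop = FALSE]
    dim(x) <- dim(epochs$eeg_epochs)[2:3]
    x <- x - rowMeans(x)
    keep[e] <- if (rule == "absolute") max(abs(x)) <= threshold
               else max(apply(x, 1, function(r) diff(range(r)))) <= 2 * threshold
    if (demean) epochs$eeg_epochs[e, , ] <- x
  }
  epochs$keep_mask <- epochs$keep_mask & keep
  epochs
}

#' Re-reference epochs to the common average of all electrodes
#'
#' Subtracts the across-channel mean at every sample of every epoch, so the
#' channel mean is exactly zero everywhere. Idempotent.
#'
#' @param epochs `epoch_set` with at least two channels.
#' @return re-referenced `epoch_set`.
#' @export
rereference_common_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ch <- dim(epochs$eeg_epochs)[2]
  if (n_ch < 2) stopf("common-average reference needs >= 2 channels")
  means <- apply(epochs$eeg_epochs, c(1, 3), mean)  # epoch x sample
  epochs$eeg_epochs <- epochs$eeg_epochs -
    aperm(array(means, c(dim(means), n_ch)), c(1, 3, 2))
  epochs
}

#' Choose one session per subject and apply the inclusion rule
#'
#' Given cleaned epoch sets from one subject's sessions, returns the one
#' with more artifact-free epochs (ties go to the earlier age, in list
#' order), or `NULL` when even the best session has fewer than `min_epochs`
#' kept epochs (the subject is excluded).
#'
#' @param sessions list of `epoch_set`s, ordered youngest first.
#' @param min_epochs inclusive minimum of kept epochs (default 30).
#' @return the selected `epoch_set` with attribute `"selected"` (index), or
#'   `NULL` for an excluded subject.
#' @export
select_session <- function(sessions, min_epochs = 30) {
  if (!length(sessions)) stopf("at least one session is required")
  kept <- vapply(sessions, function(s) sum(s$keep_mask), integer(1))
  best <- which.max(kept)   # ties resolve to the earliest (youngest) session
  if (kept[best] < min_epochs) {
    message(sprintf("subject excluded: best session has %d < %d clean epochs",
                    kept[best], min_epochs))
    return(NULL)
  }
  if (sum(kept == kept[best]) > 1L)
    message("session tie on clean-epoch count; keeping the younger session")
  out <- sessions[[best]]
  attr(out, "selected") <- best
  out
}
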