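#' Analysis frequency grid
#'
#' 3-s epochs give an intrinsic resolution of 1/3 Hz; the analysis grid runs
#' from 1 to 15 Hz, i.e., bins k/3 for k = 3..45 (43 bins).
#'
#' @param window_s epoch length in seconds (default 3).
#' @param fmin,fmax grid limits in Hz.
#' @return numeric vector of bin frequencies in Hz.
#' @export
coherence_freqs <- function(window_s = 3, fmin = 1, fmax = 15) {
  df <- 1 / window_s
  k <- seq(ceiling(fmin / df - 1e-9), floor(fmax / df + 1e-9))
  k * df
}

#' Per-epoch Fourier spectra of EEG channels and envelope
#'
#' Kept epochs are demeaned, tapered (single Hann by default), and
#' transformed without zero padding; coefficients are returned on the
#' 1-15 Hz grid.
#'
#' @param epochs `epoch_set` (kept epochs are used).
#' @param taper `"hann"` (default) or `"boxcar"`.
#' @param fmin,fmax analysis band limits in Hz.
#' @return object of class `epoch_spectra`: `eeg` (epoch x channel x bin
#'   complex array), `env` (epoch x bin complex matrix), `freqs`, metadata.
#' @export
epoch_spectra <- function(epochs, taper = c("hann", "boxcar"),
                          fmin = 1, fmax = 15) {
  stopifnot(inherits(epochs, "epoch_set"))
  taper <- match.arg(taper)
  keep <- which(epochs$keep_mask)
  if (!length(keep)) stopf("no kept epochs")
  n <- dim(epochs$eeg_epochs)[3]
  if (abs(n / epochs$sample_rate - epochs$window_s) > 1e-9)
    stopf("epoch length does not match the stated window")
  freqs <- coherence_freqs(epochs$window_s, fmin, fmax)
  bin_idx <- round(freqs * epochs$window_s) + 1L  # 1-based FFT bin index
  w <- taper_window(n, taper)
  n_ch <- dim(epochs$eeg_epochs)[2]
  X <- array(complex(real = 0), c(length(keep), n_ch, length(freqs)))
  Y <- matrix(complex(real = 0), length(keep), length(freqs))
  for (i in seq_along(keep)) {
    e <- keep[i]
    for (c in seq_len(n_ch)) {
      x <- epochs$eeg_epochs[e, c, ]
      X[i, c, ] <- stats::fft((x - mean(x)) * w)[bin_idx]
    }
    y <- epochs$env_epochs[e, ]
    Y[i, ] <- stats::fft((y - mean(y)) * w)[bin_idx]
  }
  structure(list(eeg = X, env = Y, freqs = freqs,
                 channel_labels = epochs$channel_labels,
                 subject_id = epochs$subject_id, age_group = epochs$age_group),
            class = "epoch_spectra")
}

coh_from_sums <- function(Sxy, Sxx, Syy, squared = FALSE) {
  denom <- sqrt(Sxx * Syy)
  coh <- matrix(0, nrow(Sxy), ncol(Sxy))
  ok <- denom > 0
  coh[ok] <- Mod(Sxy[ok]) / denom[ok]
  coh <- pmin(coh, 1)
  if (squared) coh <- coh^2
  coh
}

#' Speech-brain magnitude coherence over epochs
#'
#' For each channel and frequency bin, the cross-spectrum summed over epochs
#' is normalized by the summed power spectra:
#' `Coh = |sum_e X conj(Y)| / sqrt(sum_e |X|^2 * sum_e |Y|^2)`.
#' Values lie in `[0, 1]`; bins with zero power in either signal are defined
#' as 0 (and counted in the `"zero_power_bins"` attribute).
#'
#' @param spectra [epoch_spectra()] output.
#' @param squared return magnitude-squared coherence instead (default FALSE;
#'   the magnitude convention follows the normalization formula used
#'   downstream).
#' @return object of class `coherence_spectrum` with `values` (channel x
#'   frequency matrix), `freqs`, `n_epochs`, metadata.
#' @export
coherence_spectrum <- function(spectra, squared = FALSE) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  n_ep <- dim(spectra$eeg)[1]
  if (n_ep < 1) stopf("at least one epoch is required")
  # explicit loops over channels keep the complex bookkeeping transparent
  n_ch <- dim(spectra$eeg)[2]; n_f <- dim(spectra$eeg)[3]
  Sxy <- matrix(complex(real = 0), n_ch, n_f)
  Sxx <- matrix(0, n_ch, n_f)
  for (c in seq_len(n_ch)) {
    Xc <- spectra$eeg[, c, , drop = TRUE]
    if (is.null(dim(Xc))) Xc <- matrix(Xc, nrow = n_ep)
    Sxy[c, ] <- colSums(Xc * Conj(spectra$env))
    Sxx[c, ] <- colSums(Mod(Xc)^2)
  }
  Syy <- matrix(colSums(Mod(spectra$env)^2), n_ch, n_f, byrow = TRUE)
  values <- coh_from_sums(Sxy, Sxx, Syy, squared)
  dimnames(values) <- list(spectra$channel_labels, sprintf("%.2f", spectra$freqs))
  structure(list(values = values, freqs = spectra$freqs, n_epochs = n_ep,
                 subject_id = spectra$subject_id, age_group = spectra$age_group,
                 squared = squared,
                 zero_power_bins = sum(Sxx == 0 | Syy == 0)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<coherence_spectrum %s: %d ch x %d bins ",
                     "(%.2f-%.2f Hz), %d epochs, mean %.3f>\n"),
              x$subject_id, nrow(x$values), ncol(x$values),
              min(x$freqs), max(x$freqs), x$n_epochs, mean(x$values)))
  invisible(x)
}

#' @export
plot.coherence_spectrum <- function(x, ...) {
  graphics::matplot(x$freqs, t(x$values), type = "l", lty = 1,
                    col = grDevices::grey(0.6, 0.5),
                    xlab = "Frequency (Hz)", ylab = "Coherence", ...)
  graphics::lines(x$freqs, colMeans(x$values), lwd = 2)
  invisible(x)
}

#' Surrogate coherence via envelope-epoch shuffling
#'
#' Destroys the true epoch pairing by permuting envelope epochs against fixed
#' EEG epochs; the identity permutation is re-drawn. The element-wise mean
#' coherence over `n_shuffles` permutations estimates the chance/bias level
#' of the estimator at the subject's epoch count.
#'
#' @param spectra [epoch_spectra()] output with >= 2 kept epochs.
#' @param n_shuffles number of random pairings (default 100).
#' @param seed RNG seed.
#' @param squared as in [coherence_spectrum()].
#' @return `coherence_spectrum` of the mean surrogate.
#' @export
surrogate_coherence <- function(spectra, n_shuffles = 100, seed = NULL,
                                squared = FALSE) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  n_ep <- dim(spectra$eeg)[1]
  if (n_ep < 2) stopf("shuffling needs at least 2 epochs")
  n_ch <- dim(spectra$eeg)[2]; n_f <- dim(spectra$eeg)[3]
  Sxx <- matrix(0, n_ch, n_f)
  Xc_list <- vector("list", n_ch)
  for (c in seq_len(n_ch)) {
    Xc <- spectra$eeg[, c, , drop = TRUE]
    if (is.null(dim(Xc))) Xc <- matrix(Xc, nrow = n_ep)
    Xc_list[[c]] <- Xc
    Sxx[c, ] <- colSums(Mod(Xc)^2)
  }
  Syy_vec <- colSums(Mod(spectra$env)^2)
  Syy <- matrix(Syy_vec, n_ch, n_f, byrow = TRUE)
  acc <- matrix(0, n_ch, n_f)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      repeat {
        perm <- sample.int(n_ep)
        if (!all(perm == seq_len(n_ep))) break
      }
      Yp <- Conj(spectra$env[perm, , drop = FALSE])
      Sxy <- matrix(complex(real = 0), n_ch, n_f)
      for (c in seq_len(n_ch)) Sxy[c, ] <- colSums(Xc_list[[c]] * Yp)
      acc <- acc + coh_from_sums(Sxy, Sxx, Syy, squared)
    }
  })
  values <- acc / n_shuffles
  dimnames(values) <- list(spectra$channel_labels, sprintf("%.2f", spectra$freqs))
  structure(list(values = values, freqs = spectra$freqs, n_epochs = n_ep,
                 subject_id = spectra$subject_id, age_group = spectra$age_group,
                 squared = squared, n_shuffles = n_shuffles,
                 zero_power_bins = sum(Sxx == 0 | Syy == 0)),
            class = "coherence_spectrum")
}

#' Epoch-count-bias normalization of observed against surrogate coherence
#'
#' `(obs - surr) / (obs + surr)` element-wise, in `(-1, 1]`. Cells where
#' `obs + surr` is zero are undefined; they are returned as 0 and counted in
#' the `"flagged"` attribute.
#'
#' @param obs,surr `coherence_spectrum` objects of matching shape.
#' @return channel x frequency matrix of normalized coherence with
#'   attributes `freqs` and `flagged`.
#' @export
normalize_coherence <- function(obs, surr) {
  stopifnot(inherits(obs, "coherence_spectrum"),
            inherits(surr, "coherence_spectrum"))
  if (!all(dim(obs$values) == dim(surr$values)))
    stopf("observed and surrogate spectra have different shapes")
  denom <- obs$values + surr$values
  out <- matrix(0, nrow(denom), ncol(denom), dimnames = dimnames(obs$values))
  ok <- denom > 0
  out[ok] <- (obs$values[ok] - surr$values[ok]) / denom[ok]
  attr(out, "freqs") <- obs$freqs
  attr(out, "flagged") <- sum(!ok)
  if (any(!ok)) warning(sprintf("%d zero-denominator cells set to 0", sum(!ok)))
  out
}

#' Rate-band definitions on the analysis grid
#'
#' Stressed-syllable 1-3 Hz (closed), syllable (3,5] Hz, phonological
#' (5,15] Hz: each bin belongs to exactly one band; the 3.00 Hz bin goes to
#' the stressed band and the 5.00 Hz bin to the syllable band.
#' @export
NTRACK_BANDS <- list(stressed = c(1, 3), syllable = c(3, 5),
                     phonological = c(5, 15))

band_bins <- function(freqs, bands = NTRACK_BANDS) {
  lapply(seq_along(bands), function(i) {
    lo <- bands[[i]][1]; hi <- bands[[i]][2]
    if (i == 1) which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9)
    else which(freqs > lo + 1e-9 & freqs <= hi + 1e-9)
  }) |> stats::setNames(names(bands))
}

#' Electrode- and bin-averaged normalized coherence per rate band
#'
#' Unweighted mean of the normalized channel x frequency matrix over all
#' electrodes and the band's bins, yielding one value per band per subject.
#'
#' @param norm_spectrum matrix from [normalize_coherence()] (attribute
#'   `freqs` required, or pass `freqs`).
#' @param freqs frequency grid in Hz (defaults to the attribute).
#' @param bands named list of band limits (default [NTRACK_BANDS]).
#' @return one-row data.frame with `norm_<band>` columns.
#' @export
band_average <- function(norm_spectrum, freqs = attr(norm_spectrum, "freqs"),
                         bands = NTRACK_BANDS) {
  if (is.null(freqs)) stopf("frequency grid is required")
  bins <- band_bins(freqs, bands)
  out <- lapply(bins, function(ix) mean(norm_spectrum[, ix, drop = FALSE]))
  stats::setNames(as.data.frame(out), paste0("norm_", names(bands)))
}
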