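#' Specification of a nursery-rhyme-like amplitude envelope
#'
#' The envelope is a sum of jittered periodic raised-cosine bump trains, one
#' per modulation rate, around a unit baseline. With zero jitter a component
#' is an exact raised cosine at its center frequency (Hann bumps of width
#' `1/f` at spacing `1/f` overlap-add to `0.5 - 0.5*cos(2*pi*f*t)`), so the
#' modulation spectrum has a clean peak at the requested rate; jitter smears
#' the peaks into quasi-rhythmic bands like sung nursery rhymes.
#'
#' Default components emulate stressed syllables (~2 Hz, deep modulation),
#' syllables (~4 Hz) and phonemes (~10 Hz, shallower).
#'
#' @param duration_s duration in seconds (> 0).
#' @param rate_components data.frame with columns `freq` (Hz), `depth`
#'   (modulation depth, 0-1), `jitter` (per-event timing SD as a fraction of
#'   the period, 0-1).
#' @param sample_rate envelope sampling rate in Hz (default 500); must be at
#'   least 8x the highest component frequency.
#' @param seed RNG seed for the jitter.
#' @return object of class `envelope_spec`.
#' @export
envelope_spec <- function(duration_s = 69,
                          rate_components = data.frame(
                            freq = c(2, 4, 10),
                            depth = c(0.9, 0.6, 0.4),
                            jitter = c(0.1, 0.1, 0.1)),
                          sample_rate = 500, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  rc <- as.data.frame(rate_components)
  if (!all(c("freq", "depth", "jitter") %in% names(rc)))
    stopf("rate_components needs columns freq, depth, jitter")
  if (any(rc$depth < 0 | rc$depth > 1)) stopf("depths must lie in [0, 1]")
  if (any(rc$jitter < 0 | rc$jitter > 1)) stopf("jitter fractions must lie in [0, 1]")
  if (any(rc$freq <= 0)) stopf("component frequencies must be positive")
  if (sample_rate < 2 * max(rc$freq) * 4)
    stopf("sample_rate must be >= 8x the highest component frequency")
  structure(list(duration_s = duration_s, rate_components = rc,
                 sample_rate = sample_rate, seed = seed),
            class = "envelope_spec")
}

#' Generate a synthetic nursery-rhyme envelope
#'
#' @param spec [envelope_spec()].
#' @return [speech_envelope()]; non-negative, deterministic given the seed,
#'   with modulation-spectrum maxima inside each requested rate band.
#' @export
generate_envelope <- function(spec) {
  stopifnot(inherits(spec, "envelope_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration_s * fs)
  env <- rep(1, n)
  with_seed(spec$seed, {
    for (i in seq_len(nrow(spec$rate_components))) {
      f <- spec$rate_components$freq[i]
      depth <- spec$rate_components$depth[i]
      jit <- spec$rate_components$jitter[i]
      if (depth == 0) next
      period <- 1 / f
      # renewal timing: each inter-event interval gets Gaussian noise, so
      # the rhythm's phase drifts like a natural performance rather than
      # staying locked to a metronomic grid
      n_ev <- ceiling(spec$duration_s * f) + 3L
      ivals <- pmax(period + stats::rnorm(n_ev, 0, jit * period), 0.3 * period)
      times <- -period + cumsum(ivals)
      train <- numeric(n)
      half <- period / 2
      for (t0 in times) {
        i0 <- max(1L, ceiling((t0 - half) * fs) + 1L)
        i1 <- min(n, floor((t0 + half) * fs) + 1L)
        if (i0 > i1) next
        tt <- (seq(i0, i1) - 1) / fs
        train[i0:i1] <- train[i0:i1] + 0.5 * (1 + cos(pi * (tt - t0) / half))
      }
      env <- env + depth * (train - mean(train))
    }
  })
  speech_envelope(pmax(env, 0), fs, stimulus_id = "synthetic-rhyme")
}

#' Synthesize broadband audio carrying a given envelope
#'
#' Multiplies a Gaussian broadband carrier by the envelope; useful for
#' exercising [compute_envelope()] end-to-end.
#'
#' @param env [speech_envelope()].
#' @param audio_rate output audio rate in Hz (default 8000).
#' @param seed RNG seed for the carrier.
#' @return list with `samples` (scaled to max |x| = 0.9) and `sample_rate`.
#' @export
synthesize_audio <- function(env, audio_rate = 8000, seed = 1L) {
  stopifnot(inherits(env, "speech_envelope"))
  n <- round(length(env$samples) / env$sample_rate * audio_rate)
  e <- stats::approx(seq_along(env$samples) / env$sample_rate,
                     env$samples, xout = seq_len(n) / audio_rate,
                     rule = 2)$y
  x <- with_seed(seed, stats::rnorm(n)) * e
  list(samples = 0.9 * x / max(abs(x)), sample_rate = audio_rate)
}

#' Specification of a synthetic subject
#'
#' Forward model for one infant's EEG: each channel is the sum of
#' band-limited, delayed copies of the stimulus envelope (one per rate band,
#' scaled by the subject's per-band tracking gain, in microvolts RMS per
#' band), 1/f background noise, and occasional high-amplitude half-sine
#' artifact bursts.
#'
#' @param subject_id token.
#' @param likelihood_group `"HL"` or `"LL"`.
#' @param age_group `"10m"` or `"14m"`.
#' @param g_stressed,g_syllable,g_phonological per-band tracking gains
#'   (microvolts RMS of the locked component; >= 0).
#' @param noise_level background 1/f noise level in microvolts RMS
#'   (default 15).
#' @param artifact_rate expected artifact bursts per minute (default 2).
#' @param n_channels number of channels (default 28).
#' @param eeg_rate sampling rate in Hz (default 500; must exceed 90 so the
#'   45 Hz low-pass is representable).
#' @param delay_s envelope-to-EEG lag in seconds (default 0.06).
#' @param seed RNG seed.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "S01", likelihood_group = c("HL", "LL"),
                         age_group = c("10m", "14m"),
                         g_stressed = 0, g_syllable = 0, g_phonological = 0,
                         noise_level = 15, artifact_rate = 2,
                         n_channels = 28, eeg_rate = 500,
                         delay_s = 0.06, seed = 1L) {
  likelihood_group <- match.arg(likelihood_group)
  age_group <- match.arg(age_group)
  for (g in c(g_stressed, g_syllable, g_phonological))
    if (g < 0) stopf("tracking gains must be >= 0")
  if (noise_level < 0) stopf("noise_level must be >= 0")
  if (artifact_rate < 0) stopf("artifact_rate must be >= 0")
  if (n_channels < 1) stopf("n_channels must be >= 1")
  if (eeg_rate <= 90) stopf("eeg_rate must exceed 90 Hz")
  structure(list(subject_id = subject_id, likelihood_group = likelihood_group,
                 age_group = age_group,
                 gains = c(stressed = g_stressed, syllable = g_syllable,
                           phonological = g_phonological),
                 noise_level = noise_level, artifact_rate = artifact_rate,
                 n_channels = n_channels, eeg_rate = eeg_rate,
                 delay_s = delay_s, seed = seed),
            class = "subject_spec")
}

# Deterministic source topography for the forward model: a fronto-occipital
# gradient over the montage positions (normalized to max |w| = 1). A varying
# topography is required for the locked component to survive common-average
# re-referencing, as any real scalp projection would.
channel_weights <- function(n_channels) {
  pos <- ntrack_channel_positions()
  w <- pos[match(toupper(NTRACK_CHANNELS[seq_len(n_channels)]),
                 toupper(rownames(pos))), "y"]
  if (any(!is.finite(w)) || max(abs(w)) == 0 ||
      (n_channels > 1 && stats::sd(w) == 0))
    w <- rep_len(c(1, -1), n_channels)
  unname(w / max(abs(w)))
}

# 1/f^alpha noise with unit RMS, via spectral shaping of white noise.
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  g <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Poisson-timed half-sine bursts, 200-400 uV, 100-300 ms, on one random
# channel each. Returns the data with bursts added and the burst intervals.
add_artifacts <- function(data, fs, rate_per_min) {
  n_ch <- nrow(data); n <- ncol(data)
  n_burst <- stats::rpois(1, rate_per_min * n / fs / 60)
  intervals <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  for (b in seq_len(n_burst)) {
    dur <- round(stats::runif(1, 0.1, 0.3) * fs)
    amp <- stats::runif(1, 200, 400) * sample(c(-1, 1), 1)
    start <- sample.int(max(1L, n - dur), 1)
    ch <- sample.int(n_ch, 1)
    idx <- start:(start + dur - 1L)
    data[ch, idx] <- data[ch, idx] + amp * sin(pi * seq_along(idx) / dur)
    intervals <- rbind(intervals, c(start, start + dur - 1L))
  }
  list(data = data, bursts = intervals)
}

#' Generate one subject's EEG for an aligned envelope track
#'
#' @param env_track either a [speech_envelope()] (one presentation starting
#'   at sample 1) or an `envelope_track` from [align_envelope()]-style
#'   placement (fields `track`, `valid`); must be at the subject's EEG rate.
#' @param subj [subject_spec()].
#' @param resample resample the envelope to `subj$eeg_rate` when rates
#'   differ (default FALSE: a mismatch is an error).
#' @return [eeg_recording()] with attributes `"bursts"` (planted artifact
#'   intervals) and `"track"` (the envelope track used in the forward
#'   model).
#' @export
generate_subject_eeg <- function(env_track, subj, resample = FALSE) {
  stopifnot(inherits(subj, "subject_spec"))
  fs <- subj$eeg_rate
  if (inherits(env_track, "speech_envelope")) {
    if (abs(env_track$sample_rate - fs) > 1e-9) {
      if (!resample) stopf("envelope rate %g != EEG rate %g (set resample = TRUE)",
                           env_track$sample_rate, fs)
      frac <- gcd_int(round(fs), round(env_track$sample_rate))
      env_track <- speech_envelope(
        pmax(signal::resample(env_track$samples, round(fs) / frac,
                              round(env_track$sample_rate) / frac), 0),
        fs, env_track$stimulus_id)
    }
    track <- env_track$samples
  } else if (inherits(env_track, "envelope_track")) {
    if (abs(env_track$sample_rate - fs) > 1e-9)
      stopf("aligned track rate %g != EEG rate %g", env_track$sample_rate, fs)
    track <- env_track$track
    track[!env_track$valid] <- mean(track[env_track$valid])
  } else stopf("env_track must be a speech_envelope or envelope_track")
  n <- length(track)
  lag <- round(subj$delay_s * fs)
  delayed <- c(rep(track[1], lag), track)[seq_len(n)]
  centered <- delayed - mean(delayed)
  sig <- numeric(n)
  for (b in names(NTRACK_BANDS)) {
    g <- subj$gains[[b]]
    if (g <= 0) next
    comp <- fft_butterworth(centered, fs, NTRACK_BANDS[[b]], type = "band")
    s <- stats::sd(comp)
    if (s > 0) sig <- sig + g * comp / s
  }
  w <- channel_weights(subj$n_channels)
  out <- with_seed(subj$seed, {
    data <- matrix(0, subj$n_channels, n)
    for (c in seq_len(subj$n_channels))
      data[c, ] <- w[c] * sig + subj$noise_level * pink_noise(n)
    add_artifacts(data, fs, subj$artifact_rate)
  })
  rec <- eeg_recording(out$data, fs,
                       channel_labels = NTRACK_CHANNELS[seq_len(subj$n_channels)],
                       subject_id = subj$subject_id, age_group = subj$age_group)
  attr(rec, "bursts") <- out$bursts
  attr(rec, "track") <- track
  rec
}

#' Linear behavioral-outcome model for the synthetic cohort
#'
#' Vocabulary percentiles are drawn as
#' `intercept + slope*T + age_interaction*T*age + group_interaction*T*group
#' + N(0, residual_sd)`, clipped to `[0, 100]`, where `T` is the subject's
#' stressed-band tracking strength and age/group are coded 10m = 0 / 14m = 1
#' and LL = 0 / HL = 1. Autism comparison scores are integers 1-10,
#' independent of tracking by default (`ados_slope = 0`).
#'
#' @param intercept percentile at zero tracking (default 25).
#' @param slope_stressed percentile units per unit tracking strength
#'   (default 25).
#' @param age_interaction,group_interaction interaction slopes (defaults
#'   -15 and -10).
#' @param residual_sd residual SD in percentile units (default 25; >= 0).
#' @param ados_slope optional coupling of ADOS scores to tracking
#'   (default 0).
#' @return object of class `behavior_model`.
#' @export
behavior_model <- function(intercept = 25, slope_stressed = 25,
                           age_interaction = -15, group_interaction = -10,
                           residual_sd = 25, ados_slope = 0) {
  if (residual_sd < 0) stopf("residual_sd must be >= 0")
  structure(list(intercept = intercept, slope_stressed = slope_stressed,
                 age_interaction = age_interaction,
                 group_interaction = group_interaction,
                 residual_sd = residual_sd, ados_slope = ados_slope),
            class = "behavior_model")
}

#' Generate a synthetic cohort table (and optionally recordings)
#'
#' Subjects fill all four likelihood x age cells. Per-band tracking
#' strengths are drawn from a truncated normal (mean `gain_mean`, SD
#' `gain_sd`, floored at 0); vocabulary outcomes follow the
#' [behavior_model()] on the true stressed-band strength. When EEG is not
#' simulated the `norm_*` columns carry the true per-band tracking
#' strengths (an idealized noise-free tracking measurement); with
#' `simulate_eeg = TRUE` per-subject recordings are returned so the measured
#' coherence pipeline can replace them.
#'
#' @param n_per_cell subjects per cell; a single count or a length-4 vector
#'   in the order HL/10m, LL/10m, HL/14m, LL/14m.
#' @param behavior [behavior_model()].
#' @param envelope_spec [envelope_spec()] (used when `simulate_eeg = TRUE`).
#' @param seed master RNG seed.
#' @param gain_mean,gain_sd tracking-strength distribution (defaults 1, 0.4).
#' @param simulate_eeg also generate per-subject EEG (default FALSE).
#' @param subject_args extra arguments passed to [subject_spec()] when
#'   simulating EEG (e.g., `noise_level`, `n_channels`, `eeg_rate`).
#' @return data.frame of class `cohort_table` (columns `subject_id`,
#'   `likelihood_group`, `age_group`, `norm_stressed`, `norm_syllable`,
#'   `norm_phonological`, `cdi_receptive_pct`, `cdi_productive_pct`,
#'   `ados_comparison`); with `simulate_eeg = TRUE` the recordings are in
#'   attribute `"recordings"` and the stimulus envelope in `"envelope"`.
#' @export
generate_cohort <- function(n_per_cell, behavior = behavior_model(),
                            envelope_spec = NULL, seed = 1L,
                            gain_mean = 1, gain_sd = 0.4,
                            simulate_eeg = FALSE, subject_args = list()) {
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, 4)
  if (length(n_per_cell) != 4L || any(n_per_cell < 1))
    stopf("n_per_cell must be one count or four counts >= 1")
  cells <- data.frame(likelihood_group = c("HL", "LL", "HL", "LL"),
                      age_group = c("10m", "10m", "14m", "14m"))
  tab <- cells[rep(seq_len(4), times = n_per_cell), ]
  n <- nrow(tab)
  tab$subject_id <- sprintf("S%03d", seq_len(n))
  tab <- tab[, c("subject_id", "likelihood_group", "age_group")]
  rownames(tab) <- NULL
  tab <- with_seed(seed, {
    draw_gain <- function(n) pmax(stats::rnorm(n, gain_mean, gain_sd), 0)
    tab$norm_stressed <- draw_gain(n)
    tab$norm_syllable <- draw_gain(n)
    tab$norm_phonological <- draw_gain(n)
    age01 <- as.integer(tab$age_group == "14m")
    grp01 <- as.integer(tab$likelihood_group == "HL")
    mu <- behavior$intercept +
      behavior$slope_stressed * tab$norm_stressed +
      behavior$age_interaction * tab$norm_stressed * age01 +
      behavior$group_interaction * tab$norm_stressed * grp01
    clip <- function(x) pmin(100, pmax(0, x))
    tab$cdi_receptive_pct <- clip(mu + stats::rnorm(n, 0, behavior$residual_sd))
    tab$cdi_productive_pct <- clip(mu + stats::rnorm(n, 0, behavior$residual_sd))
    ados_mu <- 3 + behavior$ados_slope * tab$norm_stressed
    tab$ados_comparison <- pmin(10L, pmax(1L, as.integer(round(
      stats::rnorm(n, ados_mu, 2)))))
    tab
  })
  class(tab) <- c("cohort_table", "data.frame")
  if (simulate_eeg) {
    if (is.null(envelope_spec)) envelope_spec <- envelope_spec()
    env <- generate_envelope(envelope_spec)
    recs <- vector("list", n)
    names(recs) <- tab$subject_id
    for (i in seq_len(n)) {
      args <- c(list(subject_id = tab$subject_id[i],
                     likelihood_group = tab$likelihood_group[i],
                     age_group = tab$age_group[i],
                     g_stressed = tab$norm_stressed[i],
                     g_syllable = tab$norm_syllable[i],
                     g_phonological = tab$norm_phonological[i],
                     seed = derive_seed(seed, paste0("eeg-", i))),
                subject_args)
      subj <- do.call(subject_spec, args)
      recs[[i]] <- generate_subject_eeg(env, subj,
                                        resample = envelope_spec$sample_rate !=
                                          subj$eeg_rate)
    }
    attr(tab, "recordings") <- recs
    attr(tab, "envelope") <- env
  }
  tab
}
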