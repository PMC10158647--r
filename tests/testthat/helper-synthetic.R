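# Shared fixtures: a scaled-down single-subject pipeline (short stimulus,
# few channels, 125 Hz) used by the statistical property tests. All sizes
# are chosen so one subject takes well under 0.1 s.

fixture_envelope <- function(duration_s = 33, sample_rate = 125, seed = 777) {
  generate_envelope(envelope_spec(duration_s, sample_rate = sample_rate,
                                  seed = seed))
}

# Preprocess + spectra for one synthetic subject; returns the epoch spectra
# plus observed and surrogate coherence.
fixture_subject <- function(seed, g_stressed = 0, g_syllable = 0,
                            g_phonological = 0, noise_level = 10,
                            artifact_rate = 0, n_channels = 4,
                            duration_s = 33, fs = 125, n_shuffles = 100,
                            overlap = 2 / 3, env = NULL) {
  if (is.null(env)) env <- fixture_envelope(duration_s, fs)
  subj <- subject_spec("S", "HL", "10m", g_stressed = g_stressed,
                       g_syllable = g_syllable,
                       g_phonological = g_phonological,
                       noise_level = noise_level,
                       artifact_rate = artifact_rate,
                       n_channels = n_channels, eeg_rate = fs, seed = seed)
  blank <- eeg_recording(matrix(0, n_channels,
                                length(env$samples) + round(2 * fs)), fs)
  track <- align_envelope(env, blank, onsets = round(fs))
  rec <- bandpass(generate_subject_eeg(track, subj))
  ep <- make_epochs(rec, track, overlap = overlap)
  ep <- rereference_common_average(reject_artifacts(ep))
  sp <- epoch_spectra(ep)
  list(spectra = sp,
       obs = coherence_spectrum(sp),
       surr = surrogate_coherence(sp, n_shuffles, seed = seed + 5000L))
}

fixture_band_coherence <- function(...) {
  s <- fixture_subject(...)
  unlist(band_average(normalize_coherence(s$obs, s$surr)))
}

# Hand-built epoch_set from raw arrays, for unit tests that do not need the
# generator.
toy_epochs <- function(eeg_arr, env_mat, fs = 125, window_s = 3) {
  structure(list(eeg_epochs = eeg_arr, env_epochs = env_mat,
                 sample_rate = fs, window_s = window_s, step_s = 1,
                 keep_mask = rep(TRUE, dim(eeg_arr)[1]),
                 start_sample = seq_len(dim(eeg_arr)[1]),
                 channel_labels = NTRACK_CHANNELS[seq_len(dim(eeg_arr)[2])],
                 subject_id = "toy", age_group = "10m"),
            class = "epoch_set")
}

# Brute-force magnitude-coherence oracle: direct summation with scalar
# loops, independent of the package's vectorized path.
oracle_coherence <- function(X, Y) {
  n_ep <- dim(X)[1]; n_ch <- dim(X)[2]; n_f <- dim(X)[3]
  out <- matrix(0, n_ch, n_f)
  for (c in seq_len(n_ch)) for (f in seq_len(n_f)) {
    sxy <- 0 + 0i; sxx <- 0; syy <- 0
    for (e in seq_len(n_ep)) {
      sxy <- sxy + X[e, c, f] * Conj(Y[e, f])
      sxx <- sxx + Mod(X[e, c, f])^2
      syy <- syy + Mod(Y[e, f])^2
    }
    out[c, f] <- if (sxx > 0 && syy > 0) Mod(sxy) / sqrt(sxx * syy) else 0
  }
  out
}
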