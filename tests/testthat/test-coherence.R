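test_that("the analysis grid spans 1-15 Hz in 1/3 Hz steps", {
  fr <- coherence_freqs()
  expect_length(fr, 43)
  expect_equal(fr[1], 1)
  expect_equal(fr[43], 15)
  expect_equal(unique(round(diff(fr), 10)), round(1 / 3, 10))
})

test_that("epoch spectra concentrate an on-grid sinusoid and zero a constant", {
  fs <- 125
  t <- (0:(3 * fs - 1)) / fs
  arr <- array(0, c(2, 1, 3 * fs))
  arr[1, 1, ] <- sin(2 * pi * 2 * t)
  arr[2, 1, ] <- 5                       # constant epoch
  ep <- toy_epochs(arr, matrix(runif(2 * 3 * fs), 2), fs = fs)
  sp <- epoch_spectra(ep, taper = "boxcar")
  mags <- Mod(sp$eeg[1, 1, ])
  expect_equal(sp$freqs[which.max(mags)], 2)
  expect_gt(mags[sp$freqs == 2] / sum(mags), 0.99)
  expect_lt(max(Mod(sp$eeg[2, 1, ])), 1e-8)
})

test_that("coherence is 1 for identical signals and for a single epoch", {
  fs <- 125
  set.seed(3)
  n_ep <- 6
  env <- matrix(rnorm(n_ep * 3 * fs), n_ep)
  arr <- array(0, c(n_ep, 2, 3 * fs))
  arr[, 1, ] <- env
  arr[, 2, ] <- rnorm(n_ep * 3 * fs)
  sp <- epoch_spectra(toy_epochs(arr, env, fs = fs))
  coh <- coherence_spectrum(sp)
  expect_equal(unname(coh$values[1, ]), rep(1, 43), tolerance = 1e-10)

  ep1 <- toy_epochs(arr[1, , , drop = FALSE], env[1, , drop = FALSE], fs = fs)
  coh1 <- coherence_spectrum(epoch_spectra(ep1))
  expect_equal(unname(as.vector(coh1$values)), rep(1, 2 * 43), tolerance = 1e-10)
})

test_that("coherence matches a brute-force direct-summation oracle", {
  set.seed(9)
  fs <- 125
  arr <- array(rnorm(5 * 2 * 3 * fs), c(5, 2, 3 * fs))
  env <- matrix(rnorm(5 * 3 * fs), 5)
  sp <- epoch_spectra(toy_epochs(arr, env, fs = fs))
  ours <- coherence_spectrum(sp)$values
  oracle <- oracle_coherence(sp$eeg, sp$env)
  expect_equal(unname(ours), oracle, tolerance = 1e-12)
  expect_true(all(ours >= 0 & ours <= 1))
})

test_that("surrogate equals observed when all envelope epochs are identical", {
  set.seed(5)
  fs <- 125
  arr <- array(rnorm(8 * 2 * 3 * fs), c(8, 2, 3 * fs))
  env1 <- rnorm(3 * fs)
  env <- matrix(rep(env1, each = 8), 8)
  sp <- epoch_spectra(toy_epochs(arr, env, fs = fs))
  obs <- coherence_spectrum(sp)
  surr <- surrogate_coherence(sp, n_shuffles = 20, seed = 1)
  expect_equal(surr$values, obs$values, tolerance = 1e-12)
})

test_that("surrogate is deterministic given the seed and needs >= 2 epochs", {
  s <- fixture_subject(seed = 21)
  a <- surrogate_coherence(s$spectra, 25, seed = 42)
  b <- surrogate_coherence(s$spectra, 25, seed = 42)
  expect_identical(a$values, b$values)
  c <- surrogate_coherence(s$spectra, 25, seed = 43)
  expect_false(identical(a$values, c$values))

  fs <- 125
  one <- toy_epochs(array(rnorm(1 * 1 * 3 * fs), c(1, 1, 3 * fs)),
                    matrix(rnorm(3 * fs), 1), fs = fs)
  expect_error(surrogate_coherence(epoch_spectra(one)), "at least 2")
})

test_that("normalization follows (obs - surr)/(obs + surr)", {
  mk <- function(v) {
    structure(list(values = matrix(v, 2, 43), freqs = coherence_freqs(),
                   n_epochs = 10, subject_id = "x", age_group = "10m",
                   squared = FALSE), class = "coherence_spectrum")
  }
  expect_equal(unname(normalize_coherence(mk(0.6), mk(0.2))[1, 1]), 0.5)
  expect_true(all(normalize_coherence(mk(0.37), mk(0.37)) == 0))
  near1 <- normalize_coherence(mk(1), mk(1e-12))
  expect_gt(min(near1), 1 - 1e-9)
  bad <- mk(0.5); bad$values <- bad$values[, 1:10]
  expect_error(normalize_coherence(mk(0.5), bad), "shapes")
})

test_that("band averaging uses the 7/6/30 bin partition", {
  fr <- coherence_freqs()
  const <- matrix(0.3, 4, 43)
  attr(const, "freqs") <- fr
  ba <- band_average(const)
  expect_equal(unname(unlist(ba)), rep(0.3, 3))

  spike <- matrix(0, 4, 43)
  spike[, which(abs(fr - 2) < 1e-9)] <- 1
  attr(spike, "freqs") <- fr
  bs <- band_average(spike)
  expect_equal(bs$norm_stressed, 1 / 7)
  expect_equal(bs$norm_syllable, 0)
  expect_equal(bs$norm_phonological, 0)

  bins <- ntrack:::band_bins(fr)
  expect_identical(vapply(bins, length, integer(1)),
                   c(stressed = 7L, syllable = 6L, phonological = 30L))
  expect_identical(sort(unname(unlist(bins))), 1:43)
})

test_that("coherence approaches the analytic sqrt(SNR/(1+SNR)) limit", {
  # EEG epoch = alpha * envelope epoch + independent noise, both white, so
  # every bin has the same SNR = alpha^2 in expectation.
  set.seed(77)
  fs <- 125; n_ep <- 200; alpha <- 0.8
  snr <- alpha^2
  limit <- sqrt(snr / (1 + snr))
  reps <- vapply(1:8, function(r) {
    env <- matrix(rnorm(n_ep * 3 * fs), n_ep)
    arr <- array(alpha * env + rnorm(n_ep * 3 * fs), c(n_ep, 1, 3 * fs))
    sp <- epoch_spectra(toy_epochs(arr, env, fs = fs), taper = "boxcar")
    mean(coherence_spectrum(sp)$values)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - limit), 3 * se + 0.005)
})

test_that("coherence is invariant to envelope rescaling and a constant lag", {
  s <- fixture_subject(seed = 31, g_stressed = 3)
  sp <- s$spectra
  sp_scaled <- sp
  sp_scaled$env <- sp$env * 0.37         # global positive rescaling
  expect_equal(coherence_spectrum(sp_scaled)$values, s$obs$values,
               tolerance = 1e-12)

  # constant time lag multiplies every envelope bin by a unit phasor
  lagged <- sp
  phase <- exp(-2i * pi * sp$freqs * 0.05)
  lagged$env <- sweep(sp$env, 2, phase, `*`)
  expect_equal(coherence_spectrum(lagged)$values, s$obs$values,
               tolerance = 1e-12)
})

test_that("normalization removes the epoch-count bias of raw coherence", {
  # under independence raw coherence shrinks with epoch count, while the
  # normalized value stays centered; non-overlapping epochs keep the
  # pairing exchangeable so the surrogate is an unbiased chance level
  sub_norm <- function(seed, dur) {
    fixture_band_coherence(seed = seed, duration_s = dur, overlap = 0,
                           n_channels = 2, n_shuffles = 60)
  }
  set.seed(123)
  short <- vapply(1:24, function(s) mean(sub_norm(s, 36)), numeric(1))      # 12 epochs
  long <- vapply(101:124, function(s) mean(sub_norm(s, 150)), numeric(1))   # 50 epochs
  se <- sqrt(sd(short)^2 / 24 + sd(long)^2 / 24)
  expect_lt(abs(mean(short) - mean(long)), 3 * se)

  # raw observed coherence decreases in expectation with epoch count
  raw <- function(seed, dur) {
    s <- fixture_subject(seed = seed, duration_s = dur, overlap = 0,
                         n_channels = 2, n_shuffles = 2)
    mean(s$obs$values)
  }
  r_short <- mean(vapply(1:10, raw, numeric(1), dur = 36))
  r_long <- mean(vapply(11:20, raw, numeric(1), dur = 150))
  expect_gt(r_short, r_long)
})
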