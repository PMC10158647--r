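# ntrack

Quantifies infants' **neural tracking of sung speech** from multichannel EEG
and relates it to later language outcomes, with a synthetic-cohort generator
that makes every stage of the analysis verifiable without access to infant
recordings.

## The scientific problem

During listening, cortical activity synchronizes with the slow amplitude
modulations of speech. In sung nursery rhymes those modulations concentrate
at the rates of stressed syllables (~1–3 Hz), syllables (3–5 Hz) and
phonemes (5–15 Hz). Developmental cohort studies — for example comparing
infants with high vs. low familial likelihood of autism at 10 vs.
14 months — ask whether the strength of this tracking in infancy predicts
vocabulary and autism-symptom outcomes years later.

`ntrack` implements the full measurement and inference chain:

1. **Envelope extraction** — magnitude of the analytic (Hilbert) signal,
   zero-phase 4th-order Butterworth smoothing, resampling to the EEG rate.
2. **Preprocessing** — 0.1–45 Hz zero-phase band-pass, 3-s sliding-window
   epochs with two-thirds overlap tiling each presentation block, ±150 µV
   automatic artifact rejection on demeaned epochs, common-average
   re-referencing, a ≥ 30-clean-epoch inclusion rule and cleaner-session
   selection.
3. **Speech–brain coherence** — per epoch, Hann-tapered Fourier spectra on
   the 1–15 Hz grid (43 bins, 1/3 Hz spacing); magnitude coherence over
   epochs

   Coh_xy(f) = |Σ_e X_e(f) · conj(Y_e(f))| / sqrt(Σ_e |X_e|² · Σ_e |Y_e|²)

   compared against a **surrogate** obtained by shuffling envelope epochs
   (mean over 100 random pairings), and normalized as
   (obs − surr)/(obs + surr) to remove epoch-count bias before averaging
   into the three rate bands.
4. **Cluster-based sign-flip permutation test** over the channel × frequency
   grid (paired t map, distance-based 10–20 channel adjacency, max-mass
   null, exhaustive when 2^n permutations fit the budget).
5. **Brain–behavior models** — mixed repeated-measures ANOVA (band within,
   likelihood × age between, Type III), follow-up paired band contrasts,
   three-step hierarchical regression with incremental F-test gatekeeping,
   Monte-Carlo (200 × 20% holdout) and leave-one-out cross-validation, and
   group-wise Pearson correlations.

A forward-model **synthetic cohort generator** produces nursery-rhyme-like
envelopes (jittered bump trains), phase-locked EEG with 1/f noise, a
realistic scalp topography and artifact bursts, and behavioral outcomes from
a known linear model — so parameter recovery, specificity and calibration
are all testable. The methods vignette
(`vignettes/neural-tracking.Rmd`) documents the models, defaults, and two
measured finite-sample caveats of the surrogate procedure (anti-conservative
presence testing with overlapping epochs; small negative null bias of the
normalized ratio).

## Worked example

Run the whole pipeline — simulate a cohort, preprocess, estimate coherence
and surrogates, cluster test, behavioral models — from one configuration
(here a reduced geometry: 4 channels at 125 Hz, one 33-s presentation,
16 subjects, planted tracking and a planted vocabulary slope):

```r
library(ntrack)

cfg <- list(
  master_seed = 42, out_dir = "demo_run",
  simulate = list(
    n_per_cell = 4,
    envelope  = list(duration_s = 33, sample_rate = 125),
    subject   = list(noise_level = 10, artifact_rate = 1,
                     n_channels = 4, eeg_rate = 125, delay_s = 0.06),
    gain_mean = 2, gain_sd = 0.8, n_presentations = 1,
    behavior  = list(intercept = 20, slope_stressed = 30,
                     age_interaction = -10, group_interaction = -8,
                     residual_sd = 8, ados_slope = 0)),
  preprocess = list(min_epochs = 20),
  coherence  = list(n_shuffles = 100),
  cluster    = list(n_perm = 1000),
  behavior   = list(outcomes = "receptive", cv_rep = 200, cv_holdout = 0.2))

res <- run_pipeline(cfg)
print(res$cluster)
print(res$regressions$receptive)
```

which prints (seed 42):

```
<cluster_result: 15 cluster(s), 1000 Monte-Carlo permutations, threshold t=1.75>
  #1: 33 cells, mass 122.6, p = 0.0010
  #2: 20 cells, mass 71.4, p = 0.0020
  #3: 9 cells, mass 27.0, p = 0.0280
  ...
<hier_reg: outcome receptive, n = 16>
  step 1 [norm_stressed, norm_stressed:age01, norm_stressed:grp01]: F(3, 12) = 10.72, p = 0.0010; comparison p = 0.0010 *retained*
           CV: R2 = 0.756, RMSE = 14.10
  step 2 [norm_phonological, ...]: F(6, 9) = 14.07, p = 0.0004; comparison p = 0.0205 *retained*
  step 3 [norm_syllable, ...]: F(9, 6) = 8.18, p = 0.0094; comparison p = 0.6624
```

Reading the output: the planted envelope-locked EEG component produces a
dominant significant cluster (p = 0.001, its cells concentrated in the
stressed-syllable band), and step 1 of the hierarchical regression —
stressed-band coherence plus its age and likelihood interactions — is
retained with a positive coherence coefficient, recovering the planted
coherence → vocabulary relationship; cross-validated R² estimates the
out-of-sample predictive value. The run directory (`demo_run/`) holds the
cohort, ANOVA, contrast, correlation, regression and cluster tables as CSV,
a plain-text report, and the resolved configuration with a content hash;
re-running an unchanged configuration reproduces byte-identical tables.

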