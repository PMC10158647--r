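---
title: "Measuring infant neural tracking of sung speech: models, surrogates, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring infant neural tracking of sung speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntrack)
```

## The measurement problem

Infants' cortical activity synchronizes with the slow amplitude modulations
of speech. In sung nursery rhymes those modulations concentrate at the rates
of stressed syllables (roughly 1–3 Hz), syllables (3–5 Hz) and phonemes
(5–15 Hz). `ntrack` quantifies this synchronization as *speech–brain
coherence* between the stimulus amplitude envelope and multichannel EEG, and
carries the per-subject summaries into the group-level statistics a
developmental cohort study needs: a presence test against a surrogate null,
a mixed repeated-measures ANOVA over rate bands and groups (high vs. low
familial autism likelihood, 10 vs. 14 months), and hierarchical regressions
linking tracking to later vocabulary percentiles and autism symptom scores.

Because infant EEG of this kind is not publicly sharable, the package pairs
the analysis with a synthetic-cohort generator whose ground truth is known.
Every stage of the pipeline is exercised against that generator in the test
suite; this vignette records the models, the defaults, and the places where
we had to make a call.

## From audio to envelope

The envelope is the magnitude of the analytic (Hilbert) signal of the
stimulus waveform, low-pass filtered with a zero-phase 4th-order Butterworth
and decimated to the EEG rate (`compute_envelope()`). Two details are
under-determined by common practice and were fixed as follows:

* **Cutoff.** The Butterworth cutoff is not dictated by the analysis band;
  we default to 45 Hz, matching the EEG low-pass, which preserves all
  analyzed modulation rates (≤ 15 Hz) with a wide margin. It is a plain
  argument (`lowpass_hz`).
* **Where the filter acts.** The filter is applied to the Hilbert magnitude
  (not to the audio beforehand), and zero-phase (forward–backward
  magnitude response), so envelope–EEG lags are not biased by filter delay.

All zero-phase Butterworth filtering in the package — including the
0.1–45 Hz EEG band-pass — is realized in the frequency domain by applying
the filter's forward–backward magnitude response via FFT
(`fft_butterworth()`). At a normalized cutoff of 0.1 Hz on 500 Hz data the
classical transfer-function realization of the same filter is numerically
unstable in double precision; the frequency-domain form has the identical
ideal response and no stability issue. The test suite checks the passband
(10 Hz within 5%), the stopband (60 Hz under 10%), DC removal, and that
envelope peak times agree with a time-domain forward–backward oracle to one
sample.

## Epochs, rejection, inclusion

The aligned envelope/EEG track is cut into 3-s epochs with a sliding window
of two-thirds overlap (1-s steps), anchored at the start of each
presentation block so no epoch crosses a presentation boundary. Three 69-s
presentations yield 201 epochs. Epochs are demeaned per channel; any
demeaned sample beyond ±150 µV discards the epoch (the `peak_to_peak`
convention is available as an option). After rejection, channels are
re-referenced to the common average. A subject's session enters the
analysis only with at least 30 clean epochs (inclusive); when two sessions
are available the one with more clean epochs wins, ties going to the
younger session — a deliberate tie-break favoring early tracking, logged
when it fires.

The order demean → reject → re-reference is a choice; published
descriptions of such pipelines list the steps without fixing the order
completely. Demeaning before thresholding is the decisive part (otherwise a
DC offset could masquerade as an artifact); re-referencing afterwards does
not change which epochs were rejected.

## Coherence, surrogates, normalization

Per kept epoch, EEG channels and envelope are demeaned, Hann-tapered, and
Fourier-transformed without zero padding; 3-s epochs give an intrinsic
1/3 Hz resolution, and the analysis keeps the 43 bins from 1 to 15 Hz.
Magnitude coherence sums across epochs:

$$\mathrm{Coh}_{xy}(f) \;=\; \frac{\bigl|\sum_e X_e(f)\,\overline{Y_e(f)}\bigr|}
{\sqrt{\sum_e |X_e(f)|^2 \; \sum_e |Y_e(f)|^2}}$$

The magnitude (not magnitude-squared) convention follows the normalization
formula used downstream; `squared = TRUE` switches conventions. A single
Hann taper is the default for epochs of this length (`taper = "boxcar"`
available).

Coherence is biased upward at small epoch counts (a single epoch always
gives coherence exactly 1), so subjects with different trial counts are not
directly comparable. The chance level is estimated by *surrogate*
coherence: the envelope epochs are randomly permuted against the fixed EEG
epochs (identity permutation re-drawn) and the coherence averaged over 100
such pairings. The per-cell normalization

$$\mathrm{Coh}_{\text{norm}} = \frac{\mathrm{Coh}_{\text{obs}} - \mathrm{Coh}_{\text{surr}}}
{\mathrm{Coh}_{\text{obs}} + \mathrm{Coh}_{\text{surr}}}$$

removes the epoch-count dependence (tested: null means for 12-epoch and
50-epoch subjects agree within Monte-Carlo error). Band summaries are
unweighted means over all electrodes and the band's bins; the bins
partition as 7 (stressed, 1–3 Hz closed), 6 (syllable, (3,5]) and 30
(phonological, (5,15]), so the boundary bins at 3.00 and 5.00 Hz are
counted once each, in the lower band.

### Two finite-sample caveats we measured

These are properties of the published procedure itself, reproduced and
quantified by this implementation; neither is an implementation artifact.

1. **Overlapping epochs make the surrogate an underestimate.** With
   two-thirds-overlap windows, consecutive epochs share samples, so both
   the EEG and the envelope epoch sequences are serially correlated. The
   true, time-aligned pairing preserves the alignment of those correlations
   inside the cross-spectral sum; a random permutation destroys it. The
   observed coherence therefore exceeds the surrogate *in expectation even
   when EEG and envelope are independent*. In our synthetic nulls the
   per-cell paired t over 40 subjects averages about +1.7 at 2/3 overlap
   and 0 with non-overlapping epochs. Consequence: the observed-vs-surrogate
   cluster test is anti-conservative at the study's overlap (we measure a
   family-wise rejection rate near 0.7 on null cohorts of 10, against a
   nominal 0.05), while it is calibrated, slightly conservatively, with
   non-overlapping epochs (measured ≈ 0.02). Users testing for the
   *presence* of tracking should either epoch without overlap for the
   inference step or interpret a significant cluster at overlapping
   epoching with this bias in mind.
2. **The normalized ratio is slightly negative under the null.** The
   observed coherence is one noisy draw while the surrogate is an average
   of 100 draws; passing them through the concave ratio
   \((o-s)/(o+s)\) gives a small negative expectation (≈ −0.05 in our
   nulls) that does not vanish with more epochs. The raw difference
   \(o - s\) is centered at zero under exchangeable nulls and is what the
   cluster statistic uses. Group *contrasts* of normalized values are
   unaffected because the bias is common to all subjects.

## Cluster-based permutation test

The group-level presence test forms a channel × frequency map of paired
t statistics (observed − surrogate, df = n − 1), thresholds it one-sided at
the `cluster_alpha = 0.05` quantile, and clusters supra-threshold cells via
channel adjacency or neighboring frequency bins on the same channel.
Cluster mass is the summed t; the null of the maximum mass comes from
per-subject sign flips — exhaustive over all \(2^n\) assignments when
\(2^n \le\) `n_perm`, otherwise Monte-Carlo with the observed labeling
included, so p can never drop below 1/`n_perm`. The channel adjacency ships
as a distance-based template over schematic 10–20 positions of the
28-channel montage (`inst/extdata/neighbors_1020.json`, 3–6 neighbors per
channel, connected). Threshold, sidedness and permutation count are
recorded in the result object because published analyses of this kind
rarely state them.

## Brain–behavior statistics

* **Mixed ANOVA** (`rm_anova()`): rate band within subjects, likelihood and
  age groups between; Type III sums of squares with sum-to-zero contrasts
  (the between cells are unbalanced in realistic cohorts; the df are
  unaffected by the SS type). For 41 subjects in 2 × 2 cells the within
  effect has df (2, 74) and between effects (1, 37).
* **Hierarchical regression** (`hierarchical_regression()`): predictors
  enter in three blocks — stressed band first (with its age and likelihood
  interactions), then the phonological triple, then the syllable triple.
  Each block is kept only if the incremental F-test against the *last
  retained* model has p < 0.05, so a failed second step means step 3 is
  compared to step 1. The default design matrix contains exactly the
  three listed terms per block and no separate group main effects: with
  n = 34 that gives the overall F df (3, 30) that the design arithmetic
  requires; `main_effects = TRUE` provides the hierarchically-coded
  alternative. Group codes are LL = 0/HL = 1 and 10m = 0/14m = 1. ADOS
  models are fit in the HL group only, without likelihood terms (two
  predictors; df (2, 15) at n = 18). A retained model that already fits
  exactly (residual sum of squares at numerical zero) blocks all further
  steps rather than producing 0/0 F ratios.
* **Cross-validation**: Monte-Carlo CV with 200 repetitions holding out
  20%; per repetition R² is the squared Pearson correlation between
  predicted and observed holdout values and RMSE the root mean squared
  prediction error, averaged over repetitions (degenerate holdouts are
  skipped and counted). Leave-one-out CV pools the n held-out predictions
  before correlating. The per-repetition averaging convention matters:
  pooled and averaged R² differ in small samples, and we document ours in
  the result rather than leaving it implicit.
* **Group correlations**: Pearson r per subgroup with df = n − 2,
  two-sided.

No multiple-testing correction is applied beyond the stepwise gatekeeping,
and no automatic outlier handling exists anywhere in the pipeline; both
facts are stated in the run report.

## The synthetic cohort

`generate_envelope()` builds a nursery-rhyme-like envelope as a unit
baseline plus one jittered bump train per rate component (defaults: 2 Hz at
depth 0.9, 4 Hz at 0.6, 10 Hz at 0.4). Bumps are raised cosines of width
equal to the period, so with zero jitter a component is an exact raised
cosine at its rate — the modulation spectrum then has a single clean line,
which the tests exploit. Event timing is a renewal process: each
inter-event interval gets Gaussian noise (SD = `jitter` × period, default
0.1). We deliberately jitter the *intervals* rather than positions around a
fixed grid: grid-locked timing keeps every epoch at the same stimulus
phase, which makes the shuffled surrogate equal the observed coherence and
would defeat the very mechanism the generator exists to exercise. Interval
jitter gives the drifting, quasi-rhythmic phase of a natural performance.

`generate_subject_eeg()` is a forward model: each channel receives the
band-filtered, 60-ms-delayed envelope scaled by the subject's per-band
tracking gain (in µV RMS), projected through a fixed fronto-occipital
topography, plus 1/f background noise (default 15 µV RMS, exponent 1) and
Poisson-timed half-sine artifact bursts of 200–400 µV and 100–300 ms
(default 2/min). The topography matters: a component identical on all
channels would be annihilated by common-average re-referencing, as any
zero-rank scalp projection would be. The 60-ms lag is configurable;
coherence magnitude is invariant to a constant lag, so it affects realism,
not the statistics.

`generate_cohort()` fills the four likelihood × age cells, draws per-band
tracking strengths from a truncated normal (mean 1, SD 0.4, floored at 0),
and generates vocabulary percentiles from a linear model on the true
stressed-band strength with age and likelihood interactions
(defaults: intercept 25, slope 25, age interaction −15, likelihood
interaction −10, residual SD 25, clipped to [0, 100] — chosen to mimic the
spread of age-normed percentile outcomes in infant cohorts). ADOS
comparison scores are integers 1–10 drawn independently of tracking by
default, with an optional coupling slope for power studies. When EEG is not
simulated, the cohort table's band-coherence columns carry the true
tracking strengths (an idealized, noise-free measurement); the pipeline
replaces them with measured normalized coherences when it runs the EEG
stages.

What the generator does *not* emulate: ocular and muscle artifacts with
ICA-like structure, bad channels needing interpolation, inter-channel noise
correlation, audiovisual attention effects, or any nonlinearity between
tracking and outcomes. Passing tests on this generator therefore certify
the statistical machinery and its calibration, not the adequacy of
preprocessing choices for messy real recordings.

## Problem sizes and numerical choices

The simulation-heavy tests and the acceptance script run the pipeline at a
reduced but complete scale — 4 channels at 125 Hz, one 33-s presentation
(31 overlapping or 11 non-overlapping epochs), 10–12 subjects per cohort,
100 surrogate shuffles, ≈ 1000 permutations — sizes at which one synthetic
subject costs well under 0.1 s while every rule of the full design
(inclusion thresholds, grid, bands, test logic) still applies. The default
`run_pipeline()` configuration instead reproduces the full study geometry
(28 channels, 500 Hz, three 69-s presentations, 201 epochs).

Degenerate inputs are handled explicitly rather than left to NaN
propagation: zero-power bins define coherence as 0 (flagged), zero-variance
t-map cells are capped at ±10⁶ (flagged), identical band values give a
paired t of 0 with p = 1, a constant outcome makes leave-one-out R²
0 with a flag, and degenerate CV holdouts are skipped and counted.

## Reproducibility

Every stochastic stage derives its seed from one master seed plus the stage
name (`derive_seed()`); re-running an unchanged configuration writes
byte-identical tables, and the resolved configuration (with a content hash)
is part of every run directory. The run report lists package version,
seeds, inclusion decisions and test parameters.
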