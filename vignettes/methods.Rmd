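---
title: "Methods: multimodal SSVEP and virtual-kiosk screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal SSVEP and virtual-kiosk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ssvepkiosk`, in the order the pipeline runs. The
guiding principle throughout: where the screening protocol fixes a value
(frequencies, durations, montage, band edges, classifier
hyperparameters), we use it; where it leaves the implementation open, we
state the choice made and why.

## The stimulation paradigm and synthetic EEG

The intermittent-photic-stimulation session flashes at 3, 5, 10, 12, 15
and 20 Hz for 10 s each, alternating with 10 s of rest — a 120 s session
sampled at 200 Hz over the 19-channel 10-20 montage. `make_ips_schedule()`
encodes exactly this layout.

`simulate_eeg()` emulates the steady-state responses this paradigm
elicits: during each block, targeted channels carry sinusoids at the
block frequency and its requested harmonics. Choices:

* **Noise model.** Pink (1/f) plus white Gaussian noise, defaults 1 µV
  and 0.5 µV SD. No noise model is prescribed by the protocol; 1/f-dominant
  background is the standard stylized EEG spectrum, and the default SNR
  leaves 10 s harmonic peaks clearly detectable, which is what the
  recovery tests require.
* **Harmonic rolloff.** When amplitudes are given per lobe without
  explicit per-harmonic values, a 1/n decay is the documented default —
  typical SSVEP behavior — but every amplitude is individually
  controllable through `amplitude_spec()`.
* **Determinism.** Every generator takes a required seed and restores the
  global RNG state afterwards; identical arguments give bitwise-identical
  output.

The simulator deliberately omits volume conduction with realistic head
models, eye-tracker noise and saccade dynamics: it generates the *signal
structure* the feature definitions respond to, not biophysics. Passing
tests therefore demonstrate that the pipeline measures what it claims to
measure, not that it would behave identically on clinical recordings.

## Preprocessing

Channels are mean-centered (`zero_mean()`), then `remove_artifacts()`
applies tunable wavelet thresholding: 1 s windows with 50% overlap
(Hann-weighted overlap-add), 5-level db4 decomposition with periodic
extension, and *elimination* — zeroing — of coefficients whose magnitude
exceeds a data-adaptive threshold. The threshold per coefficient band is
`4 * (beta / 0.1) * sigma`, with `sigma` the median-absolute-deviation
scale of that band's coefficients; `beta = 0.1` is the protocol default,
and smaller `beta` removes more aggressively. The window length and
overlap are our choices (unstated in the protocol) fixed for
reproducibility. This is a self-contained simplified implementation of
the tunable-threshold family of artifact removers; the operation sits
behind one interface so a different implementation can be swapped in.
Whether the original analysis ran artifact removal per block or over the
whole record is unstated; we process the whole record, which the
windowed design makes equivalent up to edge effects.

## The spectral pathway

`time_frequency()` uses 500 ms sliding windows (100 ms hop), 1–50 Hz in
1 Hz steps. The protocol text names both a three-taper multitaper with
8 Hz smoothing *and* an FFT with a Hanning taper; we implement DPSS
multitaper (NW = 2, 3 tapers — exactly the 8 Hz total smoothing) as the
default with `taper = "hann"` as the alternative, so both readings stay
runnable. Power is scaled so a bin-centered sinusoid of amplitude *a*
reads its mean-square power *a²/2*, which makes the closed-form oracle
tests exact to within spectral leakage.

Harmonic power is the time-average of power at `f·n` over the `f` block
(converted to dB, floor −120 dB so zero power never yields −∞),
excluding 250 ms at each block edge — half a window, where the sliding
estimate smears across the block boundary. Lobe power averages
electrodes **on the dB scale** by default. This is the reading under
which the published parietal/occipital ratios of ~0.7–0.8 are
meaningful (linear-scale averaging is available via `scale =
"linear"`). The harmonic domain `f·n < 50` yields 38 `(f, n)` pairs;
the protocol's stated count of 17 lobe-power-ratio features cannot be
reconstructed from its stated rules, so the full domain is emitted and
subsetting left to the caller.

`plant_lpr_amplitudes()` inverts the pipeline for calibration: it
measures the estimator's dB response to unit amplitude once, then places
occipital and parietal amplitudes so the dB lobe powers stand in a
requested ratio — exact for the linear, noise-free pipeline.

## The connectivity pathway

wPLI is estimated per (stimulation frequency, band) over the 10 s block
as `|E[Im S]| / E[|Im S|]`, pooling Hann-tapered 1 s segments with 50%
overlap and in-band 1 Hz bins. The estimator details (segment length,
overlap, no debiasing) are our choices; wPLI itself, being a normalized
phase measure, is invariant to channel amplitude scaling and discounts
zero-lag coupling, both verified by tests.

Band edges are half-open — θ [4, 8), α [8, 12), β [12, 30), γ [30, 50) —
so each boundary frequency belongs to exactly one band.

The Onnela clustering coefficient takes the cube root on the triple
product `(w_ei w_ej w_ij)^{1/3}` and divides by `deg(e)(deg(e)−1)`;
`deg(e)` counts nonzero-weight neighbors, so wPLI graphs are effectively
complete (`deg = 18`) unless the optional proportional threshold (`keep`)
is applied. `C(e)` is defined as 0 when `deg(e) < 2` (the no-triangle
limit of an undefined quotient). Weights are not renormalized by the
maximum weight: wPLI is already bounded in [0, 1].

The feature set per session is 24 lobe connectivity ratios (6
frequencies × 4 bands) and 12 band connectivity ratios (θ/β and α/β at
6 frequencies). The protocol claims 24 band ratios; only 12 are
constructible from its naming rules, and we emit those 12. The shared
"POR" prefix between power and connectivity ratios is disambiguated by
suffix grammar (`1H`/`2H`… vs a band letter).

## Behavioral features

Six features from the kiosk logs: scanpath length (summed Euclidean gaze
steps), fixation proportion, hand distance, hand speed, time to
completion (last step-6 completion minus session start), error count.
Choices:

* Fixation proportion uses sample-wise area-of-interest dwell: each gaze
  sample's label owns the interval to the next sample, and the ratio is
  target-item dwell over all menu-item dwell. No fixation detector is
  assumed because the logs carry AOI labels; a dispersion-based detector
  was considered and rejected as out of scope for labeled logs.
* Hand speed defaults to distance over total task time; a variant
  excluding stationary periods (< 0.01 m/s) is available by flag.
* Blink samples (missing coordinates) are dropped, never interpolated —
  deterministic and conservative.
* Coordinates are treated as world-frame; all geometric features are
  rigid-motion invariant either way, which the tests verify.

## The synthetic cohort

`simulate_cohort()` draws feature tables through a Gaussian copula:
within each group a multivariate normal draw with the requested latent
correlation matrix is pushed through per-feature marginal quantile
functions. Marginal families follow the shape of the published group
statistics: features whose SD is of the order of the mean (scanpath
length, hand distance, time to completion) are log-normal and the error
count negative-binomial — both moment-matched to the printed mean/SD —
while fixation proportion and hand speed are Gaussians truncated to
their physical ranges, and the eight neurological features are Gaussian.
The published tables report no distributional forms; these families are
declared modeling choices consistent with the rank-test branches the
published analysis used, not inferences about the original data.

Correlations are specified on the latent scale. For Gaussian marginals
they equal the Pearson scale exactly; for the skewed marginals the
Pearson correlation is mildly attenuated, which the recovery tests
quantify only for the Gaussian pairs they target.

`simulate_vr_cohort()` runs the full round trip — draw per-subject
targets, synthesize each session log at 50 Hz, re-extract features from
the logs. Hand *speed* is drawn from its marginal and distance derived
as speed × duration: the printed means almost satisfy the
distance = speed × time identity (within ~3.5%), and drawing distance
instead would badly distort the emergent speed under the heavy-tailed
durations.

## Statistics

The sequential ladder: Lilliefors (KS with estimated mean/SD) normality
test on each group at α = 0.05 — the protocol names KS normality testing
without a reference distribution, and Lilliefors is the version valid
with estimated parameters; failure in either group routes to the rank
branch. Otherwise Levene's test (mean-centered, α = 0.05) routes to the
independent-samples or Welch t-test. The protocol names the signed-rank
test for its two *independent* groups; signed-rank presumes pairing, so
the default rank branch is the Mann–Whitney rank-sum test, with a
literal signed-rank mode (pairing by sorted order, equal n) behind a
flag. Type-I error of the full ladder is verified ≤ 6% at nominal 5%.

Benjamini–Hochberg correction is applied within analysis families —
behavioral tests, neurological tests, and the correlation grid each form
one family, matching how the analyses are reported separately. The
original family partition is unstated; this is our reading.

## Classification

Per repeated split (default 30; the published SDs on held-out metrics
imply repeated evaluation whose mechanism is unstated, and independent
seeded stratified splits are the natural one): standardize by training
statistics, embedded linear-SVM selection (C = 0.05; keep features with
|weight| strictly above the mean — "lower than average" excludes the
average itself), LOOCV grid search per family (grids default to the
single tuned point per family), refit, evaluate on the held-out 7:3
test split. Selection runs per split by default — the leakage-safe
choice; a `select = "global"` mode reproduces the literal
select-once-on-everything reading. Scikit-learn-style hyperparameters
map onto their R equivalents; random forest's maximum depth and minimum
split size have no `randomForest` knobs and are approximated by the
minimum leaf size alone.

Metrics come from confusion counts with aMCI positive; AUC is the
trapezoidal area under the score ROC (rank identity, tied scores
averaged). The identities accuracy = (TP+TN)/total, sensitivity =
TP/(TP+FN), specificity = TN/(TN+FP) hold exactly for every emitted
confusion matrix, by construction and by test.

## Problem sizes and runtime

The recovery analyses use 20 000 subjects per group for marginal means
(sampling error ≪ the 2% acceptance band), 10 000 for correlation
recovery (±0.02), 2000 simulations for the type-I error of the ladder,
1000 random 19-node graphs and 1000 random p-vectors for the oracle
equivalences, and 30 split repeats for the modality-ordering benchmark.
These sizes make the whole suite run in minutes on one CPU while keeping
Monte-Carlo error well inside every stated tolerance.

## Known limitations

* The synthetic EEG has no volume conduction, so wPLI graphs on
  simulated cohorts are structurally simpler than clinical ones; the
  connectivity features are validated against construction oracles, not
  against clinical effect sizes.
* Published headline classification numbers stem from a private clinical
  cohort and are not reproducible here; the benchmark validates
  qualitative structure (combined ≥ EEG-only ≥ VR-only on planted
  signal), not those figures.
* The artifact remover is a documented simplification of the tunable
  wavelet-threshold family, not a re-derivation of any specific published
  algorithm's interior.
* EDF ingestion is not implemented; recordings travel as delimited text
  with a JSON schedule sidecar.
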