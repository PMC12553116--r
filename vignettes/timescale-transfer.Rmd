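---
title: "Dynamic intrinsic timescales and semantics-to-brain transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic intrinsic timescales and semantics-to-brain transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acwte)
```

## The scientific question

During naturalistic speech, the semantic content of what is heard — how
abstract the words are, how similar each stretch of dialogue is to the
next — fluctuates on timescales of seconds to minutes. Brain signals have
their own characteristic timescales: the intrinsic neural timescale of a
region, operationalized as the autocorrelation window (ACW) of its
activity, and that timescale itself fluctuates over the course of a
stimulus. `acwte` implements a pipeline for asking whether information is
transferred from the fluctuating timescales of a speech stimulus to the
fluctuating timescales of brain activity: semantic time-series
construction, sliding-window ACW, lagged transfer entropy with
block-bootstrap significance, plus the supporting group statistics
(inter-subject correlation, Levene variance contrasts, Welch spectra) and
a synthetic-data generator with known ground-truth coupling that validates
every stage end to end.

## From transcript to semantic series

Two 1-Hz series are derived from a timed transcript (`token`, `start_s`,
`end_s`):

* **Word depth** (`word_depth_series()`): each word is looked up in a
  hypernym-depth lexicon (a TSV of `token → depth`; an external WordNet
  exporter can populate it). Words are binned into one-second intervals by
  their *start* time; a bin's value is the mean depth of its covered
  words, and bins without covered words are zero. Polarity is taken as
  given by the lexicon. Lookup is case-insensitive after stripping
  surrounding punctuation; no lemmatization by default.
* **Sentence similarity** (`sentence_similarity_series()`): overlapping
  text windows (60 s advancing 1 s, the same grid as the brain analysis;
  a word belongs to the window `[w, w+60)` iff its start time falls in
  it) are embedded and consecutive windows compared by cosine similarity.
  The embedding provider is pluggable; the default for tests and
  simulations is a deterministic hashed bag-of-words embedder
  (`toy_embedder()`, FNV-1a hash, fixed dimension, unit-normalized), so no
  pretrained model is ever required. Windows with no speech embed to a
  zero-speech sentinel and any similarity involving one is set to 0,
  keeping the series defined across rest gaps.

Because consecutive 60-s windows share 59 s of text, similarity values sit
close to 1 during continuous speech and dip where the dialogue turns over
— the qualitative behaviour expected of such a series.

## Autocorrelation windows

`acf_biased()` computes the autocorrelation as autocovariance over
variance with divisor *N* at every lag and the mean taken once over the
whole input. This biased form guarantees `|r(m)| ≤ 1`, which the
first-crossing statistic relies on. The ACW is the first lag at which the
ACF reaches or drops below a threshold — 0 for ACW-0, 0.5 for ACW-50,
`1/e` for ACW-e — reported in seconds (`acw()`). When no crossing occurs
within the available lags the value is censored at the maximum lag and
flagged, so censoring is auditable rather than silent.

The crossing is integer-lag by definition. For parameter recovery against
analytic timescales (which are continuous) that quantization is a floor:
an AR(1) with `phi = 0.3` has analytic ACW-50 `ln(0.5)/ln(0.3) = 0.58` s,
which no integer-lag estimate at 1 Hz can approach. `acw(...,
interpolate = TRUE)` therefore offers a continuous variant — log-linear
interpolation between the bracketing lags, exact for exponentially
decaying ACFs, falling back to linear interpolation when values are
non-positive. The pipeline default remains the plain crossing; the
continuous variant is used where an analytic continuous value is the
comparison target.

`dynamic_acw()` slides a 60-s window in 1-s steps (both configurable; the
window must be an integer number of samples) and computes the window's ACW
with `max_lag = window − 1`. Constant windows yield missing values.
Brain-like signals are preprocessed first: the leading and trailing 20-s
rest periods are trimmed, a least-squares line removed, and a third-order
forward–backward Butterworth band-pass (0.05–0.5 Hz) applied to the
complete series before any windowing. With 1-Hz data the upper edge sits
at Nyquist, where a digital band-pass cannot place an edge, so the filter
reduces to its high-pass half there; the zero-phase pass uses
odd-reflection padding sized to the low cutoff so edge transients decay
inside the padding.

## Transfer entropy

Transfer entropy from source to target at lag *u* is the conditional
mutual information `I(target_t ; source_{t−u} | target_{t−1})` (histories
`k = l = 1` by default, configurable). It is estimated with the
Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator (`K = 4`,
max-norm distances, algorithm-1 counting; Frenzel–Pompe digamma
correction for the conditional form), with a deterministic seeded jitter
of relative amplitude 1e−10 breaking distance ties. Estimates are in nats
and may be slightly negative; they are never clipped, and inference rests
entirely on the surrogate distribution.

Two estimator-level guards matter on sliding-window statistics, and both
are exposed as parameters rather than hidden:

* **Embedding grid** (`te$embed_step_s`, default 10 s). A 60-s window
  advancing 1 s yields a series whose consecutive samples share 59/60 of
  their data; at a 1-s embedding step the estimate is dominated by that
  redundancy and carries no information about coupling (we measured
  coupled and uncoupled ensembles as indistinguishable there). The TE
  stage therefore embeds on block means of `embed_step_s` seconds,
  matching the grid to the statistic's innovation timescale. Raw-signal
  TE keeps the native 1-s grid.
* **Theiler window** (`te$theiler_s`, default 60 s). Temporal neighbours
  closer than this are excluded from the KSG neighbour search (dynamic
  correlation exclusion), removing the serial-correlation bias that
  otherwise makes the estimate depend on how smooth each input happens to
  be.

## Surrogate significance

Significance uses Markov block bootstrapping: a series is cut into
consecutive blocks, the blocks are permuted, and the entire downstream
computation is repeated on the shuffled input — for timescale-level TE
that means re-running the sliding-window ACW, the across-subject mean and
the alignment for every one of the (default 1000) surrogates. The p-value
is the proportion of surrogate TE values strictly greater than the
observed one (no +1 correction; a bias-corrected option exists). The
shuffled side is always the brain ensemble, in both the forward and the
reverse-direction analysis.

Block geometry differs by level:

* **Raw-level TE** shuffles each subject independently with block length
  equal to that subject's mean dynamic ACW — blocks matched to the raw
  signal's own correlation length.
* **Timescale-level TE** (`config$surrogate`) uses blocks of 2.5 window
  lengths, permuted with one common permutation across subjects. Both
  choices are forced by calibration: blocks much shorter than the window
  destroy the sliding-window statistic's local structure, and independent
  per-subject permutations flatten the group mean, so the surrogate TE
  distribution shifts away from the true null (we measured a ≈ +0.03 nat
  shift against fresh independent realizations, enough to swamp the
  effect sizes at this scale). Long coherent blocks preserve the
  statistic's structure while still destroying alignment with the source.

An important honesty note: a shuffle-based test of this kind rejects when
the two sides are *dependent*; directionality rests on the conditioning in
the TE statistic, not on the surrogates. The reverse-direction control is
therefore expected to stay null only when the putative receiver's own past
shields it — which is exactly what the synthetic generator probes.

## The synthetic generator

`gen_timescale_coupled_ensemble()` provides the positive and negative
controls. A smooth bounded driver (moving-average-smoothed white noise,
standardized, squashed into `(0,1)` by a logistic map, smoothness 60 s by
default) modulates local timescales on both sides:

* every **target subject** is a time-varying AR(1) whose coefficient
  follows the driver (mapped into `phi_range = (0.3, 0.95)`) at a delay of
  `coupling_lag_s` (3 s), plus white observation noise (SD 0.1) — a noisy
  stochastic realization, like a brain region;
* the **source** is a frequency-modulated quasi-periodic series whose
  instantaneous period follows the driver at lag 0 (mapped into 6–40 s, so
  its windowed ACW-0, about a quarter period, spans the same 1–15 s range
  as the targets), plus small white noise (SD 0.05) — a nearly
  deterministic function of the driver, like a fixed stimulus series.

Raw source and target series are uncorrelated by construction (independent
innovations); only their local timescales share the driver, with the
source leading. The asymmetry between a clean source readout and noisy
target realizations is what makes the transfer directional: the source's
timescale past is close to a sufficient statistic for itself, so the brain
ensemble adds almost nothing backwards, while the noisy brain past shields
poorly in the forward direction. We originally implemented the source as a
time-varying AR(1) like the targets, and measured the consequence: the
source's timescale readout is then as noisy as a single subject's, a clean
multi-subject brain mean genuinely informs the semantic timescale
backwards (two noisy sensors of one latent driver fuse information in both
directions), and no parameter setting recovers a directional contrast.
`source_kind = "ar1"` keeps that construction available for exactly this
kind of experiment. With `independent_drivers = TRUE` the targets follow
their own driver and the ensemble is a proper null with all marginal
structure intact.

Defaults are fixed at the emulated study's conditions: 900 s at 1 Hz (a
15-minute movie run), 20 subjects (a desk-scale stand-in for a large
cohort), driver smoothness 60 s (timescale drift visible within, but not
much faster than, the analysis window). `gen_transcript()` produces timed
transcripts (Poisson word onsets, thinned inside rest gaps, vocabulary
with depths 1–10), and `gen_ar1()` stationary AR(1) series whose analytic
ACF `phi^m` makes them recovery oracles for the ACW stage.

## What the validation does and does not show

The test suite runs the full pipeline on these ensembles: type-I error of
the block-bootstrap test on null ensembles stays at its nominal level with
approximately uniform p-values (5-subject ensembles, 200 replicates × 200
surrogates); on coupled ensembles (50 replicates × 200 surrogates) the
timescale-level input-to-brain TE is detected in roughly three quarters of
replicates while the raw-level and shuffled-input controls reject at
chance level; and the window-size sweep (60–540 s) shows TE largest at
60 s and decaying to the estimator's noise floor — at long windows the
median TE fluctuates around zero, so the decay is a trend, not a strictly
monotone sample path.

Two quantitative limitations of the contrast are worth stating plainly.
First, power is bounded by the information a single 900-s run contains: a
driver drifting on a 60-s scale analysed through 60-s windows yields on
the order of ten independent timescale epochs, and about a quarter of
replicates draw a realization too flat to detect. Second, the
reverse-direction control rejects more often than its nominal level (about
one replicate in five): a shuffle-based surrogate test detects
*dependence*, and directionality rests entirely on how well the putative
receiver's own past shields that dependence inside the estimator — a
shield that is imperfect whenever the semantic timescale readout carries
any noise. Both behaviours are properties of this test family, not
implementation artefacts, and both argue for caution when interpreting
directional TE claims on real naturalistic data.

These are tests against a generator whose coupling mechanism we chose.
Passing them shows the pipeline detects timescale-coupled structure of
this kind at this scale and does not invent it in its absence. It does not
show that real BOLD data behave like time-varying AR(1) processes (no
haemodynamic convolution, no realistic noise spectrum beyond AR structure),
nor that a real semantic series is as clean a readout of anything as the
FM source is; with `source_kind = "ar1"` the directional contrast
disappears, which is itself a caution for interpreting directionality
claims on real data.

## Group statistics

`sliding_isc()` computes, per 60-s window, the Pearson correlation of all
subject pairs and takes the median as the window's inter-subject
correlation; the summary is the mean over windows. Zero-variance slices
drop the affected pairs with a count. `roi_correlation_matrices()` extends
this to region pairs (median over cross-subject ordered pairs per window,
averaged over windows; symmetric, unit diagonal), for raw panels or
dynamic-ACW panels (`dynamic_acw_panel()`) side by side. `levene_test()`
is the classic Levene W on absolute deviations from the group mean
(centering switchable to the median), used to contrast the variance of
dynamic timescales between conditions; `welch_psd()` the standard averaged
Hann-tapered periodogram, with the pipeline wrapper trimming 20 samples at
each end before estimation.

## Numerical choices and degenerate inputs

Constant series: autocorrelation errors explicitly; a constant window
inside `dynamic_acw()` yields a missing value for that window; a constant
embedded series in TE is centred but not scaled. Missing windows are
linearly interpolated only when a dynamic series must become a uniform
series for TE alignment. Cosine similarity clamps floating-point spill
into `[−1, 1]` and errors on zero vectors. Alignment between semantic and
brain series is by sample times (the sentence-similarity series is one
window shorter than the grid; both series are truncated to their common
range). Analysis segments too short for the window plus the TE embedding
produce explicit skip rows, never silent missing values. All simulation
and surrogate randomness is seeded; reruns are byte-identical.

## Problem sizes

The shipped validation uses 900-sample series, ensembles of 5 subjects
(calibration) or 20 subjects (contrast), 200 surrogates with 50–200
replicates in the test suite, and 200 000 samples for the single long
AR(1) recovery check — sizes at which every property tested is stable
under reseeding while the full suite completes in minutes on one core.
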