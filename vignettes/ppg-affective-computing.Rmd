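---
title: "Morphological PPG features and SVM-based emotion-state classification"
author: "ppgaffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological PPG features and SVM-based emotion-state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgaffect)
```

## The problem

A photoplethysmogram (PPG) records blood-volume changes in the peripheral
microvasculature, one pulse per cardiac cycle. Emotional activation changes
the pulse shape through autonomic regulation: vasoconstriction lowers the
pulse amplitude, and changes in ventricular ejection stretch or compress the
systolic upstroke. This package implements an affective-computing pipeline
that classifies short PPG recordings into emotional states using only five
morphological indices of the pulse wave:

* **BVA** (blood volume amplitude, mV): height from a beat's onset valley to
  its systolic peak;
* **ST** (systolic upstroke time, ms): time from onset valley to peak;
* **DT** (diastolic time, ms): time from the peak to the next valley;
* **PPI / VVI** (ms): peak-to-peak and valley-to-valley intervals between
  consecutive beats.

By the landmark definitions, `ST + DT = VVI` exactly for every beat; the
package asserts this identity rather than treating it as approximate.

The experimental design the pipeline mirrors is a five-stage emotion-recall
protocol in hypertensive patients: a sitting baseline followed by neutral,
anger, happiness and sadness recall, one 3-minute recording per stage per
subject, 43 subjects. Since no public recordings exist for this protocol,
the package ships a synthetic-cohort generator whose stage-wise beat
statistics are parameterized by the published per-stage means and SDs
(`default_stage_params()`), so that every downstream stage is testable
end-to-end with known ground truth.

## The synthetic cohort generator

`synthesize_cohort()` builds `n_subjects x stages` recordings from a
three-level model:

1. **Population level.** Each stage has a mean and SD for BVA, ST and DT.
   The inter-beat intervals are emergent: a beat's period is `ST + DT`
   (the published stage table is internally consistent with this choice:
   baseline `196.01 + 650.84 = 846.85` ms against a printed VVI of
   `846.90` ms).
2. **Subject level.** Each subject draws one standard-normal effect per
   index, *shared across stages*, scaled by `between_sd_fraction` (default
   0.6) times the stage SD. The per-beat SD is shrunk to
   `sqrt(1 - 0.6^2) = 0.8` of the population SD, so the marginal beat
   distribution keeps the published spread. A stable subject offset is what
   motivates differential features: subtracting the subject's baseline
   cancels it. The published analysis does not decompose variance, so the
   0.6/0.8 split is a free simulator parameter chosen once as a realistic
   middle ground (individual differences comparable to, but not dominating,
   within-subject beat variability); it is configurable and tests estimate
   their tolerances from the data rather than assuming the split.
3. **Beat level.** Per beat, ST, DT and BVA are drawn independently from
   normals truncated to physiological ranges (ST 80--450 ms, DT
   300--1200 ms, BVA > 0). Truncation shifts the realized baseline ST mean
   by about +1.4 ms; recovery tests compare against the closed-form
   truncated mean where that matters.

Each beat is rendered as a **raised-cosine upstroke** of duration ST from
the valley level to valley + BVA, followed by a raised-cosine decay of
duration DT. The published material specifies only the landmark geometry
(one peak bounded by two valleys), not a pulse shape; raised cosines are the
simplest shape with that geometry whose extrema are known analytically,
which is what makes sample-accurate delineation oracles possible. White
Gaussian sensor noise (default SD 0.15 mV) and sinusoidal baseline wander
(default 0.3 mV at 0.2 Hz) are superimposed; the device band-pass of the
emulated recorder is 0.1--50 Hz at 2048 samples/s, and the generator's
default rate of 1024 samples/s halves compute while still resolving
millisecond-scale timing.

**What the generator does not emulate:** the dicrotic notch,
respiration-coupled amplitude modulation, arrhythmia, motion artifacts, and
any coupling between indices within a beat (they are drawn independently).
Passing tests therefore demonstrate that the pipeline's machinery is
correct and recovers known structure; they do not demonstrate performance
on real PPG morphology, where the notch and correlated beat dynamics make
delineation genuinely harder.

## Delineation

`detect_peaks()` finds local maxima and rejects implausible candidates by
two rules: a prominence floor (0.3 times the median candidate prominence)
and a minimum spacing of 0.33 s (about 180 beats/min), resolved greedily in
favor of the higher-prominence candidate with ties to the earlier one.
`detect_valleys()` places one valley per consecutive-peak pair at the
minimum strictly between them (ties: earliest sample), plus the pre-first
valley. Timing is at sample resolution throughout -- no sub-sample
interpolation -- and indices are 0-based in time (`t = index / fs`).

Two numerical facts shaped the noisy-signal path of `delineate_record()`:

* **Flat-extremum bias.** Near the onset valley the diastolic tail has
  vanishing slope, and near the apex the diastolic side falls away slowly.
  With additive noise, the argmin/argmax of signal-plus-noise wanders
  across the locally flat region and lands systematically on its flatter
  side -- a 10--15 ms bias at the default noise level, which would consume
  most of the recovery tolerance. The noisy path therefore takes both
  landmark *times* from the 25% and 75% amplitude crossings of the rising
  edge, where the signal-to-noise ratio is high: for a raised-cosine
  upstroke these crossings sit at exactly one and two thirds of ST, so
  `onset = 2 t25 - t75` and `apex = onset + 3 (t75 - t25)`. Residual bias
  is ~2 ms. The crossing fractions are exact only for this package's pulse
  model; applying the estimator to real PPG would require recalibrating
  them. Amplitudes (the valley level and apex height) still come from the
  inter-peak extrema, where noise contributes only ~1% upward bias.
* **Small-pulse rejection.** The prominence floor discards genuinely
  small-amplitude beats (about 1--3% under the default BVA distributions).
  A missed peak merges two beats into one implausible span, so
  `delineate_record()` gates beats to physiological ranges (ST 80--450 ms,
  DT 300--1200 ms; PPI outside 300--1500 ms masked). Mean recovery is
  unbiased by the gate because the surviving beats are unbiased draws.

Peak detection runs on a 0.5--8 Hz detection copy of the signal (standard
practice for beat localization: baseline wander and sensor noise are
suppressed, pulses survive), while all measurements are taken on the
0.1--50 Hz measurement band. With `filter = "off"` the raw samples are used
directly with plain argmin valleys; on noiseless synthetic input this is
sample-accurate, and the test suite asserts recovery within one sample.

The band-pass itself is a cascade of Butterworth high- and low-pass stages
(order 3 each) applied forward-backward (`signal::filtfilt`), so it is
zero-phase and does not shift landmark timing; a cascade is numerically
safer than a single band-pass design when the low edge (0.1 Hz) is a tiny
fraction of Nyquist.

## Featurization

Each 3-minute recording is cut into six non-overlapping 30-s segments
(half-open windows; a beat belongs to the window containing its onset
valley, so an onset at exactly 30.0 s goes to segment 2). Per segment the
**mean and standard deviation of each of the five indices** give 10
features. Conventions chosen where the source is silent: the SD is the
population SD (divisor *n*); the final beat's PPI is undefined and excluded
pairwise; segments with fewer than three beats are invalid and excluded.

**Differential features** subtract the subject's baseline from an activated
segment, cancelling stable individual differences. The published definition
operates at stage level, so the default reference is the subject's mean
over its six baseline segments -- the lowest-variance realization;
segment-index-matched subtraction is available via
`assemble_matrix(diff_pairing = "matched")`. In the binary
baseline-vs-state tasks the baseline rows carry their own difference from
the reference (zero only on per-subject average), so the differential block
never leaks the class label.

Feature matrices come in three sets: `waveform10`, `differential10`, and
`combined20` (waveform block first). Task label schemes: four binary
baseline-vs-state tasks; `2C` = negative (anger, sadness) vs positive
(neutral, happiness); `3C` separates neutral from positive (= happiness);
`4C` keeps all four recall stages. Baseline rows participate only in the
binary tasks. The published material contains two inconsistent definitions
of 2C (body text vs a table footnote); the body-text definition above is
implemented.

**Normalization** is z-scoring with mean and SD estimated from training
rows only (`zscore_fit()` / `zscore_apply()`); a constant training column
maps to zero with a warning. Keeping fit and apply as separate objects is
the leakage guard: in cross-validation the statistics are fitted per fold
on the five training folds, and the tests assert that a fitted model is
bit-identical no matter what test rows are later transformed.

## Classification and validation

The classifier is an RBF-kernel soft-margin SVM; binary machines are
libsvm via `e1071`, and the **one-against-all** assembly is implemented
here: one machine per class, prediction by the largest decision value, ties
to the lowest class index. Decision-value signs are normalized against
libsvm's internal label ordering so "positive" always means the target
class. Hyperparameters are fixed and logged rather than searched:
`C = 10`, `gamma = "auto"` = `1 / (n_features * pooled variance)` (about
`1/n_features` after z-scoring). These are deliberate mid-range defaults --
the source protocol does not state its values -- and with them
resubstitution does *not* fully memorize overlapping classes: on the
default cohort the baseline-vs-neutral task resubstitutes at ~0.85--0.88,
not 1.0, because the neutral stage shift is small relative to
between-subject variability and a C = 10 RBF machine is too smooth to
shatter the overlap. This is reported as-is; raising C to ~1000 would
memorize perfectly but would be tuning the classifier to a foregone
conclusion.

Validation schemes:

* **Resubstitution** (all-train-all-test): normalization and classifier fit
  on all rows, tested on the same rows -- a self-consistency ceiling.
* **Six-fold segment CV**: fold *k* holds the *k*-th 30-s segment of every
  recording (deterministic, keyed by segment index -- no randomness and no
  subject leaves the training set). Per fold, z-scoring is refit on the
  five training folds; the reported accuracy is the unweighted mean over
  folds. Note this estimates generalization *across segments*, not across
  subjects: every subject contributes training data for every test fold.

## Feature selection

Wrapper selection encodes subsets as bitstrings and scores them by the
classification accuracy of the configured validation scheme.

* `full_search()` enumerates all `2^n - 1` non-empty subsets (guarded at
  n = 20); ties prefer the smaller subset, then the lexicographically
  smallest bitstring (parsimony tie-break; the source is silent).
* `ga_select()` is a plain generational GA: roulette selection on min-max
  scaled fitness, one-point crossover (p = 0.8), per-bit mutation
  (p = 1/n), all-zero offspring re-mutated until non-empty, elitism 1 (so
  best-so-far fitness is provably non-decreasing), early stop after 20 flat
  generations, at most 100 generations of 50 chromosomes. The source
  describes the operators but no numbers; these are standard wrapper-GA
  values and all configurable. On 10-bit lookup problems with a unique
  optimum the GA recovers the exhaustive optimum in >= 4/5 seeded runs, and
  the evaluator memoizes subsets so converged populations cost little.

Fitness uses the *same* six-fold CV that is reported, matching the apparent
published protocol. This optimizes on the reported folds, so selected-cell
accuracies carry an optimistic selection bias; they are comparable with the
source's numbers but should not be read as unbiased generalization
estimates. A nested protocol (selection inside each training fold) would
remove the bias at ~6x cost and is deliberately not the default here.

## Problem sizes used by the shipped analyses and tests

The analysis scripts regenerate the full study geometry: 43 subjects x 5
stages x 180 s at 1024 Hz (215 records, ~9,000 beats per stage). Parameter
recovery checks use 3-standard-error tolerances computed from the data
(subject-level SEs for cohort grand means, beat-level SEs for single long
records). Classifier-level tests use smaller truth-table cohorts (8--10
subjects, no waveform rendering) because every classifier property being
tested is independent of the rendering path. The exhaustive-search analyses
evaluate 1023 subsets per 10-feature cell; the GA analyses use population
30 x 60 generations on the 20-feature cells.

## Known limitations

* The delineator's crossing fractions assume the raised-cosine pulse model;
  real PPG (dicrotic notch, reflected waves) needs different constants and
  notch-aware valley logic.
* Indices are drawn independently per beat; real beats correlate BVA with
  upstroke dynamics, so the synthetic covariance structure is optimistic
  for feature-selection stability.
* Six-fold segment CV shares subjects between train and test; accuracies do
  not transfer to subject-independent deployment.
* The 2C/3C/4C task difficulty ordering seen on real recordings is not
  reproduced by this generator: each synthetic stage forms its own compact
  class, so valence-merging does not make the task easier here.
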