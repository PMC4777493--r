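---
title: "Nonlinear respiratory-signal screening for obstructive sleep apnea: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear respiratory-signal screening for obstructive sleep apnea: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osascreen)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed by attended polysomnography and
graded by the apnea-hypopnea index (AHI, events per hour of sleep): normal
below 5, mild 5–15, moderate 15–30, severe above 30. Full polysomnography is
expensive and scarce; `osascreen` implements a screening pipeline that works
from three inexpensive overnight channels — nasal cannula airflow (F),
thoracic belt movement (T) and pulse-oximetry SpO2 — by extracting
*nonlinear* descriptors of breathing dynamics and feeding them to simple,
auditable predictive models:

1. an affine AHI predictor,
   `AHI = 1.2·BMI + 0.4·T90 − 18.6·dDFA_f2 + 7.8·dLLE + 60.5·mmDFA_t2 − 27`,
2. severity classification and the normal/mild vs moderate/severe (CPAP
   treatment) dichotomy, and
3. gain-ratio decision trees with stratified 10-fold cross-validation and
   best-first wrapper feature selection.

Because raw patient recordings cannot ship with a package, a synthetic
recording generator with controllable ground truth stands in for the cohort;
every stage of the pipeline is exercised and validated against it.

## The three estimators

**Detrended fluctuation analysis (DFA).** The series is integrated
(cumulative sum of mean-subtracted samples), cut into non-overlapping boxes
of `n` samples, a least-squares line is removed per box and
`F(n) = sqrt(mean(residual²))`. A straight `log F(n)` vs `log n` line
indicates power-law scaling with exponent α: ~0.5 for uncorrelated noise,
~1 for strong long-range correlation. Box durations are anchored at 8, 30
and 100 s — roughly 2, 6 and 24 breaths at the nominal 4-s breath — and two
slopes are fitted: `alpha_fast` over 8–30 s and `alpha_slow` over 30–100 s.
Each band contains at least 7 log-spaced box sizes because a two- or
three-point slope would be dominated by single-box noise. Detrending is
linear and trailing partial boxes are discarded (the canonical procedure).
A zero-variance series gives `F(n) = 0` everywhere; the slopes are then
reported as `NA` with a `degenerate` flag rather than as an arbitrary
number.

**Approximate entropy.** `ApEn(m, r, N)` (Pincus form, self-matches
included, Chebyshev distance) with `m = 2` and `r = 0.2 ×` the SD of the
whole series, which makes the statistic invariant to affine rescaling of
the signal. ApEn is O(N²); computing it on a full night of 200 Hz flow
(millions of samples) is not meaningful numerically or computationally, so
the recording is block-averaged to 1 Hz first — breath-to-breath regularity
lives well below 0.5 Hz, and the working rate is a configuration parameter
(`apen_rate`). Whether the tolerance should use the whole-recording SD or
per-window SDs is ambiguous in practice; the whole-recording SD is used so
that sub-window values share one scale. The high/low swing statistics
(`APEN_high`, `APEN_low`) are the maximum and minimum of the first
differences of ApEn over successive non-overlapping 5-minute sub-windows:
signed quantities, near-symmetric about zero, that capture the largest
regularity shifts across the night. The derived parameters follow the sum
convention `dAPEN = APEN_high + APEN_low`, `mAPEN = dAPEN / 2`. A constant
series returns `ApEn = 0` exactly — every epoch matches every other — even
though its tolerance degenerates to zero.

**Largest Lyapunov exponent (Rosenstein method).** The series is
delay-embedded; each point is paired with its nearest neighbour at temporal
separation beyond a Theiler window; the mean log separation of pairs is
tracked over time and λ is the least-squares slope of the initial,
approximately linear part of that divergence curve, converted to per-second
units by the sampling rate. Defaults: embedding dimension 5 for respiratory
signals (2 for map fixtures), delay at the first autocorrelation zero
crossing, Theiler window of one mean breath, and a fit over the first third
of the divergence horizon. None of these is canonical; all are exposed.
Respiratory channels are block-averaged to a working rate before embedding
(2 Hz for flow, 1 Hz for the slower belt signal): a few samples per breath
carry the divergence structure, and the O(N²) neighbour search over a
170-minute window would otherwise be prohibitive. For the logistic-map
validation the divergence saturates after about six doublings of a typical
neighbour separation, so the fit uses steps 0–5 of a 15-step horizon; on
that fixture the estimate lands within 0.05 of the analytic ln 2. λ may
legitimately be negative for contracting dynamics, and a pure sine gives
|λ| below 0.02 per step.

## Windowing scheme and the derived feature set

All analysis windows start one hour after recording start, when sleep is
established. DFA uses 20 min of flow, 240 min of thoracic signal, and 80
min of *quarter-rate* flow (`f2`): the flow decimated by literally keeping
every fourth sample — no anti-alias filter, because the decimation is part
of the feature definition, not a resampling step. LLE uses 20-min flow,
80-min quarter-rate flow and 170-min thoracic windows; ApEn and T90 use the
full recording. T90 is the percentage of SpO2 samples strictly below 90%.

Every difference/mean pair is stored redundantly with its components and
satisfies `X = m + d/2`, `Y = m − d/2` exactly: `dDFA = alpha_fast −
alpha_slow` per signal (the orientation is genuinely ambiguous in the
literature this feature set descends from, so `dfa_sign` flips it),
`dLLE = LLEf − LLEt`, `dLLE2 = LLEf2 − LLEt`, and the cross-signal pair
`dmDFA_t2 = mDFA_f2 − mDFA_t`, `mmDFA_t2 = (mDFA_f2 + mDFA_t)/2` that the
affine AHI model uses. Feature tables are written as CSV under the field's
display names (`DFA slow_f`, `APEN high_t`, `mmDFAt2`, …) with a JSON
sidecar of every estimator setting for provenance.

## The synthetic generator

`generate_recording()` emulates what the estimators sense, not full
physiology:

* quasi-periodic breathing, `sin(2πt / 4 s)`, in flow and belt channels;
* events at an exact count `round(AHI × hours)`, placed by a renewal-style
  arrangement (exponential gaps rescaled into the free time) with at least
  one breath between events — so the realized AHI equals the requested one
  by construction;
* apneas reduce flow amplitude to 5% of baseline, hypopneas to a uniform
  30–70% residual, while the belt keeps 60% excursion (paradoxical effort);
* SpO2 desaturations ramp down linearly starting 10 s after event onset and
  recover exponentially (τ = 15 s) from a ~96% baseline, with mean depth
  8 points;
* measurement noise with SD 5% of the breathing amplitude (the noise floor
  of real equipment is not documented for this feature set; 5% is a typical
  figure and a config default, not a fitted value);
* a slow amplitude modulation whose depth grows with event load, giving
  severe nights more long-range correlation structure than quiet ones.

`generate_cohort()` draws true AHI from a mixture — 24% normal-range
subjects, the rest log-normal (meanlog 3.58, sdlog 0.64, capped at 110
events/h so that the densest nights remain schedulable without event
overlap) — and couples BMI (target r ≈ 0.58) and Epworth score (r ≈ 0.47)
to the severity latent through a Gaussian copula, with age ~ N(48, 13.6)
truncated to 16–83 and a 74% male fraction, matching a typical sleep-clinic
case mix. Everything is a pure function of (spec, seed).

What the generator does **not** emulate: sleep staging and arousals,
central apneas and Cheyne–Stokes breathing, cardiac or EEG coupling,
movement artifacts, sensor detachment. Consequently, green pipeline tests
demonstrate correctness of the computations and sensible behaviour of the
estimators — they do not certify clinical performance on real recordings,
and no clinical figure from any patient cohort is asserted by the test
suite.

## Classifier details

The tree inducer follows the common C4.5/J48 reading: splits maximize gain
ratio (information gain over split information); numeric features use
binary thresholds at midpoints between consecutive distinct values;
categorical features split multiway; growth stops on pure nodes or nodes
smaller than `2 × min_leaf` (default `min_leaf = 2`); pessimistic
error-based subtree replacement at confidence 0.25 prunes the result. Leaf
class frequencies serve as ROC scores; AUC uses tie-aware trapezoids
(equal to the normalized Mann-Whitney U). Cross-validation folds are
stratified with a fold counter shared across classes, so total fold sizes
differ by at most one and every sample is tested exactly once. Wrapper
feature selection is best-first: single-feature additions/removals scored
by internal cross-validated accuracy, backtracking to the best unexpanded
subset, stopping after five non-improving expansions; ties prefer smaller
subsets, then feature order. Missing feature values are refused rather than
imputed.

The CPAP dichotomy has a genuinely ambiguous boundary: the severity bands
make AHI = 15 "mild" (conservative group) while the treatment dichotomy is
usually stated as AHI ≥ 15. Both conventions are implemented —
`binarize_for_cpap(labels)` vs `binarize_for_cpap(ahi, by_ahi = TRUE)` —
and they agree everywhere except at exactly 15.

## Statistics

`compare_groups()` gates on normality per group — Lilliefors-corrected KS
by default, because group means and SDs are estimated; plain KS behind a
flag — then applies a pooled-variance t-test (Welch optional) or
Mann-Whitney U. `power_two_sample()` is the closed-form normal
approximation (noncentral t behind a flag); the classic 25/75 design with
Δ = 0.15, SD = 0.2 at α = 0.05 gives 90.1% power. Cohen's kappa uses
marginal-product expected agreement and refuses the degenerate `p_e = 1`
case. Bland–Altman limits are bias ± 1.96 SD of the paired differences. No
multiple-testing correction is applied by default (mirroring common
practice in this screening literature); `p.adjust` can be applied by the
caller.

## Numerical choices and problem sizes

* EDF I/O is 16-bit; round-trip error is bounded by one quantization step
  of each channel's physical range. Continuous EDF/EDF+C only — the
  analysis assumes a contiguous time axis, so EDF+D is rejected.
* Windows are half-open `[start, start + duration)` with 0-based sample
  indexing, which makes nested extraction compose exactly.
* The ApEn kernel and the Lyapunov neighbour search are the two O(N²) inner
  loops and are written in C++ (match symmetry halves the ApEn work; the
  two template lengths share one pass).
* fGn is synthesized exactly by circulant embedding (Davies–Harte); the
  circulant eigenvalues are non-negative for all H in (0,1), tiny negative
  round-off is clamped.
* Package tests and examples run cohorts of 24–40 subjects with 6-hour
  nights at reduced channel rates (flow 8 Hz, belt 4 Hz, SpO2 1 Hz). The
  windowing scheme is defined in seconds, so the features are
  rate-agnostic; reduced rates keep a full-cohort run to a few minutes
  while exercising every code path at full window lengths. Estimator
  validation uses n = 16384 reference series averaged over 20 seeds.

## Known limitations

* The high/low ApEn swing statistics are one defensible reading of a
  loosely specified construct; their absolute scale is not comparable to
  historical tables built with other software.
* DFA's fast band carries a small positive bias (~+0.02 at α = 0.5) from
  boxes of only a few samples at low rates; the slow band is nearly
  unbiased. Band edges are configurable.
* The Rosenstein estimator's fit region matters: on strongly chaotic maps
  the divergence saturates quickly and the default first-third fit is too
  long — pass explicit `fit_steps` for such fixtures.
* The affine AHI model can predict negative values; screening thresholds
  are applied to the raw affine output by design (`clamp_zero` exists but
  is off).
* Synthetic cohorts validate computation, not clinical accuracy.
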