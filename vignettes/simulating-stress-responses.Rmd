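---
title: "Simulating acute glucocorticoid responses: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating acute glucocorticoid responses: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its model: what is being
simulated, which knobs matter, which numerical and design choices were
genuinely open and how they were settled, and what passing tests do and
do not establish about real hormone data.

## The phenomenological curve model

`cortsim` makes no mechanistic (HPA-axis) assumptions. An acute response
is a shape: flat baseline `B` until `T_on`, linear rise to the maximum
`M` at `T_max`, plateau of length `D`, linear return over `T_ret` to a
recovery level `E`, held flat afterwards. Those seven parameters pin five
turning points; everything else about the curve comes from smoothing.

The skeleton is interpolated to a 1-minute grid over `[0, t_end]`
(default `t_end = 120` min, long enough to contain the default response
with its recovery tail) and smoothed by locally weighted linear
regression (`lowess`, no robustness iterations). Two numerical choices
matter:

* **Bandwidth.** `smooth_span` (default 0.3) is interpreted as a fraction
  of a fixed 120-minute reference window — an absolute bandwidth of about
  36 min — rather than a fraction of whatever grid `t_end` happens to
  produce. With a purely proportional span, extending `t_end` would
  change the curve everywhere; with an absolute bandwidth the curve is
  bit-identical on the shared grid away from the old boundary (any local
  smoother must still differ within one bandwidth of a boundary). The
  default produces rounded shoulders and pulls the smoothed peak a few
  percent below `M` and a few minutes past `T_max`; the regression test
  freezes that behavior (smoothed maximum within 10% of `M`, argmax
  within 5 min of `T_max` for the reference parameters).
* **Clamping.** Concentrations cannot be negative, so smoothed values are
  clamped at 0 *after* smoothing, and assay noise is clamped at the assay
  floor (default 0). Clamping after smoothing avoids kinks inside the
  smoother's window.

Degenerate inputs are legal where they are scientifically meaningful: a
flat response (`B = M = E`) passes through the smoother unchanged, and a
zero-length plateau collapses two turning points onto one time (handled
as ordered ties in the interpolation). A zero onset delay is rejected —
the baseline segment needs positive width for the skeleton to be a
function of time.

## The population and what "true" means

Individuals are draws from a 7-dimensional multivariate normal on the
*sampling scale*: parameters flagged `log` (default: only `max_value`)
have mean and SD interpreted on the natural-log scale and are
exponentiated after the joint draw. Correlations are specified on the
sampling scale, where the joint distribution actually is normal.

The package default population — baseline 5 ± 1 ng/µl, onset 3 ± 1 min,
time-to-max 30 ± 5 min, log-maximum log(25) ± 0.3, plateau 10 ± 3 min,
return 30 ± 5 min, recovery 6 ± 1 ng/µl, uncorrelated — is an artifact
default chosen once to resemble published acute corticosterone responses
in shape and spread (baseline an order of magnitude below the peak, peak
near half an hour, right-skewed maxima). Every scenario overrides the
parameters it studies; nothing downstream depends on these numbers being
"correct" for any particular species.

Draws that violate the curve invariants (e.g. a negative plateau, or
`T_max ≤ T_on`) are rejected and redrawn per individual, which preserves
the joint shape better than clamping would; if more than half of a first
batch is invalid the population is considered mis-specified and sampling
errors out rather than silently truncating. User-supplied correlation
matrices with slightly negative eigenvalues (rounding in hand-written
configs) are repaired by eigenvalue clipping; genuinely indefinite
matrices are rejected.

## Expression: within-individual variation

Each observed event mixes the individual's true parameters with a fresh
draw from the same population, on the sampling scale, under a fidelity
weight `w` per parameter. Because the fresh draw comes from the full
multivariate normal, expressed parameters retain the population's
correlation structure for any `w` — the property tests check this
directly.

Two mixing rules ship because the natural description ("partly the true
value, partly a new draw") is ambiguous about variance:

* `convex` (default): `w·true + (1−w)·fresh`. Literal, but shrinks the
  expressed marginal variance by `w² + (1−w)²`.
* `variance_preserving`: `μ + w(true−μ) + √(1−w²)(fresh−μ)`, which keeps
  the expressed marginal variance exactly at the population variance for
  every `w`.

The package default fidelity is 0.8 for all parameters — "moderate"
within-individual consistency, between the extremes of a perfectly
repeatable phenotype and pure noise, and the same value the
single-trait-accuracy scenario fixes. One subtle consequence of
population-based mixing is worth stating plainly: within-individual
noise *scales with the population SD*. Shrinking a parameter's
between-individual variation also shrinks its within-individual
variation, so expression mixing alone can never make a trait
unmeasurable. A fixed-scale noise floor — the assay error — is what
breaks that proportionality, which is why the covariation scenario keeps
the standard 1 ng/µl assay error rather than sampling noiselessly (see
below).

## Observation, seeding, and fitness

Sampling designs are `fixed` times (standardized protocols),
`uniform_random` over a window, or `weighted_normal` (times drawn from a
normal centred where peaks are expected, default mean 32 / SD 9 min,
truncated to the grid by redraw). Times are drawn once per individual
and shared across that individual's events. Assay error is additive
Gaussian on the concentration scale; a multiplicative-CV error model is
deliberately out of scope.

One master seed drives everything through fixed per-stage child seeds
(population, expression, times, assay, fitness), so changing the assay
model does not perturb the expressed curves, and identical configurations
write byte-identical CSVs — both are tested.

Fitness for individual *j* is `Σ_i √v_i·z_ij + √v_u·ε_j`, with `z` the
cohort z-scores on the sampling scale and shares summing to 1. Z-scoring
makes the configured share `v_i` equal the asymptotic R² of fitness on
true parameter *i* (for uncorrelated parameters), which turns a vague
"relative contribution" into something an acceptance check can measure.
The flip side: the true fitness–hormone *correlation* is scale-free, so
lowering a parameter's between-individual SD does not weaken the true
relationship, only the observable one.

## Repeatability estimators

* **Per-timepoint ICC**: one-way ANOVA ICC(1),
  `(MS_B − MS_W)/(MS_B + (k̄−1)MS_W)` with harmonic-mean events per
  individual — transparent, dependency-light, and asymptotically
  equivalent to a mixed-model fit for balanced designs. Negative
  estimates are clamped to 0 (and >1 to 1) with a warning; an optional
  nonparametric bootstrap resamples individuals for a 95% CI.
* **Profile repeatability**: `V_a/(V_a + V_w)` over whole fixed-time
  profiles, where `V_w` averages per-timepoint within-individual variance
  and `V_a` is the across-individual variance of timepoint-specific
  individual means *minus* the `V_w/k̄` those means retain. Without that
  standard variance-components correction the ratio sits near `1/(1+k)`
  (≈ 0.25 at three events) for completely unrepeatable profiles, which
  would defeat the statistic's purpose of separating consistent from
  inconsistent individuals.
* **AUC repeatability**: trapezoidal AUC per event — ground mode (above
  zero) or increase mode (above the first sample) — computed from the
  full stored curve, from only the observed noisy points, or from the
  curve restricted to the observed time window, then ICC across events.

## The scenario pipelines and their settled questions

Four seeded pipelines wrap the generator into complete studies. Where
their configurations were genuinely open, the choices and reasons:

* **Single-trait accuracy sweep** (`scenario_peak_timing_sweep`): all
  parameters except the maximum and time-to-max are frozen across
  individuals; the maximum is swept on the *linear* scale so the grid of
  SDs in ng/µl applies exactly; fidelity 0.8 and 1 ng/µl assay error are
  held constant across cells. Cells with zero true variance report `NA`
  with a warning rather than a meaningless R².
* **Speed–scope covariation** (`scenario_covariation`): base population
  with mean peak at 30 min and the chosen correlation imposed between
  time-to-max and (log) maximum; the variance sweep again uses a linear
  maximum so low/high SDs in ng/µl are exact. The standard assay error
  stays on, for the proportionality reason above.
* **Fitness-link power** (`scenario_fitness_detection`): the maximum's
  true share of fitness variance is 0.8; "low/high between" is log-SD
  0.1/0.5 and "low/high within" is fidelity 0.9/0.5; detection is a
  two-sided p < 0.05 from the simple regression of fitness on the 30-min
  value. Note that with n = 50 these settings give near-complete
  detection in *every* cell — the observed correlation (0.5–0.85) is
  simply too strong for significance testing to fail at this sample
  size — so the informative outcome is the ordered attenuation of the
  observed correlation across cells, which the acceptance suite asserts.
* **Sampling-scheme comparison** (`scenario_sampling_schemes`): control
  peaks at 30 min; treatment at 18 min with proportionally shorter onset
  (steeper initial rise) and an identical maximum distribution. Samples
  are read directly off the true curves (fidelity 1, no assay error).
  Group curves are estimated by a penalized-spline GAM of value on time;
  the estimate is **never extrapolated** — outside a fit's sampled time
  support it is held at its boundary value and the peak search is
  restricted to the support, because extrapolated splines produced
  runaway edge maxima for designs that concentrate samples mid-response.
  Schemes are scored by mean absolute error against the true group-mean
  curve over 0–60 min and by the estimated group difference in peak
  time. The weighted design's near-empty first ~12 minutes means it
  cannot win on full-window MAE against a design with a 1-min sample; it
  wins on what it is for — recovering the peak-time difference.

## Problem sizes and what the tests show

Population-level checks (means, SDs, correlations, fitness shares,
design time distributions) use 10,000 draws, where Monte-Carlo error on
a mean is ~1% of an SD. Curve-heavy pipelines are scaled to what they
need: 200 individuals per sweep cell for the accuracy scenario, 10
replicates × 100 individuals per covariation cell, 50 populations of 50
for the power scenario, and 100 paired replicates for the
sampling-scheme comparison — the last because the weighted scheme's
peak-error advantage is under a minute and smaller batches cannot
resolve it reliably. All suite seeds are fixed.

Passing tests show that the *generator* has the properties it claims
(distributions realized, invariants preserved, estimators correct on
data with known truth) and that the *study-design conclusions* hold
within this model of hormone data. They do not show that real
glucocorticoid responses are five-turning-point curves with normally
distributed parameters, that real within-individual variation is
population-shaped expression mixing, or that real assay error is
additive Gaussian. In particular, real data features deliberately not
emulated: circadian baseline drift, context-dependent reaction norms
(stressor identity, habituation), negative-feedback dynamics coupling
late-response parameters to early ones, multiplicative assay error, and
unmeasured third variables that could *inflate* observed
hormone–fitness correlations rather than attenuate them.

## Known limitations

* The seven-parameter decomposition is one consistent realization of the
  named response traits; other parameterizations (e.g. explicit rate of
  increase) would fit the same prose.
* Rejection-resampling truncates the multivariate normal near invariant
  boundaries, so realized moments drift slightly from specification for
  populations that put substantial mass on invalid curves (the sampler
  errors out past 50% invalid).
* The profile-repeatability statistic is a documented variance-ratio
  summary, not a reimplementation of any particular published formula.
* Fitness is linear in z-scored parameters: no nonlinear selection
  surfaces, no survival or longitudinal fitness models.
* Group-curve comparison uses a single smoother family (thin-plate GAM);
  conclusions about scheme rankings could shift with strongly different
  smoothers.
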