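---
title: "Methods: from gradient-boosted model to 0-100 scorecard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gradient-boosted model to 0-100 scorecard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`shapcard` automates the construction of an interval-based clinical risk
score from a gradient-boosted tree classifier. This vignette is the
package's own account of the method: the model and its assumptions, the
parameters that matter, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The model and its assumptions

The outcome is binary and rare-to-moderate in prevalence; features are a
mix of continuous measurements and unordered categories. The predictive
engine is a gradient-boosted tree ensemble fit on a 70/30 stratified
split with grid-search cross-validation (mean CV AUC is the selection
criterion). The scoring system does not assume linearity anywhere: all
shape information comes from the model's Shapley attributions.

Three assumptions are load-bearing:

* **Additivity in margin space.** Shapley attributions decompose the
  model's *log-odds* output exactly: `margin(x) = base + sum_j phi_j(x)`.
  Everything downstream (interval sums, patient totals) relies on this
  identity, which is why attributions are computed in margin space, never
  probability space, where additivity would only hold approximately.
* **Per-feature separability.** The scorecard replaces `phi_j(x_i)` by a
  step function of `x_ij` alone. Interaction structure learned by the
  ensemble is averaged into the per-feature profiles; a strongly
  interacting pair of features will lose fidelity in the scorecard.
* **Slope changes mark clinically meaningful interval boundaries.** The
  detector assumes that where the dependence profile's slope changes
  sharply, the model's sensitivity to the feature changes — the premise
  of interval scoring.

## Exact attribution and local accuracy

Attributions use the polynomial-time tree-path Shapley algorithm,
implemented in C++ (`src/treeshap.cpp`) over the parsed trees in double
precision, with node covers (training hessian sums) as the background
weights. The model's margin is computed by the same double-precision
traversal (split comparisons are done in float32, matching the boosting
library's routing, so both routes classify every sample identically).
Consequently `|base + sum(phi) - margin|` is at the level of double
rounding (~1e-12), comfortably inside the 1e-6 tolerance the test suite
asserts, and interval scores conserve attribution column sums to 1e-9.
The boosting library's own float32 SHAP implementation is retained as an
independent cross-check in the tests (agreement to ~1e-4).

For the logistic baseline the decomposition is the exact linear one,
`beta_j (x_ij - mean_j)` around the training means.

## Change-point detection

The raw dependence profile is a scatter of n points; slopes estimated on
raw points would be dominated by noise. The profile is therefore
quantile-binned:

* `n_bins = 50` (default): enough resolution to localize a breakpoint to
  a few percent of the feature's range at the cohort sizes the package
  targets, while keeping hundreds of samples per bin at n in the tens of
  thousands.
* `min_bin_count = max(20, floor(n/1000))`: bins below this merge into
  their right neighbour (left-to-right scan; the last bin merges
  leftward), so every slope estimate rests on comparable support even
  when the feature has heavy point masses.
* Bin centers are in-bin mean values (not edge midpoints), so slopes are
  computed between the actual centers of mass.

"Steepest slope change" is operationalized as the absolute second
difference of bin mean attributions over bin-center spacing: candidate
bin `i` is scored by `|s_i - s_{i-1}|`, where `s_i` is the slope between
centers `i` and `i+1`. Alternatives (segmented regression with
information-criterion model selection, derivatives of a kernel smoother)
were deliberately not used: the second difference is transparent, exact
on noiseless piecewise-linear profiles, and the test suite verifies it
against an exhaustive segmented-least-squares oracle on profiles of up to
30 bins and 3 kinks — on those inputs the two agree exactly, bin
boundary for bin boundary.

Selection rules:

* at most `k_max = 5` points per feature, the largest magnitudes first;
* a detection threshold `epsilon = 0.1 * sd(slopes)` of the profile. A
  perfectly linear profile has zero slope variance, hence `epsilon = 0`
  and *strictly greater* comparison returns no points — linear features
  contribute no interval boundaries, and fewer than five points is a
  legitimate outcome;
* a minimum separation of one bin between selected points, so a single
  noisy kink cannot consume several of the five slots;
* ties in magnitude break toward the smaller feature value, and the
  reported point is the left edge of the candidate bin, which places a
  detected point within one bin width of the underlying kink.

Categorical features bypass detection entirely — slope is undefined on
unordered categories; each category is its own segment.

## Interval scoring and normalization

The raw score of a segment is the **sum** of the attributions of the
training samples in it. A sum (not a mean) is the declared scoring rule;
note the consequence that a segment's score scales with its occupancy, so
densely populated segments dominate the normalization range. The global
min-max normalization — minimum raw score across *all* features maps to
0, maximum to 100 — puts every feature on one scale and implicitly
weights features by the spread of their attribution sums.

Degenerate and sparse cases are handled explicitly:

* an empty segment is flagged unscored and later filled: if **all** of
  its immediately adjacent segments are scored, it receives their mean
  (an edge segment has one neighbour, whose score is used directly);
  if any neighbour is itself empty, the fallback widens to the entire
  feature — the mean of all its scored segments. Filled values are
  flagged and excluded from the normalization constants, since they are
  derived, not observed;
* if every raw score is identical the model is degenerate; all scores
  are set to 50 with a prominent warning;
* a continuous feature with a single observed value, or whose binned
  profile has fewer than three bins, falls back to one all-covering
  segment;
* segments are half-open `[lo, hi)` with unbounded extremes, so any
  patient value — including values outside the training range — maps to
  exactly one segment; an unseen category receives the feature-wide mean
  of scored segments, with a warning.

Patient-level missing values are *not* handled by interval averaging:
they are imputed with the mean/mode table frozen on the training set
(the same table applied to validation data, preventing leakage).
Interval averaging concerns intervals lacking training data; the two
mechanisms are deliberately distinct.

A scorecard rebuild from identical model, cohort and configuration is
bit-identical, and the JSON serialization is byte-identical (numbers at
17 significant digits, unbounded edges as strings). For this reason
provenance carries a configuration hash and package version rather than
a wall-clock timestamp.

## The synthetic cohort generator

The generator is a first-class module, not a test fixture: it draws
features independently from declared distributions and the outcome from
`Bernoulli(plogis(intercept + sum of piecewise-constant effects))`, so
the true interval structure is known exactly. Two presets ship with the
package:

* `default_cohort_preset()`: 29 features shaped like a perioperative
  surgical registry (17 continuous — demographics, physical metrics, a
  laboratory panel; 12 categorical — sex, a five-level physical-status
  class, emergency surgery, comorbidity flags, high-risk surgery type),
  with piecewise-nonlinear effects on a handful of features and an
  intercept calibrated by a deterministic Monte-Carlo root-finder to a
  rare-event prevalence of 0.38% by default.
* `benchmark_preset()`: five features with one non-monotone "bump"
  effect (breakpoints −0.8/0.8), one monotone step, two nulls and a weak
  categorical, at 10% prevalence. The moderate prevalence is a
  deliberate design choice: the preset isolates breakpoint recovery and
  the nonlinearity advantage from rare-event estimation noise, which the
  default preset exercises separately.

Missingness is injected missing-completely-at-random *after* outcome
generation, with an explicit `NA` marker (never a numeric sentinel that
could collide with laboratory ranges). Because the original missingness
rates and mechanism of real registries vary, both are exposed as
parameters rather than baked into a default.

What the simulator does **not** emulate: covariance between features
(real labs are correlated), informative missingness, time-to-event
structure, measurement error, and site effects. Tests passing on
simulated cohorts therefore demonstrate that the machinery recovers
known structure under clean conditions; they do not certify performance
on any real registry.

## Evaluation choices

AUC is the Mann–Whitney statistic (ties one half); its 95% CI is a
percentile bootstrap with `B = 1000` stratified resamples — cases and
controls resampled separately, which is essential at sub-percent
prevalence where an unstratified resample can lose every case. Operating
thresholds use the Youden index over midpoints of consecutive distinct
scores (ties toward the lower threshold; score ties at the threshold
classify positive, stated for bit-reproducibility). PPV/NPV with empty
denominators are reported as missing, not zero. The six-item RCRI
comparator is a plain indicator count.

## Problem sizes used by the automated checks

The test suite validates breakpoint recovery and the scorecard-vs-logistic
AUC ordering on ten seeded replicates of the benchmark preset at
n = 20,000 (70/30 split), and the normalization bounds on a default-preset
pipeline at n = 5,000; the acceptance script uses the same n = 5,000
pipeline. These sizes give the detector several hundred samples per bin
while keeping the whole suite desk-scale.

## Known limitations

* Interaction effects are averaged into per-feature profiles (see
  assumptions); the package intentionally does not compute pairwise
  attributions.
* Sum-based interval scores couple score magnitude to segment occupancy;
  monotone effects can in principle yield locally non-monotone score
  sequences when occupancies differ sharply, although the high-signal
  benchmark shows non-decreasing scores for the monotone step feature.
* The five-point cap is a hard design constant of the method; profiles
  with more than five genuine kinks will be under-segmented, keeping the
  five steepest.
* Grid-search defaults are small (8 candidates, 3 folds) to stay
  desk-scale; serious applications should widen the grid via
  `model_config()`.
* No calibration analysis, decision-curve analysis, or risk-category
  cutoffs on the total score are provided.
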