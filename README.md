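# shapcard

**Explainable nonlinear clinical scorecards from gradient-boosted models.**

Clinical risk scores (think RCRI-style point systems) are loved for their
transparency — a clinician can read the score table, add up the points, and
see exactly why a patient is high risk — but they are traditionally built
on logistic regression and inherit its linearity assumption. Gradient-boosted
tree classifiers capture the nonlinear risk patterns that are common in
clinical data (a U-shaped BMI effect, a haemoglobin threshold), yet their
predictions are opaque. `shapcard` turns a fitted boosted model into a
plain, auditable score table while keeping the nonlinearity it learned.

It is aimed at biostatisticians and clinical-ML researchers who want an
automated scoring-system generator they can validate end to end: the
package includes a synthetic cohort simulator with known piecewise
log-odds ground truth, so every stage — attribution, change-point
detection, interval scoring — can be tested against truth without any
patient data.

## Method

For a binary outcome \(y\) and features \(x_1,\dots,x_p\):

1. **Fit.** A gradient-boosted tree classifier \(f\) is trained (70/30
   stratified split, grid-search cross-validation maximizing AUC;
   mean/mode imputation frozen on the training set).
2. **Attribute.** Exact tree-path Shapley values decompose every
   prediction additively in log-odds space:
   \(f(x_i) = \phi_0 + \sum_j \phi_{ij}\) (local accuracy, held here to
   ~1e-12 by a double-precision implementation).
3. **Segment.** For each continuous feature, the dependence profile
   \((x_{ij}, \phi_{ij})\) is quantile-binned and the detector keeps the
   (at most) **5 steepest slope-change points** — feature values where
   \(|\Delta \text{slope}|\) of the binned profile is largest and exceeds a
   noise threshold. A linear profile yields no change points; each category
   of a categorical feature is its own segment.
4. **Score.** Each interval's raw score is the **sum of the Shapley values
   of the training samples falling in it**; raw scores are min-max
   normalized **globally across all features** to a unified 0–100 scale
   (global minimum ↦ 0, maximum ↦ 100). Intervals with no training data
   are filled by the average of adjacent intervals, falling back to the
   feature-wide mean when a neighbour is also empty.
5. **Apply.** A patient's total risk score is the plain sum of the
   per-feature interval scores; evaluation uses Mann–Whitney AUC with a
   stratified bootstrap CI, Youden-index operating thresholds, and an
   RCRI comparator.

## Worked example

```r
library(shapcard)

preset <- benchmark_preset()       # known truth: x_bump has breakpoints at -0.8 / 0.8
co     <- generate_cohort(preset$schema, preset$risk, 10000, seed = 1)
parts  <- split_cohort(co, train_fraction = 0.7, seed = 2)
imp    <- impute_cohort(parts$train)
model  <- fit_gbdt(imp$cohort, model_config(seed = 3))
card   <- build_scorecard(model, imp$cohort)
card$changepoints$x_bump
#> changepoint_set of 'x_bump': 5 point(s) at -2.148, -0.9228, -0.7732, 0.706, 0.8624
subset(scorecard_table(card), feature == "x_bump")
#>   feature    interval  score n_points filled
#> 1  x_bump     < -2.15  46.20      140  FALSE
#> 2  x_bump -2.15–-0.92  19.52     1120  FALSE
#> 3  x_bump -0.92–-0.77  48.14      280  FALSE
#> 4  x_bump  -0.77–0.71 100.00     3780  FALSE
#> 5  x_bump   0.71–0.86  50.85      280  FALSE
#> 6  x_bump     >= 0.86  12.59     1400  FALSE
```

Four of the five detected points bracket the true breakpoints (−0.8 and
0.8) within a bin width or two, and the score table makes the planted
non-monotone "bump" visible: the middle interval (−0.77 to 0.71), where
the true log-odds are elevated, carries the maximum score 100, while both
tails score low. Scoring the held-out 30% and evaluating:

```r
test   <- apply_imputation(parts$test, imp$table)
scores <- apply_scorecard(card, test)
head(scores[, c("x_bump", "x_step", "flag", "total")], 3)
#>      x_bump   x_step     flag    total
#> 1  12.58786  0.00000 64.83080 192.0455
#> 2  48.14345  0.00000 64.83080 218.4931
#> 3 100.00000 74.83721 38.05564 310.6008
evaluate_scores(scores$total, test$outcome, seed = 4)
#> eval_report: AUC 0.702 (95% CI 0.671-0.734), threshold 249.1
#>   accuracy 0.629, sensitivity 0.709, specificity 0.621, ppv 0.164, npv 0.953
```

The total is an exact sum of the per-feature scores, so any individual
prediction can be audited row by row against the printed score table. A
main-effects logistic baseline (`fit_logistic_baseline()`) on the same
cohorts reaches a materially lower AUC — the non-monotone effect is
invisible to it.

`run_pipeline(run_config(...))` wires all stages together (and
`inst/cli/shapcard.R` exposes them as `simulate` / `fit` / `build-score` /
`apply` / `evaluate` / `run-all` shell verbs).

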