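Package: shapcard
Title: Explainable Nonlinear Clinical Scorecards from Gradient-Boosted Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable clinical risk scorecards from
    gradient-boosted tree classifiers. Per-feature Shapley attribution
    profiles are segmented by automated slope-change-point detection (at
    most five points per feature), each interval is scored by the summed
    attributions of the training samples it contains, and all interval
    scores are min-max normalized to a unified 0-100 scale with a
    neighbour-averaging fallback for empty intervals. Includes a synthetic
    cohort simulator with known piecewise log-odds ground truth, exact
    double-precision Shapley attributions for tree ensembles, a logistic
    baseline, and bootstrap AUC evaluation utilities, so the full pipeline
    can be validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
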