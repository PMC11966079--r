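# Expensive shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# Default-preset pipeline run: n = 5000, rare outcome, full grid search.
default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    cfg <- run_config(n = 5000L, base_seed = 42L, bootstrap_B = 200L)
    .fixtures$default_run <- run_pipeline(cfg)
  }
  .fixtures$default_run
}

# Ten seeded replicates of the piecewise benchmark family (n = 20000):
# one non-monotone bump feature with breakpoints at -0.8 / 0.8, one
# monotone step feature, nulls, and a weak categorical. Used for
# breakpoint recovery and the nonlinearity-gain comparison.
benchmark_runs <- function(n_seeds = 10L) {
  if (is.null(.fixtures$benchmark)) {
    bp <- benchmark_preset()
    cfg_grid <- list(max_depth = 3L, eta = 0.1, nrounds = 150L)
    .fixtures$benchmark <- lapply(seq_len(n_seeds), function(s) {
      co <- generate_cohort(bp$schema, bp$risk, 20000L, seed = 1000L + s)
      parts <- split_cohort(co, 0.7, seed = s)
      imp <- impute_cohort(parts$train)
      train <- imp$cohort
      test <- apply_imputation(parts$test, imp$table)
      model <- fit_gbdt(train, model_config(grid = cfg_grid, seed = s))
      attrs <- compute_attributions(model, train)
      card <- build_scorecard(model, train, attrs = attrs)
      baseline <- fit_logistic_baseline(train)
      list(seed = s, train = train, test = test, model = model,
           attrs = attrs, card = card,
           auc_card = roc_auc(apply_scorecard(card, test)$total,
                              test$outcome, conf = FALSE)$auc,
           auc_logit = roc_auc(predict(baseline, test, type = "margin"),
                               test$outcome, conf = FALSE)$auc,
           sd_bump = stats::sd(train$features$x_bump))
    })
  }
  .fixtures$benchmark
}

# Small two-feature cohort with a clean linear signal, for quick model and
# attribution checks.
toy_linear_cohort <- function(n = 500L, seed = 11L) {
  schema <- feature_schema(list(
    feature_spec("a", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("b", "continuous", distribution = dist_normal(0, 1))
  ))
  risk <- risk_spec(0, list(a = piecewise_effect(0, c(-3, 3))))
  generate_cohort(schema, risk, n, seed)
}
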