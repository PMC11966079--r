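make_missing_cohort <- function() {
  schema <- feature_schema(list(
    feature_spec("lab", "continuous", "mg/dL"),
    feature_spec("grp", "categorical", categories = c("A", "B"))))
  cohort(data.frame(lab = c(1, 2, NA, 3),
                    grp = factor(c("A", "A", "B", NA), levels = c("A", "B"))),
         outcome = c(0, 1, 0, 1), schema = schema)
}

test_that("imputation fills means and modes and freezes the table", {
  co <- make_missing_cohort()
  imp <- impute_cohort(co)
  expect_equal(imp$cohort$features$lab[3], 2.0)        # mean of 1, 2, 3
  expect_equal(as.character(imp$cohort$features$grp[4]), "A")  # mode
  expect_equal(imp$table$lab, 2.0)
  expect_equal(imp$table$grp, "A")
  # idempotence
  again <- impute_cohort(imp$cohort)
  expect_identical(again$cohort$features, imp$cohort$features)
  # no-missing cohort passes through but the table is still recorded
  expect_equal(again$table$lab, mean(c(1, 2, 2, 3)))
  # the frozen table transfers to new data unchanged
  fresh <- cohort(data.frame(lab = c(NA, 10),
                             grp = factor(c(NA, "B"), levels = c("A", "B"))),
                  outcome = c(0, 1), schema = co$schema)
  applied <- apply_imputation(fresh, imp$table)
  expect_equal(applied$features$lab[1], 2.0)
  expect_equal(as.character(applied$features$grp[1]), "A")
})

test_that("a fully-missing column is rejected by name", {
  co <- make_missing_cohort()
  co$features$lab <- NA_real_
  expect_error(impute_cohort(co), "'lab'")
})

test_that("stratified splitting conserves rows and balances cases", {
  schema <- feature_schema(list(
    feature_spec("x", "continuous", distribution = dist_normal(0, 1))))
  risk <- risk_spec(qlogis(0.01))
  co <- generate_cohort(schema, risk, 1000, seed = 20)
  parts <- split_cohort(co, 0.7, seed = 1)
  expect_equal(nrow(parts$train$features), 700)
  expect_equal(nrow(parts$test$features), 300)
  n_cases <- sum(co$outcome)
  expect_lte(abs(sum(parts$train$outcome) - 0.7 * n_cases), 1)
  expect_lte(abs(sum(parts$test$outcome) - 0.3 * n_cases), 1)
  # disjoint and exhaustive
  expect_equal(nrow(parts$train$features) + nrow(parts$test$features), 1000)
  key <- function(p) paste(p$features$x)
  expect_length(intersect(key(parts$train), key(parts$test)), 0)
  # determinism
  parts2 <- split_cohort(co, 0.7, seed = 1)
  expect_identical(parts$train$features, parts2$train$features)
  # degenerate class
  co$outcome[] <- 0L; co$outcome[1] <- 1L
  expect_error(split_cohort(co, 0.7, seed = 1), "stratify")
})

test_that("the boosted model nails a linearly separable toy problem", {
  schema <- feature_schema(list(
    feature_spec("u", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("v", "continuous", distribution = dist_normal(0, 1))))
  co <- with(list(), {
    set.seed(30)
    f <- data.frame(u = rnorm(500), v = rnorm(500))
    cohort(f, as.integer(f$u + f$v > 0), schema)
  })
  m <- fit_gbdt(co, model_config(grid = list(max_depth = 3, eta = 0.3, nrounds = 100)))
  auc <- roc_auc(predict(m, co, type = "margin"), co$outcome, conf = FALSE)$auc
  expect_gt(auc, 0.99)
  # probabilities respect the predictor contract
  p <- predict(m, co, type = "response")
  expect_true(all(p > 0 & p < 1))
})

test_that("degenerate training inputs are rejected before fitting", {
  co <- toy_linear_cohort()
  co$outcome[] <- 1L
  expect_error(fit_gbdt(co, model_config()), "single-class")
  expect_error(model_config(grid = list(depth = 2)), "illegal hyperparameter")
  expect_error(model_config(grid = list()), "non-empty")
  expect_error(model_config(cv_folds = 1), "cv_folds")
})

test_that("grid search selects the candidate with maximal CV AUC", {
  co <- toy_linear_cohort(n = 800, seed = 12)
  cfg <- model_config(grid = list(max_depth = c(1L, 3L), nrounds = c(10L, 60L)),
                      cv_folds = 3L, seed = 7L)
  m <- fit_gbdt(co, cfg)
  grid_df <- expand.grid(cfg$grid, KEEP.OUT.ATTRS = FALSE)
  # chosen pair is a member of the grid
  expect_true(any(grid_df$max_depth == m$chosen$max_depth &
                  grid_df$nrounds == m$chosen$nrounds))
  # oracle: re-evaluate every candidate on the same folds with xgboost directly
  X <- shapcard:::encode_features(co$features, co$schema, m$encoder)
  folds <- stratified_folds(co$outcome, 3L, seed = 7L)
  oracle_auc <- vapply(seq_len(nrow(grid_df)), function(ci) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L, seed = 7L,
                      max_depth = grid_df$max_depth[ci]),
        data = xgboost::xgb.DMatrix(X[tr, ], label = co$outcome[tr], nthread = 1L),
        nrounds = grid_df$nrounds[ci], verbose = 0)
      pred <- predict(bst, xgboost::xgb.DMatrix(X[!tr, ], nthread = 1L),
                      outputmargin = TRUE)
      pROC::auc(pROC::roc(co$outcome[!tr], pred, quiet = TRUE, direction = "<"))
    }, numeric(1)))
  }, numeric(1))
  chosen_idx <- which(grid_df$max_depth == m$chosen$max_depth &
                      grid_df$nrounds == m$chosen$nrounds)
  expect_equal(m$cv_results$cv_auc, oracle_auc, tolerance = 1e-8)
  expect_gte(oracle_auc[chosen_idx], max(oracle_auc) - 1e-12)
})

test_that("the logistic baseline recovers a known linear slope", {
  schema <- feature_schema(list(
    feature_spec("x", "continuous", distribution = dist_normal(0, 1))))
  beta_true <- 0.8
  co <- local({
    set.seed(40)
    x <- rnorm(20000)
    y <- rbinom(20000, 1, plogis(-2 + beta_true * x))
    cohort(data.frame(x = x), y, schema)
  })
  m <- fit_logistic_baseline(co)
  # dual route: formula-interface glm must agree exactly
  ref <- glm(co$outcome ~ co$features$x, family = binomial())
  expect_equal(unname(m$coef), unname(coef(ref)), tolerance = 1e-8)
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(m$coef[2] - beta_true), 2 * se)
})

test_that("the logistic baseline carries no signal on null features", {
  schema <- feature_schema(list(
    feature_spec("x", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("z", "continuous", distribution = dist_normal(0, 1))))
  risk <- risk_spec(qlogis(0.2))
  m <- fit_logistic_baseline(generate_cohort(schema, risk, 3000, seed = 41))
  fresh <- generate_cohort(schema, risk, 3000, seed = 42)
  auc <- roc_auc(predict(m, fresh, type = "margin"), fresh$outcome, conf = FALSE)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})
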