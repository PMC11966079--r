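#' Configuration for gradient-boosted model fitting
#'
#' @param train_fraction Training proportion used by [split_cohort()]
#'   (default 0.70).
#' @param cv_folds Number of stratified cross-validation folds (`>= 2`).
#' @param grid Named list of candidate values for the searched
#'   hyperparameters. Legal names: `max_depth`, `eta`, `nrounds`,
#'   `min_child_weight`, `subsample`, `colsample_bytree`, `lambda`,
#'   `alpha`, `gamma`. The default grid is deliberately small
#'   (depth x learning rate x boosting rounds, 8 points).
#' @param seed Integer seed governing fold assignment and fitting.
#' @param class_weight If `TRUE`, weight the positive class by the
#'   control/case ratio (`scale_pos_weight`). Off by default.
#' @return An object of class `model_config`.
#' @export
model_config <- function(train_fraction = 0.7, cv_folds = 3L,
                         grid = list(max_depth = c(2L, 3L), eta = c(0.1, 0.3),
                                     nrounds = c(100L, 200L)),
                         seed = 1L, class_weight = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (!length(grid)) stop("hyperparameter grid must be non-empty", call. = FALSE)
  legal <- c("max_depth", "eta", "nrounds", "min_child_weight", "subsample",
             "colsample_bytree", "lambda", "alpha", "gamma")
  bad <- setdiff(names(grid), legal)
  if (length(bad))
    stop("illegal hyperparameter(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 grid = grid, seed = as.integer(seed),
                 class_weight = isTRUE(class_weight),
                 objective_metric = "auc"),
            class = "model_config")
}

# ---- feature encoding -------------------------------------------------------
# Trees are fit on a numeric matrix: continuous features pass through, each
# categorical feature becomes one 0/1 indicator column per category. The
# `group` map sends encoded columns back to the original feature, so Shapley
# attributions of indicator columns can be summed per clinical feature.

make_encoder <- function(schema) {
  cols <- character(0); group <- integer(0)
  nms <- schema_names(schema)
  for (j in seq_along(schema)) {
    s <- schema[[j]]
    if (s$kind == "continuous") {
      cols <- c(cols, s$name); group <- c(group, j)
    } else {
      cols <- c(cols, paste0(s$name, "=", s$categories))
      group <- c(group, rep(j, length(s$categories)))
    }
  }
  list(schema_names = nms, colnames = cols, group = group,
       fingerprint = schema_fingerprint(schema))
}

encode_features <- function(features, schema, encoder) {
  n <- nrow(features)
  X <- matrix(0, n, length(encoder$colnames),
              dimnames = list(NULL, encoder$colnames))
  k <- 1L
  for (s in schema) {
    col <- features[[s$name]]
    if (anyNA(col))
      stop("feature '", s$name, "' holds missing values; impute first", call. = FALSE)
    if (s$kind == "continuous") {
      X[, k] <- as.numeric(col); k <- k + 1L
    } else {
      col <- factor(as.character(col), levels = s$categories)
      for (cat in s$categories) {
        X[, k] <- as.numeric(col == cat); k <- k + 1L
      }
    }
  }
  X
}

#' Stratified cross-validation fold assignment
#'
#' @param labels 0/1 outcome vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, balanced within each class.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

xgb_params <- function(candidate, class_weight, y, seed) {
  p <- list(objective = "binary:logistic", nthread = 1L, seed = as.integer(seed))
  for (nm in setdiff(names(candidate), "nrounds")) p[[nm]] <- candidate[[nm]]
  if (class_weight) p$scale_pos_weight <- sum(y == 0) / sum(y == 1)
  p
}

fit_booster <- function(X, y, candidate, class_weight, seed) {
  nrounds <- if (!is.null(candidate$nrounds)) as.integer(candidate$nrounds) else 100L
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(params = xgb_params(candidate, class_weight, y, seed),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

# ---- tree parsing -----------------------------------------------------------
# The booster's trees are re-parsed into flat double-precision arrays. All
# downstream predictions and Shapley attributions run over these arrays in
# double arithmetic, so that the additive decomposition base + sum(phi)
# reproduces the model margin to ~1e-12 (the float32 output of the booster
# itself agrees with this margin to ~1e-6).

parse_booster <- function(bst, encoder) {
  dt <- xgboost::xgb.model.dt.tree(model = bst)
  cfg <- xgboost::xgb.config(bst)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  trees <- split(dt, dt$Tree)
  id2idx <- function(td) stats::setNames(seq_len(nrow(td)), td$ID)
  col_index <- stats::setNames(seq_along(encoder$colnames), encoder$colnames)
  parsed <- lapply(trees, function(td) {
    m <- id2idx(td)
    leaf <- td$Feature == "Leaf"
    list(
      feature = ifelse(leaf, -1L, as.integer(col_index[td$Feature]) - 1L),
      threshold = ifelse(leaf, 0, td$Split),
      yes = ifelse(leaf, -1L, as.integer(m[td$Yes]) - 1L),
      no = ifelse(leaf, -1L, as.integer(m[td$No]) - 1L),
      value = ifelse(leaf, td$Gain, 0),
      cover = td$Cover
    )
  })
  list(trees = unname(parsed), intercept = stats::qlogis(base_score))
}

#' Fit a gradient-boosted tree classifier with grid-search cross-validation
#'
#' Every grid candidate is scored by its mean cross-validated AUC on
#' stratified folds; the best candidate (ties broken toward the first grid
#' point in row-major grid order) is refit on the full training cohort.
#' Categorical features are handled internally (indicator encoding behind
#' the interface); the caller never one-hot encodes.
#'
#' @param train A [cohort()] with both classes present and no missing
#'   entries (run [impute_cohort()] first).
#' @param config A [model_config()].
#' @return An object of class `fitted_gbdt` (also `fitted_model`) exposing
#'   `predict(model, cohort, type = "margin" | "response")`, the chosen
#'   hyperparameters (`$chosen`), and the per-candidate CV table
#'   (`$cv_results`).
#' @export
fit_gbdt <- function(train, config = model_config()) {
  stopifnot(inherits(train, "cohort"), inherits(config, "model_config"))
  y <- train$outcome
  if (length(unique(y)) < 2L)
    stop("training outcome is single-class; cannot fit a classifier", call. = FALSE)
  encoder <- make_encoder(train$schema)
  X <- encode_features(train$features, train$schema, encoder)
  grid_df <- expand.grid(config$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  candidates <- lapply(seq_len(nrow(grid_df)), function(i) as.list(grid_df[i, , drop = FALSE]))

  cv_auc <- rep(NA_real_, length(candidates))
  if (length(candidates) > 1L) {
    folds <- stratified_folds(y, config$cv_folds, config$seed)
    for (ci in seq_along(candidates)) {
      aucs <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- folds != f
        bst <- fit_booster(X[tr, , drop = FALSE], y[tr], candidates[[ci]],
                           config$class_weight, config$seed)
        pred <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1L),
                        outputmargin = TRUE)
        auc_mw(pred, y[!tr])
      }, numeric(1))
      cv_auc[ci] <- mean(aucs)
    }
    best <- which.max(cv_auc)   # first index on ties
  } else best <- 1L

  chosen <- candidates[[best]]
  bst <- fit_booster(X, y, chosen, config$class_weight, config$seed)
  parsed <- parse_booster(bst, encoder)
  cv_results <- cbind(grid_df, cv_auc = cv_auc)
  structure(list(booster = bst, trees = parsed$trees,
                 intercept = parsed$intercept, encoder = encoder,
                 schema = train$schema, fingerprint = encoder$fingerprint,
                 chosen = chosen, cv_results = cv_results, config = config),
            class = c("fitted_gbdt", "fitted_model"))
}

check_model_cohort <- function(model, cohort) {
  if (!identical(model$fingerprint, schema_fingerprint(cohort$schema)))
    stop("cohort schema does not match the schema the model was trained on",
         call. = FALSE)
}

#' @export
predict.fitted_gbdt <- function(object, newdata, type = c("margin", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cohort")) {
    check_model_cohort(object, newdata)
    newdata <- newdata$features
  }
  X <- encode_features(newdata, object$schema, object$encoder)
  m <- ensemble_margin(object$trees, X) + object$intercept
  if (type == "margin") m else stats::plogis(m)
}

#' @export
print.fitted_gbdt <- function(x, ...) {
  cat("fitted_gbdt: ", length(x$trees), " trees; chosen hyperparameters: ",
      paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fit a main-effects logistic regression baseline
#'
#' The linear comparator for the nonlinearity analyses: a plain
#' main-effects logistic model on the (imputed) features, exposing the
#' same margin/probability predictor contract as [fit_gbdt()].
#'
#' @param train A [cohort()] with both classes and no missing entries.
#' @return An object of class `fitted_logistic` (also `fitted_model`).
#' @export
fit_logistic_baseline <- function(train) {
  stopifnot(inherits(train, "cohort"))
  y <- train$outcome
  if (length(unique(y)) < 2L)
    stop("training outcome is single-class; cannot fit a classifier", call. = FALSE)
  X <- logistic_design(train$features, train$schema)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(coef = coefs, design_cols = colnames(X),
                 train_means = colMeans(X), schema = train$schema,
                 fingerprint = schema_fingerprint(train$schema)),
            class = c("fitted_logistic", "fitted_model"))
}

# design matrix: continuous columns as-is, reference-coded category dummies
logistic_design <- function(features, schema) {
  cols <- list()
  for (s in schema) {
    col <- features[[s$name]]
    if (anyNA(col))
      stop("feature '", s$name, "' holds missing values; impute first", call. = FALSE)
    if (s$kind == "continuous") {
      cols[[s$name]] <- as.numeric(col)
    } else {
      col <- factor(as.character(col), levels = s$categories)
      for (cat in s$categories[-1])
        cols[[paste0(s$name, "=", cat)]] <- as.numeric(col == cat)
    }
  }
  do.call(cbind, cols)
}

#' @export
predict.fitted_logistic <- function(object, newdata, type = c("margin", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cohort")) {
    check_model_cohort(object, newdata)
    newdata <- newdata$features
  }
  X <- logistic_design(newdata, object$schema)
  m <- drop(cbind(1, X[, object$design_cols, drop = FALSE]) %*% object$coef)
  if (type == "margin") m else stats::plogis(m)
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat("fitted_logistic: main-effects logistic baseline, ",
      length(x$coef) - 1L, " coefficients\n", sep = "")
  invisible(x)
}
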