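#' Per-sample Shapley attributions in margin (log-odds) space
#'
#' Decomposes every prediction additively: for each sample,
#' `base_value + sum(values[i, ]) == margin(x_i)` ("local accuracy").
#' Tree-ensemble attributions use the exact polynomial-time tree-path
#' algorithm over the parsed trees in double precision, so the identity
#' holds to ~1e-12; attributions of the internal indicator columns of a
#' categorical feature are summed back onto the clinical feature. For the
#' logistic baseline the decomposition is the exact linear one,
#' `beta_j * (x_ij - mean_j)` around the training means.
#'
#' Margin (log-odds) space is used rather than probability space because
#' additivity is exact there, and interval scoring later relies on summing
#' attributions.
#'
#' @param model A `fitted_gbdt` or `fitted_logistic`.
#' @param cohort A [cohort()] with the model's schema and no missing
#'   entries (impute first).
#' @return An object of class `attribution_set`: list with `values`
#'   (n x p matrix, columns = schema features), `base_value`,
#'   `feature_names`, `sample_index`.
#' @export
compute_attributions <- function(model, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  check_model_cohort(model, cohort)
  UseMethod("compute_attributions")
}

#' @export
compute_attributions.fitted_gbdt <- function(model, cohort) {
  X <- encode_features(cohort$features, model$schema, model$encoder)
  phi_enc <- ensemble_shap(model$trees, X)
  nms <- schema_names(model$schema)
  values <- matrix(0, nrow(X), length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms))
    values[, j] <- rowSums(phi_enc[, model$encoder$group == j, drop = FALSE])
  base <- model$intercept + sum(ensemble_expected_value(model$trees))
  attribution_set(values, base)
}

#' @export
compute_attributions.fitted_logistic <- function(model, cohort) {
  X <- logistic_design(cohort$features, model$schema)
  X <- X[, model$design_cols, drop = FALSE]
  beta <- model$coef[-1]
  centered <- sweep(X, 2, model$train_means)
  contrib <- sweep(centered, 2, beta, `*`)
  nms <- schema_names(model$schema)
  values <- matrix(0, nrow(X), length(nms), dimnames = list(NULL, nms))
  owner <- sub("=.*$", "", model$design_cols)
  for (j in seq_along(nms))
    values[, j] <- rowSums(contrib[, owner == nms[j], drop = FALSE])
  base <- model$coef[1] + sum(beta * model$train_means)
  attribution_set(values, base)
}

attribution_set <- function(values, base_value) {
  structure(list(values = values, base_value = base_value,
                 feature_names = colnames(values),
                 sample_index = seq_len(nrow(values))),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat("attribution_set: ", nrow(x$values), " samples x ", ncol(x$values),
      " features; base value ", sprintf("%.4f", x$base_value), "\n", sep = "")
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param attrs An [compute_attributions()] result.
#' @param top_k Optional cut: keep only the `top_k` most important
#'   features. By default all features are kept — the scorecard covers the
#'   full schema.
#' @return A data.frame with columns `feature` and `importance`, in
#'   descending importance; ties broken by schema (column) order.
#' @export
rank_features <- function(attrs, top_k = NULL) {
  stopifnot(inherits(attrs, "attribution_set"))
  imp <- colMeans(abs(attrs$values))
  ord <- order(-imp, seq_along(imp))
  out <- data.frame(feature = attrs$feature_names[ord],
                    importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  out
}

#' Dependence profile of one feature
#'
#' The (feature value, attribution) scatter across all samples, sorted by
#' value ascending (sample index breaks ties), i.e. the data behind a
#' Shapley dependence plot. Nonlinearity of the model's response to a
#' feature appears as slope changes in this profile.
#'
#' @param attrs An [compute_attributions()] result.
#' @param cohort The cohort the attributions were computed on.
#' @param feature Feature name.
#' @return An object of class `dependence_profile`: data.frame with
#'   columns `value`, `attribution`, `sample`, plus attributes `feature`,
#'   `kind`, and `degenerate` (all samples share one value).
#' @export
dependence_profile <- function(attrs, cohort, feature) {
  stopifnot(inherits(attrs, "attribution_set"), inherits(cohort, "cohort"))
  if (!feature %in% attrs$feature_names)
    stop("unknown feature '", feature, "'", call. = FALSE)
  spec <- cohort$schema[[feature]]
  vals <- cohort$features[[feature]]
  if (spec$kind == "categorical") vals <- as.character(vals)
  av <- attrs$values[, feature]
  ord <- order(vals, seq_along(vals))
  df <- data.frame(value = vals[ord], attribution = av[ord], sample = ord,
                   stringsAsFactors = FALSE)
  structure(df, feature = feature, kind = spec$kind,
            degenerate = length(unique(vals)) < 2L,
            class = c("dependence_profile", "data.frame"))
}
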