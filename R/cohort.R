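#' Declare a single cohort feature
#'
#' A feature specification records everything the pipeline needs to know
#' about one column of a cohort: its name, whether it is continuous or
#' categorical, its measurement units, and (for the simulator) the
#' distribution it is drawn from.
#'
#' @param name Feature name (a syntactically unique identifier).
#' @param kind `"continuous"` or `"categorical"`.
#' @param units Free-text measurement units (e.g. `"g/dL"`); purely
#'   descriptive.
#' @param categories Ordered character vector of legal category labels
#'   (categorical features only, at least two).
#' @param distribution Sampling distribution used by [generate_cohort()]:
#'   one of [dist_normal()], [dist_uniform()] or [dist_multinomial()].
#'   Optional for cohorts that are only read from files.
#' @return An object of class `feature_spec`.
#' @seealso [feature_schema()], [generate_cohort()]
#' @export
feature_spec <- function(name, kind = c("continuous", "categorical"),
                         units = "", categories = NULL, distribution = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical feature '", name, "' needs at least two categories", call. = FALSE)
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("duplicate categories in feature '", name, "'", call. = FALSE)
  } else if (!is.null(categories)) {
    stop("continuous feature '", name, "' cannot declare categories", call. = FALSE)
  }
  if (!is.null(distribution)) {
    if (!inherits(distribution, "feature_dist"))
      stop("distribution must be built with dist_normal()/dist_uniform()/dist_multinomial()", call. = FALSE)
    if (kind == "categorical") {
      if (distribution$type != "multinomial")
        stop("categorical feature '", name, "' needs a multinomial distribution", call. = FALSE)
      if (length(distribution$probs) != length(categories))
        stop("feature '", name, "': probs length must match categories", call. = FALSE)
    } else if (distribution$type == "multinomial") {
      stop("continuous feature '", name, "' cannot use a multinomial distribution", call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind, units = units,
                 categories = categories, distribution = distribution),
            class = "feature_spec")
}

#' Sampling distributions for simulated features
#'
#' Small constructors describing how [generate_cohort()] draws a feature.
#'
#' @param mu,sigma Mean and standard deviation (`sigma > 0`).
#' @param lo,hi Uniform bounds (`hi > lo`).
#' @param probs Category probabilities, summing to 1 (tolerance 1e-12).
#' @return An object of class `feature_dist`.
#' @name feature_dist
#' @export
dist_normal <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(type = "normal", mu = mu, sigma = sigma), class = "feature_dist")
}

#' @rdname feature_dist
#' @export
dist_uniform <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi))
  if (hi <= lo) stop("hi must be > lo", call. = FALSE)
  structure(list(type = "uniform", lo = lo, hi = hi), class = "feature_dist")
}

#' @rdname feature_dist
#' @export
dist_multinomial <- function(probs) {
  probs <- as.numeric(probs)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  structure(list(type = "multinomial", probs = probs), class = "feature_dist")
}

#' Bundle feature specifications into a schema
#'
#' @param specs A list of [feature_spec()] objects (or several specs passed
#'   as `...`).
#' @return An object of class `feature_schema`: a named list of specs in
#'   declaration order. Declaration order is meaningful — it is the
#'   tie-break used by [rank_features()].
#' @export
feature_schema <- function(specs) {
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  stopifnot(is.list(specs), length(specs) >= 1L)
  ok <- vapply(specs, inherits, logical(1), "feature_spec")
  if (!all(ok)) stop("all elements must be feature_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate feature names in schema", call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat("feature_schema: ", length(x), " features (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "categorical"), " categorical)\n", sep = "")
  invisible(x)
}

schema_names <- function(schema) unname(vapply(schema, `[[`, character(1), "name"))
schema_kinds <- function(schema) unname(vapply(schema, `[[`, character(1), "kind"))

#' A fingerprint identifying a schema's shape
#'
#' Used to check that a cohort fed to a fitted model matches the schema the
#' model was trained on.
#' @param schema A [feature_schema()].
#' @return A single string.
#' @export
schema_fingerprint <- function(schema) {
  parts <- vapply(schema, function(s) {
    cats <- if (is.null(s$categories)) "" else paste(s$categories, collapse = "|")
    paste(s$name, s$kind, cats, sep = ":")
  }, character(1))
  paste(parts, collapse = ";")
}

#' Construct a cohort object
#'
#' A cohort is the universal tabular input of the pipeline: one row per
#' patient, typed feature columns, and a binary outcome. Missing values are
#' represented by `NA` (never by a numeric sentinel, which could collide
#' with legal laboratory values).
#'
#' @param features A data.frame whose columns match `schema` (continuous
#'   columns numeric, categorical columns factors with the schema's
#'   levels).
#' @param outcome Integer/numeric vector of 0/1 labels, one per row.
#' @param schema A [feature_schema()].
#' @param provenance Optional list recording how the cohort was produced
#'   (seed, risk specification, ...).
#' @return An object of class `cohort`.
#' @export
cohort <- function(features, outcome, schema, provenance = list()) {
  stopifnot(is.data.frame(features))
  if (!inherits(schema, "feature_schema")) stop("schema must be a feature_schema", call. = FALSE)
  nms <- schema_names(schema)
  if (!identical(sort(names(features)), sort(nms)))
    stop("feature columns do not match schema names", call. = FALSE)
  features <- features[, nms, drop = FALSE]
  n <- nrow(features)
  if (n < 1L) stop("cohort must contain at least one row", call. = FALSE)
  outcome <- as.integer(outcome)
  if (length(outcome) != n || anyNA(outcome) || !all(outcome %in% c(0L, 1L)))
    stop("outcome must be a 0/1 vector with one entry per row", call. = FALSE)
  for (s in schema) {
    col <- features[[s$name]]
    if (s$kind == "continuous") {
      if (!is.numeric(col))
        stop("column '", s$name, "' must be numeric (continuous)", call. = FALSE)
    } else {
      col <- factor(as.character(col), levels = s$categories)
      bad <- !is.na(features[[s$name]]) & is.na(col)
      if (any(bad))
        stop("column '", s$name, "' holds categories outside the schema (first bad row ",
             which(bad)[1], ")", call. = FALSE)
      features[[s$name]] <- col
    }
  }
  structure(list(features = features, outcome = outcome, schema = schema,
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", nrow(x$features), " patients x ", ncol(x$features),
      " features; outcome prevalence ",
      sprintf("%.4f", mean(x$outcome)), "\n", sep = "")
  nmiss <- sum(is.na(x$features))
  if (nmiss > 0) cat("  missing entries: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$features)

# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
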