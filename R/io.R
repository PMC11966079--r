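#' Write / read a feature schema as JSON
#'
#' @param schema A [feature_schema()].
#' @param path File path.
#' @return `read_schema()` returns a [feature_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @name schema_io
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  specs <- lapply(unname(schema), function(s) {
    out <- list(name = s$name, kind = s$kind, units = s$units)
    if (!is.null(s$categories)) out$categories <- s$categories
    if (!is.null(s$distribution)) out$distribution <- unclass(s$distribution)
    out
  })
  jsonlite::write_json(specs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname schema_io
#' @export
read_schema <- function(path) {
  specs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  feature_schema(lapply(specs, function(s) {
    dist <- NULL
    if (!is.null(s$distribution)) {
      d <- s$distribution
      dist <- switch(d$type,
        normal = dist_normal(d$mu, d$sigma),
        uniform = dist_uniform(d$lo, d$hi),
        multinomial = dist_multinomial(unlist(d$probs)),
        stop("unknown distribution type '", d$type, "'", call. = FALSE))
    }
    feature_spec(s$name, s$kind, units = s$units %||% "",
                 categories = if (!is.null(s$categories)) unlist(s$categories),
                 distribution = dist)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort as CSV with a JSON schema sidecar
#'
#' Missing entries are written as empty cells and read back as `NA`. The
#' outcome occupies the `outcome` column; all other columns must match the
#' schema exactly (a stray or missing column is an error naming it).
#'
#' @param cohort A [cohort()].
#' @param csv_path Path of the CSV file.
#' @param schema_path Path of the JSON schema sidecar.
#' @param schema A [feature_schema()] (for `read_cohort()`, when no
#'   `schema_path` is given).
#' @return `read_cohort()` returns a [cohort()]; `write_cohort()` returns
#'   `csv_path` invisibly.
#' @name cohort_io
#' @export
write_cohort <- function(cohort, csv_path, schema_path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cohort$features
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  df$outcome <- cohort$outcome
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  if (!is.null(schema_path)) write_schema(cohort$schema, schema_path)
  invisible(csv_path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(csv_path, schema_path = NULL, schema = NULL) {
  if (is.null(schema)) {
    if (is.null(schema_path)) stop("provide schema_path or schema", call. = FALSE)
    schema <- read_schema(schema_path)
  }
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, na.strings = "")
  if (!"outcome" %in% names(df))
    stop("cohort CSV lacks an 'outcome' column", call. = FALSE)
  outcome <- df$outcome
  if (anyNA(outcome) || !all(outcome %in% c(0, 1)))
    stop("outcome column must be binary 0/1 without missing entries", call. = FALSE)
  df$outcome <- NULL
  stray <- setdiff(names(df), schema_names(schema))
  if (length(stray))
    stop("cohort CSV holds column(s) not in the schema: ",
         paste(stray, collapse = ", "), call. = FALSE)
  absent <- setdiff(schema_names(schema), names(df))
  if (length(absent))
    stop("cohort CSV lacks schema column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (s in schema)
    if (s$kind == "categorical")
      df[[s$name]] <- factor(as.character(df[[s$name]]), levels = s$categories)
  cohort(df, outcome, schema)
}

SCORECARD_FORMAT_VERSION <- 1L

#' Write / read a scorecard as canonical JSON
#'
#' The JSON round trip is lossless (numbers serialized at full precision)
#' and versioned; a file missing its normalization constants or carrying
#' an unknown format version is rejected. Serialization is deterministic:
#' identical scorecards produce byte-identical files.
#'
#' @param card A [build_scorecard()] result.
#' @param path File path.
#' @return `read_scorecard()` returns a `scorecard`; `write_scorecard()`
#'   returns `path` invisibly.
#' @name scorecard_io
#' @export
write_scorecard <- function(card, path) {
  stopifnot(inherits(card, "scorecard"))
  e <- card$entries
  # JSON has no +-Inf: unbounded segment edges travel as strings; 17
  # significant digits round-trip every finite double exactly
  e$lo <- ifelse(is.na(e$lo), NA_character_, sprintf("%.17g", e$lo))
  e$hi <- ifelse(is.na(e$hi), NA_character_, sprintf("%.17g", e$hi))
  payload <- list(format_version = SCORECARD_FORMAT_VERSION,
                  raw_min = card$raw_min, raw_max = card$raw_max,
                  provenance = card$provenance,
                  entries = e)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname scorecard_io
#' @export
read_scorecard <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format_version) ||
      payload$format_version != SCORECARD_FORMAT_VERSION)
    stop("unsupported or missing scorecard format version", call. = FALSE)
  if (is.null(payload$raw_min) || is.null(payload$raw_max))
    stop("scorecard file lacks its normalization constants", call. = FALSE)
  e <- as.data.frame(payload$entries, stringsAsFactors = FALSE)
  for (nm in c("lo", "hi", "raw_score", "normalized_score"))
    e[[nm]] <- as.numeric(e[[nm]])
  e$lo[is.na(e$lo) & e$kind == "continuous"] <- NA  # keep NA for categorical
  structure(list(entries = e, raw_min = payload$raw_min,
                 raw_max = payload$raw_max,
                 provenance = payload$provenance),
            class = "scorecard")
}

#' Human-readable score table
#'
#' Renders the scorecard as a presentation table: one row per segment,
#' with interval text such as `"2.40-3.50"` (unbounded edges shown as
#' `"< x"` / `">= x"`) and scores rounded to 2 decimals.
#'
#' @param card A scorecard.
#' @param digits Rounding for the displayed scores (default 2).
#' @return A data.frame with columns `feature`, `interval`, `score`,
#'   `n_points`, `filled`.
#' @export
scorecard_table <- function(card, digits = 2) {
  stopifnot(inherits(card, "scorecard"))
  e <- card$entries
  fmt <- function(x) sprintf("%.2f", x)
  interval <- ifelse(e$kind == "categorical", e$category,
              ifelse(is.infinite(e$lo) & is.infinite(e$hi), "any",
              ifelse(is.infinite(e$lo), paste0("< ", fmt(e$hi)),
              ifelse(is.infinite(e$hi), paste0(">= ", fmt(e$lo)),
                     paste0(fmt(e$lo), "–", fmt(e$hi))))))
  data.frame(feature = e$feature, interval = interval,
             score = round(e$normalized_score, digits),
             n_points = e$n_points, filled = e$filled,
             stringsAsFactors = FALSE)
}

#' Export an attribution set as CSV
#'
#' One row per sample: the per-feature attribution columns plus a
#' `base_value` column, for external plotting or auditing.
#'
#' @param attrs An [compute_attributions()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(attrs, path) {
  stopifnot(inherits(attrs, "attribution_set"))
  df <- as.data.frame(attrs$values)
  df$base_value <- attrs$base_value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
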