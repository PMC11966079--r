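#' Mean/mode imputation with a frozen imputation table
#'
#' Continuous missing entries are replaced by the mean of the observed
#' entries of their column; categorical missing entries by the mode (ties
#' broken toward the first schema category). The per-feature imputation
#' values are returned so that exactly the same values can be re-applied
#' to validation or external data via [apply_imputation()] — the table is
#' frozen on the training data to avoid leakage.
#'
#' @param cohort A [cohort()]. Every feature must have at least one
#'   observed value.
#' @return A list with elements `cohort` (imputed) and `table` (an
#'   `imputation_table`: named list of fill values).
#' @export
impute_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  tab <- list()
  for (s in cohort$schema) {
    col <- cohort$features[[s$name]]
    obs <- col[!is.na(col)]
    if (length(obs) == 0L)
      stop("feature '", s$name, "' is fully missing; cannot impute", call. = FALSE)
    if (s$kind == "continuous") {
      tab[[s$name]] <- mean(as.numeric(obs))
    } else {
      counts <- table(factor(obs, levels = s$categories))
      tab[[s$name]] <- names(counts)[which.max(counts)]
    }
  }
  tab <- structure(tab, class = "imputation_table")
  list(cohort = apply_imputation(cohort, tab), table = tab)
}

#' Apply a frozen imputation table to a cohort
#'
#' @param cohort A [cohort()].
#' @param table An `imputation_table` from [impute_cohort()] covering every
#'   schema feature.
#' @return The cohort with all missing entries filled.
#' @export
apply_imputation <- function(cohort, table) {
  stopifnot(inherits(cohort, "cohort"), inherits(table, "imputation_table"))
  missing_feat <- setdiff(schema_names(cohort$schema), names(table))
  if (length(missing_feat))
    stop("imputation table lacks feature(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  for (s in cohort$schema) {
    col <- cohort$features[[s$name]]
    na <- is.na(col)
    if (any(na)) {
      fill <- table[[s$name]]
      if (s$kind == "continuous") col[na] <- as.numeric(fill)
      else col[na] <- factor(fill, levels = s$categories)
      cohort$features[[s$name]] <- col
    }
  }
  cohort
}

#' Stratified train/test split
#'
#' Rows are partitioned into a training set of `round(f * n)` rows and a
#' test set of the remainder, stratified on the outcome so that the rare
#' class is represented proportionally on both sides (with a 0.4%
#' prevalence an unstratified split can easily starve the test set of
#' cases). The split is seeded and reproducible.
#'
#' @param cohort A [cohort()] with both classes present (each with at
#'   least 2 members).
#' @param train_fraction Training proportion in `(0, 1)` (default 0.70).
#' @param seed Integer seed.
#' @return A list with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"),
            train_fraction > 0, train_fraction < 1)
  y <- cohort$outcome
  n <- length(y)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("both outcome classes need at least 2 members to stratify", call. = FALSE)
  n_train <- round(train_fraction * n)
  n1 <- sum(y == 1L)
  n_train_cases <- round(train_fraction * n1)
  n_train_cases <- min(max(n_train_cases, 1L), n1 - 1L)
  n_train_controls <- n_train - n_train_cases
  idx <- with_seed(seed, {
    cases <- sample(which(y == 1L))
    controls <- sample(which(y == 0L))
    sort(c(cases[seq_len(n_train_cases)], controls[seq_len(n_train_controls)]))
  })
  subset_cohort <- function(keep) {
    cohort(cohort$features[keep, , drop = FALSE], cohort$outcome[keep],
           cohort$schema, cohort$provenance)
  }
  list(train = subset_cohort(idx), test = subset_cohort(setdiff(seq_len(n), idx)))
}
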