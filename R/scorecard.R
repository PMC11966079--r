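#' Turn change points into covering half-open intervals
#'
#' `k` points yield `k + 1` segments: `(-Inf, p1)`, `[p1, p2)`, ...,
#' `[pk, Inf)`. The unbounded edges guarantee that any future patient
#' value — including values outside the training range — maps to exactly
#' one segment; the half-open convention removes boundary double-counting.
#'
#' @param cps A [detect_changepoints()] result, or a sorted numeric vector
#'   of points (possibly empty).
#' @param observed_range Optional length-2 numeric; when given, points are
#'   checked to lie strictly inside it.
#' @return A data.frame with columns `lo` and `hi`, one row per segment.
#' @export
build_intervals <- function(cps, observed_range = NULL) {
  points <- if (inherits(cps, "changepoint_set")) cps$points else as.numeric(cps)
  if (length(points) && any(diff(points) <= 0))
    stop("change points must be strictly increasing", call. = FALSE)
  if (!is.null(observed_range) && length(points) &&
      (any(points <= observed_range[1]) || any(points >= observed_range[2])))
    stop("change points must lie strictly inside the observed range", call. = FALSE)
  lo <- c(-Inf, points)
  hi <- c(points, Inf)
  data.frame(lo = lo, hi = hi)
}

segment_of <- function(values, lo) {
  # segments are [lo_i, hi_i) with lo_1 = -Inf; findInterval on the finite
  # cut points returns the half-open segment index directly
  findInterval(values, lo[-1]) + 1L
}

#' Score segments by summed in-segment attributions
#'
#' Implements interval scoring: the raw score of a segment is the sum of
#' the attributions of the training samples whose feature value falls in
#' it (so raw scores conserve each feature's attribution column sum
#' exactly). Categories of a categorical feature are their own segments.
#' Segments containing no training sample are flagged unscored; they
#' receive a value later via [fill_missing_intervals()].
#'
#' @param attrs An [compute_attributions()] result on the training cohort.
#' @param cohort The (imputed) training cohort, aligned with `attrs`.
#' @param segments Named list: for each continuous feature, a data.frame
#'   of `lo`/`hi` segments from [build_intervals()]. Continuous features
#'   absent from the list get a single all-covering segment.
#' @return A data.frame of raw interval scores with columns `feature`,
#'   `kind`, `lo`, `hi`, `category`, `raw_score`, `n_points`, `scored`.
#' @export
score_intervals <- function(attrs, cohort, segments = list()) {
  stopifnot(inherits(attrs, "attribution_set"), inherits(cohort, "cohort"))
  if (nrow(attrs$values) != nrow(cohort$features))
    stop("attribution set and cohort are not aligned", call. = FALSE)
  out <- list()
  for (s in cohort$schema) {
    av <- attrs$values[, s$name]
    col <- cohort$features[[s$name]]
    if (s$kind == "continuous") {
      seg <- segments[[s$name]]
      if (is.null(seg)) seg <- build_intervals(numeric(0))
      if (any(seg$lo[-1] != seg$hi[-nrow(seg)]) || any(diff(seg$lo) <= 0))
        stop("segments of '", s$name, "' must be disjoint, ordered and covering",
             call. = FALSE)
      idx <- segment_of(as.numeric(col), seg$lo)
      raw <- as.numeric(tapply(av, factor(idx, levels = seq_len(nrow(seg))), sum))
      np <- tabulate(idx, nbins = nrow(seg))
      out[[s$name]] <- data.frame(
        feature = s$name, kind = "continuous", lo = seg$lo, hi = seg$hi,
        category = NA_character_, raw_score = ifelse(np > 0, raw, NA_real_),
        n_points = np, scored = np > 0, stringsAsFactors = FALSE)
    } else {
      f <- factor(as.character(col), levels = s$categories)
      raw <- as.numeric(tapply(av, f, sum))
      np <- as.integer(table(f))
      out[[s$name]] <- data.frame(
        feature = s$name, kind = "categorical", lo = NA_real_, hi = NA_real_,
        category = s$categories, raw_score = ifelse(np > 0, raw, NA_real_),
        n_points = np, scored = np > 0, stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, out)
  rownames(entries) <- NULL
  entries
}

#' Min-max normalize raw interval scores onto a unified 0-100 scale
#'
#' Normalization is global across all features — the overall minimum raw
#' score maps to 0 and the overall maximum to 100 — so that interval
#' scores of different features are directly comparable and the feature
#' with the widest attribution range carries the most weight. Unscored
#' (empty) segments are excluded from the normalization constants.
#'
#' @param entries Raw interval scores from [score_intervals()].
#' @param provenance Optional provenance list stored on the scorecard.
#' @return An object of class `scorecard`.
#' @export
normalize_scores <- function(entries, provenance = list()) {
  raw <- entries$raw_score[entries$scored]
  if (length(raw) < 1L) stop("no scored segments to normalize", call. = FALSE)
  rmin <- min(raw); rmax <- max(raw)
  if (rmax - rmin <= 0) {
    warning("all raw interval scores are identical; the model is degenerate ",
            "and every score is set to 50", call. = FALSE)
    entries$normalized_score <- ifelse(entries$scored, 50, NA_real_)
  } else {
    entries$normalized_score <-
      ifelse(entries$scored, 100 * (entries$raw_score - rmin) / (rmax - rmin),
             NA_real_)
  }
  entries$filled <- FALSE
  structure(list(entries = entries, raw_min = rmin, raw_max = rmax,
                 provenance = provenance),
            class = "scorecard")
}

#' Fill unscored segments from their neighbours
#'
#' Segments with no training data receive the mean of the normalized
#' scores of their immediately adjacent segments (an edge segment has a
#' single neighbour, whose score is used directly). If any immediately
#' adjacent segment is itself unscored, the fallback widens to the entire
#' range of the feature: the mean over all its scored segments. Filled
#' scores are flagged and never enter the normalization constants.
#'
#' @param card A [normalize_scores()] result.
#' @return The scorecard with every segment scored and `filled` flags set.
#' @export
fill_missing_intervals <- function(card) {
  stopifnot(inherits(card, "scorecard"))
  e <- card$entries
  for (feat in unique(e$feature)) {
    rows <- which(e$feature == feat)
    scored <- e$scored[rows]
    if (!any(scored))
      stop("feature '", feat, "' has no scored segment at all", call. = FALSE)
    feat_mean <- mean(e$normalized_score[rows][scored])
    for (k in which(!scored)) {
      nb <- c(if (k > 1L) k - 1L, if (k < length(rows)) k + 1L)
      fill <- if (length(nb) && all(scored[nb]))
        mean(e$normalized_score[rows][nb]) else feat_mean
      e$normalized_score[rows[k]] <- fill
      e$filled[rows[k]] <- TRUE
    }
  }
  card$entries <- e
  card
}

#' @export
print.scorecard <- function(x, ...) {
  cat("scorecard: ", length(unique(x$entries$feature)), " features, ",
      nrow(x$entries), " segments; raw range [",
      sprintf("%.4g", x$raw_min), ", ", sprintf("%.4g", x$raw_max), "]\n",
      sep = "")
  if (any(x$entries$filled))
    cat("  ", sum(x$entries$filled), " segment(s) filled by neighbour averaging\n",
        sep = "")
  invisible(x)
}

#' Build a complete scorecard from a fitted model and training cohort
#'
#' Orchestrates the scoring pipeline: Shapley attributions, per-feature
#' dependence profiles, quantile binning, slope-change-point detection
#' (at most `k_max` points per continuous feature), interval construction,
#' attribution-sum scoring, global 0-100 normalization, and empty-interval
#' filling. Categorical features bypass change-point detection — each
#' category is its own segment. Continuous features whose binned profile
#' is too short for slope estimation (fewer than 3 bins, or a single
#' observed value) fall back to one all-covering segment.
#'
#' @param model A `fitted_gbdt` (or any model with attribution support).
#' @param cohort The imputed training cohort.
#' @param attrs Optional precomputed [compute_attributions()] result.
#' @param n_bins,min_bin_count Binning parameters, see [bin_profile()].
#' @param k_max,epsilon Detection parameters, see [detect_changepoints()].
#' @return A `scorecard` whose provenance records the model fingerprint
#'   and the change-point configuration, plus a `changepoints` element
#'   (named list of [detect_changepoints()] results per continuous
#'   feature).
#' @export
build_scorecard <- function(model, cohort, attrs = NULL, n_bins = 50L,
                            min_bin_count = NULL, k_max = 5L, epsilon = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(attrs)) attrs <- compute_attributions(model, cohort)
  segments <- list()
  cps <- list()
  for (s in cohort$schema) {
    if (s$kind != "continuous") next
    prof <- dependence_profile(attrs, cohort, s$name)
    points <- numeric(0)
    if (!isTRUE(attr(prof, "degenerate")) && k_max > 0L) {
      binned <- bin_profile(prof, n_bins = n_bins, min_bin_count = min_bin_count)
      if (length(binned$centers) >= 3L) {
        cp <- detect_changepoints(binned, k_max = k_max, epsilon = epsilon)
        cps[[s$name]] <- cp
        points <- cp$points
      }
    }
    segments[[s$name]] <- build_intervals(points)
  }
  entries <- score_intervals(attrs, cohort, segments)
  prov <- list(model_fingerprint = model$fingerprint,
               changepoint_config = list(n_bins = n_bins,
                                         min_bin_count = min_bin_count,
                                         k_max = k_max, epsilon = epsilon),
               n_train = nrow(cohort$features),
               package_version = as.character(utils::packageVersion("shapcard")))
  card <- normalize_scores(entries, provenance = prov)
  card <- fill_missing_intervals(card)
  card$changepoints <- cps
  card
}

#' Total patient score from per-feature assigned scores
#'
#' The aggregation step of scorecard application: a patient's total risk
#' score is the plain (unweighted) sum of the per-feature scores assigned
#' by the scorecard.
#'
#' @param feature_scores A named numeric vector (one patient) or a numeric
#'   matrix / data.frame with one column per feature (one row per
#'   patient).
#' @return A numeric vector of totals, one per patient.
#' @export
total_score <- function(feature_scores) {
  if (is.data.frame(feature_scores)) feature_scores <- as.matrix(feature_scores)
  if (is.matrix(feature_scores)) {
    stopifnot(is.numeric(feature_scores))
    rowSums(feature_scores)
  } else {
    stopifnot(is.numeric(feature_scores))
    sum(feature_scores)
  }
}

#' Apply a scorecard to patient records
#'
#' For each patient and each scorecard feature, the segment containing the
#' patient's value (or the matching category) is located and its
#' normalized score assigned; the total is the exact sum of the assigned
#' per-feature scores. Values outside the training range fall into the
#' unbounded edge segments. An unseen category receives the feature-wide
#' mean of scored segments, with a warning (the same fallback philosophy
#' as empty-interval filling). Missing values are an error — apply the
#' frozen training imputation table ([apply_imputation()]) first.
#'
#' @param card A [build_scorecard()] result.
#' @param patients A data.frame of patient records (or a [cohort()]);
#'   every scorecard feature must be present.
#' @return An object of class `patient_scores`: data.frame with one row
#'   per patient, one column per feature, and a `total` column.
#' @export
apply_scorecard <- function(card, patients) {
  stopifnot(inherits(card, "scorecard"))
  if (inherits(patients, "cohort")) patients <- patients$features
  stopifnot(is.data.frame(patients))
  e <- card$entries
  feats <- unique(e$feature)
  missing_feat <- setdiff(feats, names(patients))
  if (length(missing_feat))
    stop("patient records lack feature(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  n <- nrow(patients)
  scores <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (feat in feats) {
    rows <- e[e$feature == feat, , drop = FALSE]
    v <- patients[[feat]]
    if (anyNA(v))
      stop("feature '", feat, "' holds missing values; impute before scoring",
           call. = FALSE)
    if (rows$kind[1] == "continuous") {
      idx <- segment_of(as.numeric(v), rows$lo)
      scores[, feat] <- rows$normalized_score[idx]
    } else {
      idx <- match(as.character(v), rows$category)
      unseen <- is.na(idx)
      assigned <- rows$normalized_score[idx]
      if (any(unseen)) {
        warning(sum(unseen), " record(s) hold unseen categories for '", feat,
                "'; assigned the feature-wide mean score", call. = FALSE)
        assigned[unseen] <- mean(rows$normalized_score[rows$scored])
      }
      scores[, feat] <- assigned
    }
  }
  out <- as.data.frame(scores)
  out$total <- total_score(scores)
  out <- cbind(patient = seq_len(n), out)
  class(out) <- c("patient_scores", "data.frame")
  out
}
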