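#' Quantile-bin a dependence profile
#'
#' Raw dependence profiles are a noisy scatter; slopes are estimated on
#' quantile bins so every slope rests on comparable support. Bins with
#' fewer than `min_bin_count` samples are merged left-to-right into their
#' right neighbour (the last bin merges leftward).
#'
#' @param profile A [dependence_profile()] of a continuous feature with at
#'   least two distinct values.
#' @param n_bins Target number of quantile bins (default 50).
#' @param min_bin_count Minimum samples per bin; default
#'   `max(20, floor(n / 1000))`.
#' @return An object of class `binned_profile` (see [binned_profile()]).
#' @export
bin_profile <- function(profile, n_bins = 50L, min_bin_count = NULL) {
  stopifnot(inherits(profile, "dependence_profile"))
  if (attr(profile, "kind") != "continuous")
    stop("bin_profile applies to continuous features only; score each category directly",
         call. = FALSE)
  if (isTRUE(attr(profile, "degenerate")))
    stop("feature '", attr(profile, "feature"),
         "' has a single observed value; treat it as categorical", call. = FALSE)
  v <- profile$value
  a <- profile$attribution
  n <- length(v)
  if (is.null(min_bin_count)) min_bin_count <- max(20L, floor(n / 1000))
  edges <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L)
    stop("cannot form bins: all values identical", call. = FALSE)
  # half-open binning [e_i, e_{i+1}); top edge closed
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[bin == length(edges)] <- length(edges) - 1L
  counts <- tabulate(bin, nbins = length(edges) - 1L)

  # merge small bins into the right neighbour, scanning left to right
  group <- seq_along(counts)
  i <- 1L
  while (i <= length(counts)) {
    if (counts[i] < min_bin_count && length(counts) > 1L) {
      j <- if (i < length(counts)) i + 1L else i - 1L
      keep_lo <- min(i, j); drop_hi <- max(i, j)
      counts[keep_lo] <- counts[keep_lo] + counts[drop_hi]
      counts <- counts[-drop_hi]
      edges <- edges[-(drop_hi)]       # remove the internal edge between them
      group[group >= drop_hi] <- group[group >= drop_hi] - 1L
      if (j < i) i <- i - 1L
      # stay on the merged bin in case it is still too small
    } else i <- i + 1L
  }
  bin <- factor(group[bin], levels = seq_along(counts))
  centers <- as.numeric(tapply(v, bin, mean))
  means <- as.numeric(tapply(a, bin, mean))
  binned_profile(edges, centers, means, counts, feature = attr(profile, "feature"))
}

#' Construct a binned dependence profile directly
#'
#' Mostly used to build synthetic profiles with planted kinks; the
#' pipeline itself produces binned profiles via [bin_profile()].
#'
#' @param edges Strictly increasing bin edges (length = bins + 1).
#' @param centers Representative value per bin (strictly increasing).
#' @param mean_attribution Mean attribution per bin.
#' @param counts Sample count per bin.
#' @param feature Feature name.
#' @return An object of class `binned_profile`.
#' @export
binned_profile <- function(edges, centers, mean_attribution, counts, feature = "feature") {
  edges <- as.numeric(edges); centers <- as.numeric(centers)
  mean_attribution <- as.numeric(mean_attribution)
  counts <- as.integer(counts)
  m <- length(centers)
  stopifnot(length(edges) == m + 1L, length(mean_attribution) == m,
            length(counts) == m)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  if (any(diff(centers) <= 0)) stop("bin centers must be strictly increasing", call. = FALSE)
  structure(list(feature = feature, edges = edges, centers = centers,
                 mean_attribution = mean_attribution, counts = counts),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat("binned_profile of '", x$feature, "': ", length(x$centers),
      " bins over [", sprintf("%.4g", min(x$edges)), ", ",
      sprintf("%.4g", max(x$edges)), "]\n", sep = "")
  invisible(x)
}

#' Detect the steepest slope-change points of a binned profile
#'
#' Slopes are computed between consecutive bin centers from the bin mean
#' attributions; each interior bin is scored by the absolute change of
#' slope across it (the absolute second difference of the profile). The
#' up-to-`k_max` largest slope changes exceeding `epsilon` are kept,
#' subject to a minimum separation of one bin between selected points;
#' ties break toward the smaller feature value. Each selected point is
#' reported as the left edge of its bin, so a detected point lies within
#' one bin width of the underlying kink. A perfectly linear profile has
#' zero slope change everywhere and yields an empty set — linear features
#' contribute no change points, by design.
#'
#' @param binned A [binned_profile()] with at least 3 bins.
#' @param k_max Maximum number of points to return (default 5).
#' @param epsilon Slope-change detection threshold; default
#'   `0.1 * sd(slopes)` of the profile, which keeps purely linear (and
#'   near-linear) features from contributing spurious points.
#' @return An object of class `changepoint_set`: list with `feature`,
#'   `points` (ascending feature values, at most `k_max`), and
#'   `magnitudes` (the |slope change| at each point, same order).
#' @export
detect_changepoints <- function(binned, k_max = 5L, epsilon = NULL) {
  stopifnot(inherits(binned, "binned_profile"))
  m <- length(binned$centers)
  if (m < 3L) stop("need at least 3 bins to detect slope changes", call. = FALSE)
  k_max <- as.integer(k_max)
  slopes <- diff(binned$mean_attribution) / diff(binned$centers)
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(slopes)
  # candidate j = interior bin j, slope change across it
  cand_bins <- 2:(m - 1L)
  delta <- abs(slopes[cand_bins] - slopes[cand_bins - 1L])
  cand_points <- binned$edges[cand_bins]

  ord <- order(-delta, cand_points)
  chosen <- integer(0)
  for (idx in ord) {
    if (length(chosen) >= k_max) break
    if (delta[idx] <= epsilon) break           # sorted: the rest are smaller
    if (all(abs(cand_bins[idx] - cand_bins[chosen]) >= 2L))
      chosen <- c(chosen, idx)
  }
  o <- order(cand_points[chosen])
  structure(list(feature = binned$feature,
                 points = cand_points[chosen][o],
                 magnitudes = delta[chosen][o],
                 epsilon = epsilon, k_max = k_max),
            class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat("changepoint_set of '", x$feature, "': ", length(x$points),
      " point(s)", sep = "")
  if (length(x$points))
    cat(" at ", paste(sprintf("%.4g", x$points), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}
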