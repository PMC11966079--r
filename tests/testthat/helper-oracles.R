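# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Exhaustive k-segment least-squares breakpoints on a binned profile.
# A boundary b means "segment break between bin b-1 and bin b"; the returned
# points are the corresponding bin edges. Ties break toward the
# lexicographically smallest boundary set (i.e. the smallest feature values).
segmented_ls_breakpoints <- function(binned, k) {
  x <- binned$centers
  y <- binned$mean_attribution
  m <- length(x)
  stopifnot(k >= 1, m >= k + 1)
  sse_seg <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    if (length(xs) < 3L) return(0)
    fit <- stats::lm.fit(cbind(1, xs), ys)
    sum(fit$residuals^2)
  }
  best <- NULL; best_sse <- Inf
  for (comb in utils::combn(2:m, k, simplify = FALSE)) {
    bounds <- c(1L, comb, m + 1L)
    sse <- 0
    for (s in seq_len(k + 1)) sse <- sse + sse_seg(bounds[s], bounds[s + 1] - 1L)
    if (sse < best_sse - 1e-10) { best_sse <- sse; best <- comb }
  }
  binned$edges[best]
}

# Noiseless piecewise-linear binned profile with kinks exactly at the
# centers of the bins listed in `kink_bins` (slope changes by `deltas`).
# Bins are unit-width with centers at i - 0.5 and edges 0..m.
kink_profile <- function(m, kink_bins, deltas, base_slope = 1,
                         feature = "x") {
  stopifnot(length(kink_bins) == length(deltas),
            all(kink_bins > 1), all(kink_bins < m))
  centers <- seq_len(m) - 0.5
  y <- base_slope * centers
  for (k in seq_along(kink_bins))
    y <- y + deltas[k] * pmax(0, centers - (kink_bins[k] - 0.5))
  binned_profile(0:m, centers, y, rep(100L, m), feature = feature)
}

# Brute-force Mann-Whitney AUC by explicit pair enumeration (ties = 1/2).
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Brute-force Youden maximizer over the same candidate set convention
# (midpoints between distinct scores, plus the minimum), via direct 2x2
# tabulation.
youden_scan <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) c(s[1], (s[-1] + s[-length(s)]) / 2) else s
  best_th <- cand[1]; best_j <- -Inf
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_th <- th }
  }
  list(threshold = best_th, j = best_j)
}
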