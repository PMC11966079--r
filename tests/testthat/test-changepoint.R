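make_profile <- function(values, attributions) {
  df <- data.frame(value = values, attribution = attributions,
                   sample = seq_along(values))
  df <- df[order(df$value, df$sample), ]
  structure(df, feature = "x", kind = "continuous",
            degenerate = length(unique(values)) < 2L,
            class = c("dependence_profile", "data.frame"))
}

test_that("quantile binning gives equal support and respects the merge rule", {
  set.seed(60)
  v <- runif(1000)
  prof <- make_profile(v, 2 * v)
  b <- bin_profile(prof, n_bins = 50, min_bin_count = 10)
  expect_true(all(abs(b$counts - 20) <= 1))
  expect_equal(sum(b$counts), 1000)
  expect_true(all(diff(b$edges) > 0))
  # n_bins = 1: a single bin holding everything, mean = overall mean
  b1 <- bin_profile(prof, n_bins = 1, min_bin_count = 1)
  expect_length(b1$centers, 1L)
  expect_equal(b1$mean_attribution, mean(2 * v))
  # heavy point mass: remaining bins merged up to min_bin_count
  v2 <- c(rep(0.5, 900), runif(100))
  b2 <- bin_profile(make_profile(v2, v2), n_bins = 20, min_bin_count = 15)
  expect_true(all(b2$counts >= 15))
  expect_true(any(b2$counts >= 900))
  expect_equal(sum(b2$counts), 1000)
  # degenerate profile refused
  expect_error(bin_profile(make_profile(rep(1, 50), rep(0, 50))), "categorical")
})

test_that("a linear profile yields no change points", {
  b <- kink_profile(20, kink_bins = integer(0), deltas = numeric(0),
                    base_slope = 2)
  cp <- detect_changepoints(b)
  expect_length(cp$points, 0)
})

test_that("noiseless kinks are recovered within one bin width", {
  b <- kink_profile(25, kink_bins = c(8, 17), deltas = c(3, -2))
  cp <- detect_changepoints(b)
  true_kinks <- c(8, 17) - 0.5
  expect_length(cp$points, 2)
  expect_true(all(abs(sort(cp$points) - sort(true_kinks)) <= 1))
  expect_equal(sort(cp$magnitudes, decreasing = TRUE), c(3, 2))
})

test_that("detection matches the exhaustive segmented least-squares oracle", {
  cases <- list(
    list(m = 12, bins = 5L, deltas = 2.5),
    list(m = 20, bins = c(6L, 14L), deltas = c(3, -1.5)),
    list(m = 30, bins = c(7L, 15L, 24L), deltas = c(2, -3, 1.2)),
    list(m = 30, bins = c(5L, 16L, 26L), deltas = c(-1, 2.5, -2))
  )
  for (cs in cases) {
    b <- kink_profile(cs$m, cs$bins, cs$deltas, base_slope = 0.5)
    cp <- detect_changepoints(b)
    expect_length(cp$points, length(cs$bins))
    oracle <- segmented_ls_breakpoints(b, k = length(cs$bins))
    expect_equal(sort(cp$points), sort(oracle))
  }
})

test_that("at most five points are returned, the five steepest", {
  deltas <- c(0.5, -4, 1, 6, -2, 3.5, -0.8, 5)
  bins <- c(4L, 8L, 12L, 16L, 20L, 24L, 28L, 32L)
  b <- kink_profile(36, bins, deltas)
  cp <- detect_changepoints(b, k_max = 5)
  expect_length(cp$points, 5)
  top5_bins <- bins[order(-abs(deltas))][1:5]
  expect_setequal(cp$points, b$edges[top5_bins])
  expect_setequal(round(cp$magnitudes, 10), sort(abs(deltas), decreasing = TRUE)[1:5])
  # cap property on arbitrary noisy profiles
  set.seed(61)
  for (r in 1:20) {
    m <- sample(10:40, 1)
    noisy <- binned_profile(0:m, seq_len(m) - 0.5, rnorm(m), rep(50L, m))
    expect_lte(length(detect_changepoints(noisy)$points), 5)
  }
})

test_that("selected points keep a minimum one-bin separation", {
  set.seed(62)
  for (r in 1:20) {
    m <- sample(12:40, 1)
    noisy <- binned_profile(0:m, seq_len(m) - 0.5, rnorm(m), rep(50L, m))
    cp <- detect_changepoints(noisy)
    if (length(cp$points) > 1) expect_true(all(diff(cp$points) >= 2))
  }
})

test_that("detection is equivariant under translation of feature values", {
  b <- kink_profile(20, c(6L, 13L), c(2, -3))
  cp <- detect_changepoints(b)
  shift <- 17.3
  b2 <- binned_profile(b$edges + shift, b$centers + shift,
                       b$mean_attribution, b$counts)
  cp2 <- detect_changepoints(b2)
  expect_equal(cp2$points, cp$points + shift)
  expect_equal(cp2$magnitudes, cp$magnitudes)
})

test_that("profiles with fewer than three bins are rejected", {
  b <- binned_profile(0:2, c(0.5, 1.5), c(0, 1), c(10L, 10L))
  expect_error(detect_changepoints(b), "3 bins")
})
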