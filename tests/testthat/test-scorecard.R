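test_that("change points become covering half-open segments", {
  expect_equal(build_intervals(numeric(0)), data.frame(lo = -Inf, hi = Inf))
  seg <- build_intervals(c(-1, 2))
  expect_equal(seg$lo, c(-Inf, -1, 2))
  expect_equal(seg$hi, c(-1, 2, Inf))
  seg5 <- build_intervals(1:5)
  expect_equal(nrow(seg5), 6)                        # 5 points -> 6 segments
  expect_equal(seg5$lo[-1], seg5$hi[-6])             # adjacent, disjoint
  expect_error(build_intervals(c(2, 1)), "strictly increasing")
  expect_error(build_intervals(c(0.5), observed_range = c(1, 2)), "inside")
})

simple_setup <- function() {
  schema <- feature_schema(list(
    feature_spec("x", "continuous"),
    feature_spec("g", "categorical", categories = c("A", "B"))))
  co <- cohort(data.frame(x = c(-2, -1, 0.5, 1, 3),
                          g = factor(c("A", "B", "A", "B", "A"),
                                     levels = c("A", "B"))),
               outcome = c(0, 0, 1, 0, 1), schema)
  vals <- cbind(x = c(0.1, -0.2, 0.3, 0.4, -0.5),
                g = c(0.05, -0.05, 0.05, -0.05, 0.05))
  attrs <- shapcard:::attribution_set(vals, base_value = -1)
  list(co = co, attrs = attrs)
}

test_that("interval scores are summed attributions and conserve column sums", {
  s <- simple_setup()
  segs <- list(x = build_intervals(c(0)))
  e <- score_intervals(s$attrs, s$co, segs)
  ex <- e[e$feature == "x", ]
  expect_equal(ex$raw_score, c(0.1 - 0.2, 0.3 + 0.4 - 0.5))
  expect_equal(ex$n_points, c(2L, 3L))
  # conservation per feature
  for (f in c("x", "g"))
    expect_equal(sum(e$raw_score[e$feature == f], na.rm = TRUE),
                 sum(s$attrs$values[, f]), tolerance = 1e-9)
  # empty segment flagged unscored with no numeric raw value
  e2 <- score_intervals(s$attrs, s$co, list(x = build_intervals(c(10, 20))))
  ex2 <- e2[e2$feature == "x", ]
  expect_equal(ex2$scored, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(ex2$raw_score[!ex2$scored])))
})

test_that("normalization maps the global extremes to 0 and 100", {
  e <- data.frame(feature = c("f", "f", "g"), kind = "continuous",
                  lo = NA, hi = NA, category = NA,
                  raw_score = c(-3, 1, 5), n_points = 1L, scored = TRUE)
  card <- normalize_scores(e)
  expect_equal(card$entries$normalized_score, c(0, 50, 100))
  expect_equal(card$raw_min, -3); expect_equal(card$raw_max, 5)
  # affine invariance under a constant shift of raw scores
  e2 <- e; e2$raw_score <- e2$raw_score + 42
  expect_equal(normalize_scores(e2)$entries$normalized_score,
               card$entries$normalized_score)
  # degenerate: all raw scores identical
  e3 <- e; e3$raw_score <- 7
  expect_warning(card3 <- normalize_scores(e3), "degenerate")
  expect_equal(card3$entries$normalized_score, c(50, 50, 50))
})

test_that("a binary feature holding both extremes scores 0 and 100", {
  e <- data.frame(feature = c("surg", "surg", "f"), kind = c("categorical",
                  "categorical", "continuous"), lo = NA, hi = NA,
                  category = c("no", "yes", NA),
                  raw_score = c(-10, 25, 3), n_points = 1L, scored = TRUE)
  card <- normalize_scores(e)
  expect_equal(card$entries$normalized_score[1:2], c(0, 100))
})

test_that("empty segments are filled from their neighbours", {
  mk <- function(raw, scored) {
    e <- data.frame(feature = "f", kind = "continuous",
                    lo = c(-Inf, 1, 2, 3, 4), hi = c(1, 2, 3, 4, Inf),
                    category = NA_character_, raw_score = raw,
                    n_points = ifelse(scored, 5L, 0L), scored = scored)
    normalize_scores(e)
  }
  # interior gap between 40 and 60 -> 50 (on the normalized scale)
  card <- mk(c(0, 40, NA, 60, 100), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  filled <- fill_missing_intervals(card)
  expect_equal(filled$entries$normalized_score[3], 50)
  expect_true(filled$entries$filled[3])
  # edge gap: the single adjacent segment's score is used directly
  card2 <- mk(c(NA, 40, 60, 80, 100), c(FALSE, TRUE, TRUE, TRUE, TRUE))
  f2 <- fill_missing_intervals(card2)
  expect_equal(f2$entries$normalized_score[1], f2$entries$normalized_score[2])
  # two consecutive gaps -> feature-wide mean over scored segments
  card3 <- mk(c(0, NA, NA, 60, 100), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  f3 <- fill_missing_intervals(card3)
  feat_mean <- mean(f3$entries$normalized_score[c(1, 4, 5)])
  expect_equal(f3$entries$normalized_score[2:3], rep(feat_mean, 2))
  # filled values never move the normalization constants
  expect_equal(f3$raw_min, 0); expect_equal(f3$raw_max, 100)
  # a feature with no scored segment at all is an error
  e <- data.frame(feature = c("f", "z"), kind = "continuous", lo = -Inf,
                  hi = Inf, category = NA, raw_score = c(1, NA),
                  n_points = c(1L, 0L), scored = c(TRUE, FALSE))
  expect_error(fill_missing_intervals(suppressWarnings(normalize_scores(e))), "'z'")
})

test_that("patients are scored by segment lookup with exact totals", {
  runs <- benchmark_runs()
  card <- runs[[1]]$card
  test <- runs[[1]]$test
  ps <- apply_scorecard(card, test)
  feats <- setdiff(names(ps), c("patient", "total"))
  # totals equal the sum of per-feature scores exactly
  expect_equal(ps$total, rowSums(as.matrix(ps[feats])))
  # brute-force oracle on a handful of patients: independent lookup
  e <- card$entries
  for (i in c(1, 17, 101)) {
    tot <- 0
    for (f in feats) {
      rows <- e[e$feature == f, ]
      v <- test$features[[f]]
      if (rows$kind[1] == "continuous") {
        v <- as.numeric(v[i])
        hit <- which(v >= rows$lo & v < rows$hi)
      } else hit <- which(rows$category == as.character(v[i]))
      tot <- tot + rows$normalized_score[hit]
    }
    expect_equal(ps$total[i], tot)
  }
  # out-of-range values clamp to the unbounded edge segments
  low <- test$features[1, , drop = FALSE]
  low$x_bump <- -1e9
  e_bump <- e[e$feature == "x_bump", ]
  expect_equal(apply_scorecard(card, low)$x_bump,
               e_bump$normalized_score[1])
  # missing values must be imputed before scoring
  bad <- test$features[1:2, , drop = FALSE]
  bad$x_step[1] <- NA
  expect_error(apply_scorecard(card, bad), "impute")
})

test_that("unseen categories fall back to the feature mean with a warning", {
  s <- simple_setup()
  e <- score_intervals(s$attrs, s$co, list(x = build_intervals(numeric(0))))
  card <- fill_missing_intervals(normalize_scores(e))
  pat <- data.frame(x = 0, g = "C")
  expect_warning(ps <- apply_scorecard(card, pat), "unseen")
  g_rows <- card$entries[card$entries$feature == "g", ]
  expect_equal(ps$g, mean(g_rows$normalized_score[g_rows$scored]))
})

test_that("scorecards rebuild deterministically from identical inputs", {
  runs <- benchmark_runs()
  r <- runs[[1]]
  card2 <- build_scorecard(r$model, r$train, attrs = r$attrs)
  expect_identical(r$card$entries, card2$entries)
  expect_identical(r$card$raw_min, card2$raw_min)
})

test_that("a monotone effect yields non-decreasing segment scores", {
  r <- benchmark_runs()[[1]]
  e <- r$card$entries
  step_scores <- e$normalized_score[e$feature == "x_step"]
  expect_true(all(diff(step_scores) >= 0))
})
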