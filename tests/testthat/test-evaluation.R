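test_that("AUC follows the Mann-Whitney definition with tie handling", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(0, 0, 1, 1), conf = FALSE)$auc, 1)
  expect_equal(roc_auc(rep(3, 10), rep(0:1, 5), conf = FALSE)$auc, 0.5)
  set.seed(70)
  scores <- sample(1:8, 20, replace = TRUE)   # force ties
  labels <- rbinom(20, 1, 0.4)
  expect_equal(roc_auc(scores, labels, conf = FALSE)$auc,
               auc_pairs(scores, labels))
  # independent library cross-check
  expect_equal(roc_auc(scores, labels, conf = FALSE)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_auc(1:5, rep(1, 5), conf = FALSE), "both classes")
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(71)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  a <- roc_auc(scores, labels, conf = FALSE)$auc
  expect_equal(roc_auc(exp(scores), labels, conf = FALSE)$auc, a)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels, conf = FALSE)$auc, a)
  expect_equal(roc_auc(-scores, labels, conf = FALSE)$auc, 1 - a)
})

test_that("the stratified bootstrap CI brackets the AUC and narrows with n", {
  width <- vapply(c(500, 5000), function(n) {
    set.seed(72)
    scores <- rnorm(n)
    labels <- rbinom(n, 1, plogis(-2 + scores))
    r <- roc_auc(scores, labels, B = 400, seed = 5)
    expect_gte(r$auc, r$ci[1]); expect_lte(r$auc, r$ci[2])
    r$ci[2] - r$ci[1]
  }, numeric(1))
  expect_lt(width[2], width[1])
  # resampling is seeded
  set.seed(73); s <- rnorm(100); l <- rbinom(100, 1, 0.3)
  expect_identical(roc_auc(s, l, B = 50, seed = 9)$ci,
                   roc_auc(s, l, B = 50, seed = 9)$ci)
})

test_that("classification metrics reproduce direct contingency arithmetic", {
  # 9 true positives, 1 false negative, 65 true negatives, 35 false positives
  scores <- c(rep(1, 9), 0, rep(0, 65), rep(1, 35))
  labels <- c(rep(1, 10), rep(0, 100))
  m <- classification_metrics(scores, labels, threshold = 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.65)
  expect_equal(m$ppv, 9 / 44)
  expect_equal(m$npv, 65 / 66)
  expect_equal(m$accuracy, 74 / 110)
  # saturation below the minimum and above the maximum
  lo <- classification_metrics(scores, labels, threshold = -1)
  expect_equal(lo$sensitivity, 1); expect_equal(lo$specificity, 0)
  hi <- classification_metrics(scores, labels, threshold = 2)
  expect_equal(hi$sensitivity, 0); expect_equal(hi$specificity, 1)
  expect_true(is.na(hi$ppv))   # no predicted positives: NA, not 0
})

test_that("the Youden threshold matches a brute-force scan", {
  # perfectly separated: midpoint of the gap, J = 1
  th <- select_threshold(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(th, 5)
  m <- classification_metrics(c(1, 2, 8, 9), c(0, 0, 1, 1), th)
  expect_equal(m$sensitivity + m$specificity - 1, 1)
  set.seed(74)
  for (r in 1:10) {
    scores <- round(rnorm(60), 1)
    labels <- rbinom(60, 1, plogis(scores))
    if (length(unique(labels)) < 2) next
    ref <- youden_scan(scores, labels)
    expect_equal(select_threshold(scores, labels), ref$threshold)
  }
  # label inversion cannot push the maximal J below zero
  scores <- 1:20; labels <- rep(c(1, 0), each = 10)   # inverted orientation
  th2 <- select_threshold(scores, labels)
  m2 <- classification_metrics(scores, labels, th2)
  expect_gte(m2$sensitivity + m2$specificity - 1, 0)
})

test_that("the RCRI is a simple count of its six indicators", {
  expect_equal(rcri_score(rcri_input()), 0L)
  all6 <- rcri_input(1, 1, 1, 1, 1, creatinine_mg_dl = 2.5)
  expect_equal(rcri_score(all6), 6L)
  # creatinine above 2 mg/dL alone contributes exactly one point
  expect_equal(rcri_score(rcri_input(creatinine_mg_dl = 2.5)), 1L)
  expect_equal(rcri_score(rcri_input(creatinine_mg_dl = 2.0)), 0L)
  df <- rcri_input(); df$insulin_treatment <- NULL
  expect_error(rcri_score(df), "insulin_treatment")
})

test_that("evaluate_scores bundles AUC, CI and threshold metrics", {
  set.seed(75)
  scores <- rnorm(400); labels <- rbinom(400, 1, plogis(-1 + 1.5 * scores))
  ev <- evaluate_scores(scores, labels, B = 100, seed = 2)
  expect_s3_class(ev, "eval_report")
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_equal(ev$threshold, select_threshold(scores, labels))
  expect_equal(ev$n_cases, sum(labels))
})
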