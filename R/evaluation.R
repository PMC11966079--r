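# Mann-Whitney AUC: P(case score > control score) with ties counting 1/2.
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with a stratified bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen case
#' outscores a randomly chosen control, ties counting one half. The 95%
#' interval comes from `B` stratified bootstrap resamples (cases and
#' controls resampled separately — essential with rare outcomes), using
#' the percentile method.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param labels 0/1 outcome labels.
#' @param conf If `FALSE`, skip the bootstrap and return only the point
#'   estimate.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `auc`, `ci` (length-2 vector, or `NULL`), `n_cases`,
#'   `n_controls`.
#' @export
roc_auc <- function(scores, labels, conf = TRUE, B = 1000L, seed = 1L,
                    conf_level = 0.95) {
  labels <- as.integer(labels)
  auc <- auc_mw(scores, labels)
  ci <- NULL
  if (conf) {
    cases <- which(labels == 1L); controls <- which(labels == 0L)
    boots <- with_seed(seed, {
      vapply(seq_len(as.integer(B)), function(b) {
        i1 <- sample(cases, length(cases), replace = TRUE)
        i0 <- sample(controls, length(controls), replace = TRUE)
        auc_mw(scores[c(i1, i0)], labels[c(i1, i0)])
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  }
  list(auc = auc, ci = ci, n_cases = sum(labels == 1L),
       n_controls = sum(labels == 0L))
}

#' Classification metrics at a threshold
#'
#' Computes the 2x2 table at `score >= threshold` (ties at the threshold
#' classify as positive) and reports accuracy, sensitivity, specificity,
#' PPV and NPV. A PPV (or NPV) whose denominator is empty is reported as
#' `NA`, not 0.
#'
#' @param scores,labels Numeric scores and 0/1 labels.
#' @param threshold Classification threshold.
#' @return A list with `threshold`, `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(labels),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn))
}

#' Select an operating threshold by the Youden index
#'
#' Scans the midpoints between consecutive distinct score values (plus the
#' minimum score, so the all-positive rule is reachable) and returns the
#' threshold maximizing J = sensitivity + specificity - 1; ties break
#' toward the lower threshold. For perfectly separated classes this is the
#' midpoint of the gap, with J = 1.
#'
#' @param scores,labels Numeric scores and 0/1 labels.
#' @param rule Threshold rule; only `"youden"` is implemented.
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(scores, labels, rule = c("youden")) {
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) c(s[1], (s[-1] + s[-length(s)]) / 2) else s
  j <- vapply(cand, function(th) {
    m <- classification_metrics(scores, labels, th)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  cand[which.max(j)]   # which.max takes the first (lowest) on ties
}

#' Evaluate a score against outcomes
#'
#' Bundles discrimination (AUC with bootstrap CI) and threshold-based
#' classification metrics into one report. When no threshold is given it
#' is selected by [select_threshold()] on the same data.
#'
#' @param scores,labels Numeric scores and 0/1 labels.
#' @param threshold Optional fixed threshold.
#' @param B,seed Bootstrap parameters, see [roc_auc()].
#' @return An object of class `eval_report`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL, B = 1000L,
                            seed = 1L) {
  roc <- roc_auc(scores, labels, conf = TRUE, B = B, seed = seed)
  if (is.null(threshold)) threshold <- select_threshold(scores, labels)
  cm <- classification_metrics(scores, labels, threshold)
  structure(c(list(auc = roc$auc, auc_ci = roc$ci,
                   n_cases = roc$n_cases, n_controls = roc$n_controls), cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC %.3f (95%% CI %.3f-%.3f), threshold %.4g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, ppv %s, npv %s\n",
              x$accuracy, x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv))))
  invisible(x)
}

#' Build the six binary indicators of the Revised Cardiac Risk Index
#'
#' @param high_risk_surgery,ischemic_heart_disease,congestive_heart_failure,cerebrovascular_disease,insulin_treatment
#'   Logical/0-1 indicators.
#' @param creatinine_mg_dl Preoperative creatinine in mg/dL; the indicator
#'   is `creatinine > 2`.
#' @return A one-row data.frame of six 0/1 indicators.
#' @export
rcri_input <- function(high_risk_surgery = 0, ischemic_heart_disease = 0,
                       congestive_heart_failure = 0,
                       cerebrovascular_disease = 0, insulin_treatment = 0,
                       creatinine_mg_dl = 1.0) {
  data.frame(high_risk_surgery = as.integer(high_risk_surgery),
             ischemic_heart_disease = as.integer(ischemic_heart_disease),
             congestive_heart_failure = as.integer(congestive_heart_failure),
             cerebrovascular_disease = as.integer(cerebrovascular_disease),
             insulin_treatment = as.integer(insulin_treatment),
             high_creatinine = as.integer(creatinine_mg_dl > 2))
}

#' Revised Cardiac Risk Index score
#'
#' The traditional six-item additive comparator: one point each for
#' high-risk surgery, ischemic heart disease, congestive heart failure,
#' cerebrovascular disease, preoperative insulin treatment, and
#' creatinine above 2 mg/dL.
#'
#' @param records A data.frame with the six indicator columns of
#'   [rcri_input()], each 0/1.
#' @return Integer vector of scores in 0..6.
#' @export
rcri_score <- function(records) {
  cols <- c("high_risk_surgery", "ischemic_heart_disease",
            "congestive_heart_failure", "cerebrovascular_disease",
            "insulin_treatment", "high_creatinine")
  missing_col <- setdiff(cols, names(records))
  if (length(missing_col))
    stop("records lack indicator(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(records[cols])
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("all six indicators must be present and binary", call. = FALSE)
  as.integer(rowSums(m))
}
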