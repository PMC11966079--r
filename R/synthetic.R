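#' True effect functions for the cohort simulator
#'
#' The simulator draws outcomes from a logistic model whose log-odds are an
#' intercept plus a sum of per-feature effects. Continuous effects are
#' piecewise-constant in the feature value — the nonlinear ground truth the
#' change-point detector is later asked to recover. Categorical effects
#' assign one log-odds level per category. Features without an effect are
#' null (zero contribution).
#'
#' @param breakpoints Strictly increasing numeric vector of cut points.
#' @param levels For [piecewise_effect()]: numeric vector of log-odds
#'   levels, one more than `breakpoints` (level `i` applies on
#'   `[breakpoints[i-1], breakpoints[i])`, with unbounded edges). For
#'   [category_effect()]: named numeric vector of per-category log-odds.
#' @return An object of class `risk_effect`.
#' @name risk_effect
#' @export
piecewise_effect <- function(breakpoints, levels) {
  breakpoints <- as.numeric(breakpoints)
  levels <- as.numeric(levels)
  if (length(breakpoints) > 0 && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  if (length(levels) != length(breakpoints) + 1L)
    stop("need exactly length(breakpoints) + 1 levels", call. = FALSE)
  if (!all(is.finite(levels)) || !all(is.finite(breakpoints)))
    stop("breakpoints and levels must be finite", call. = FALSE)
  structure(list(type = "piecewise", breakpoints = breakpoints, levels = levels),
            class = "risk_effect")
}

#' @rdname risk_effect
#' @export
category_effect <- function(levels) {
  if (is.null(names(levels)) || any(!nzchar(names(levels))))
    stop("category levels must be named by category", call. = FALSE)
  if (!all(is.finite(levels))) stop("levels must be finite", call. = FALSE)
  structure(list(type = "category", levels = levels), class = "risk_effect")
}

#' Evaluate a true effect on a vector of feature values
#'
#' @param effect A [piecewise_effect()] or [category_effect()].
#' @param values Feature values (numeric, or factor/character for
#'   categorical effects).
#' @return Numeric vector of log-odds contributions.
#' @export
eval_effect <- function(effect, values) {
  stopifnot(inherits(effect, "risk_effect"))
  if (effect$type == "piecewise") {
    idx <- findInterval(as.numeric(values), effect$breakpoints) + 1L
    effect$levels[idx]
  } else {
    lev <- effect$levels[as.character(values)]
    unname(ifelse(is.na(lev), 0, lev))
  }
}

#' Specify the true outcome model of a simulated cohort
#'
#' @param intercept Baseline log-odds.
#' @param effects Named list of [risk_effect] objects; names must refer to
#'   schema features. Features absent from the list are null.
#' @return An object of class `risk_spec`.
#' @export
risk_spec <- function(intercept, effects = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be a named list", call. = FALSE)
    ok <- vapply(effects, inherits, logical(1), "risk_effect")
    if (!all(ok)) stop("all effects must be risk_effect objects", call. = FALSE)
  }
  structure(list(intercept = intercept, effects = effects), class = "risk_spec")
}

check_risk_schema <- function(risk, schema) {
  unknown <- setdiff(names(risk$effects), schema_names(schema))
  if (length(unknown))
    stop("risk effects reference unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(risk$effects)) {
    eff <- risk$effects[[nm]]
    kind <- schema[[nm]]$kind
    if (eff$type == "piecewise" && kind != "continuous")
      stop("piecewise effect on non-continuous feature '", nm, "'", call. = FALSE)
    if (eff$type == "category" && kind != "categorical")
      stop("category effect on non-categorical feature '", nm, "'", call. = FALSE)
  }
  invisible(TRUE)
}

draw_feature <- function(spec, n) {
  d <- spec$distribution
  if (is.null(d))
    stop("feature '", spec$name, "' has no sampling distribution", call. = FALSE)
  switch(d$type,
    normal = stats::rnorm(n, d$mu, d$sigma),
    uniform = stats::runif(n, d$lo, d$hi),
    multinomial = factor(sample(spec$categories, n, replace = TRUE, prob = d$probs),
                         levels = spec$categories))
}

#' True log-odds of a feature table under a risk specification
#'
#' @param features Data.frame of feature values.
#' @param risk A [risk_spec()].
#' @return Numeric vector of log-odds, one per row.
#' @export
true_logodds <- function(features, risk) {
  lp <- rep(risk$intercept, nrow(features))
  for (nm in names(risk$effects))
    lp <- lp + eval_effect(risk$effects[[nm]], features[[nm]])
  lp
}

#' Simulate a cohort with known piecewise log-odds ground truth
#'
#' Features are drawn independently from the distributions declared in the
#' schema; the binary outcome is Bernoulli with
#' `P(y = 1 | x) = plogis(intercept + sum of effects)`. The same
#' `(schema, risk, n, seed)` always yields a bitwise-identical cohort.
#'
#' @param schema A [feature_schema()] whose specs carry distributions.
#' @param risk A [risk_spec()] consistent with the schema.
#' @param n Number of patients (`>= 1`).
#' @param seed Integer seed; all randomness flows from it.
#' @return A [cohort()] whose provenance records the seed and risk.
#' @export
generate_cohort <- function(schema, risk, n, seed) {
  stopifnot(inherits(schema, "feature_schema"), inherits(risk, "risk_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  check_risk_schema(risk, schema)
  with_seed(seed, {
    cols <- lapply(schema, draw_feature, n = n)
    features <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
    names(features) <- schema_names(schema)
    p <- stats::plogis(true_logodds(features, risk))
    outcome <- stats::rbinom(n, 1L, p)
    cohort(features, outcome, schema,
           provenance = list(generator = "generate_cohort", seed = as.integer(seed),
                             risk = risk))
  })
}

#' Mask feature entries completely at random
#'
#' Entries of each feature column are independently replaced by `NA` with
#' the given per-feature probability. The outcome is never masked, and
#' masking happens after outcome generation, so missingness is
#' missing-completely-at-random with respect to the true risk.
#'
#' @param cohort A [cohort()].
#' @param rates Either a single probability applied to every feature or a
#'   named vector of per-feature probabilities (features not named keep
#'   rate 0). All rates must lie in `[0, 1]`.
#' @param seed Integer seed.
#' @return The cohort with `NA` entries injected.
#' @export
inject_missingness <- function(cohort, rates, seed) {
  stopifnot(inherits(cohort, "cohort"))
  nms <- schema_names(cohort$schema)
  if (is.null(names(rates))) {
    if (length(rates) != 1L)
      stop("rates must be a scalar or a named vector", call. = FALSE)
    rates <- stats::setNames(rep(as.numeric(rates), length(nms)), nms)
  } else {
    unknown <- setdiff(names(rates), nms)
    if (length(unknown))
      stop("rates name unknown feature(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    full <- stats::setNames(numeric(length(nms)), nms)
    full[names(rates)] <- as.numeric(rates)
    rates <- full
  }
  if (any(rates < 0 | rates > 1 | is.na(rates)))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  n <- nrow(cohort$features)
  with_seed(seed, {
    for (nm in nms) {
      r <- rates[[nm]]
      if (r > 0) {
        mask <- stats::runif(n) < r
        cohort$features[[nm]][mask] <- NA
      }
    }
  })
  cohort$provenance$missingness <- list(rates = rates, seed = as.integer(seed))
  cohort
}

#' Calibrate the intercept of a risk model to a target prevalence
#'
#' Solves `E[plogis(b0 + s)] = target` over a large Monte-Carlo draw of the
#' effect sums `s` implied by the schema, using a fixed internal seed so
#' the calibration is deterministic.
#'
#' @param schema,risk Schema and risk specification (the risk's current
#'   intercept is ignored).
#' @param target Target outcome prevalence in `(0, 1)`.
#' @param n_mc Monte-Carlo sample size for the effect-sum distribution.
#' @return The calibrated intercept (scalar log-odds).
#' @export
calibrate_intercept <- function(schema, risk, target, n_mc = 200000L) {
  stopifnot(target > 0, target < 1)
  check_risk_schema(risk, schema)
  s <- with_seed(912803L, {
    cols <- lapply(schema[names(risk$effects)], draw_feature, n = n_mc)
    tot <- numeric(n_mc)
    for (nm in names(risk$effects))
      tot <- tot + eval_effect(risk$effects[[nm]], cols[[nm]])
    tot
  })
  f <- function(b0) mean(stats::plogis(b0 + s)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Default simulated-cohort preset
#'
#' A 29-feature preset shaped like a perioperative surgical registry:
#' 17 continuous features (demographics, vitals-adjacent physical metrics,
#' and a preoperative laboratory panel) and 12 categorical features (sex,
#' a five-level physical-status class, emergency surgery, comorbidity
#' flags, and a binary high-risk surgery type). A handful of features carry
#' piecewise-nonlinear log-odds effects (age rising in steps, low albumin
#' and low haemoglobin raising risk, a low-BMI bump, high glucose, low
#' platelets) alongside categorical effects (physical-status class,
#' emergency and high-risk surgery, prior cerebrovascular event); the rest
#' are null. The intercept is calibrated so the marginal outcome
#' prevalence matches `prevalence` (default 0.38%, a rare event).
#'
#' @param prevalence Target outcome prevalence (default `0.0038`).
#' @return A list with elements `schema` (a [feature_schema()]) and `risk`
#'   (a [risk_spec()] with calibrated intercept).
#' @export
default_cohort_preset <- function(prevalence = 0.0038) {
  yn <- c("no", "yes")
  bern <- function(p) dist_multinomial(c(1 - p, p))
  specs <- list(
    feature_spec("age", "continuous", "years", distribution = dist_normal(56.9, 15.2)),
    feature_spec("height", "continuous", "cm", distribution = dist_normal(162.0, 8.7)),
    feature_spec("weight", "continuous", "kg", distribution = dist_normal(63.5, 12.0)),
    feature_spec("bmi", "continuous", "kg/m2", distribution = dist_normal(24.1, 3.7)),
    feature_spec("hemoglobin", "continuous", "g/dL", distribution = dist_normal(12.9, 1.9)),
    feature_spec("platelet", "continuous", "10^3/uL", distribution = dist_normal(245, 79)),
    feature_spec("bun", "continuous", "mg/dL", distribution = dist_normal(15.8, 6.0)),
    feature_spec("creatinine", "continuous", "mg/dL", distribution = dist_normal(1.0, 0.35)),
    feature_spec("albumin", "continuous", "g/dL", distribution = dist_normal(4.05, 0.47)),
    feature_spec("sodium", "continuous", "mmol/L", distribution = dist_normal(140.2, 2.7)),
    feature_spec("potassium", "continuous", "mmol/L", distribution = dist_normal(4.24, 0.41)),
    feature_spec("glucose", "continuous", "mg/dL", distribution = dist_normal(114.9, 39.9)),
    feature_spec("pt", "continuous", "%", distribution = dist_normal(103.6, 14.9)),
    feature_spec("ptt", "continuous", "sec", distribution = dist_normal(31.5, 5.6)),
    feature_spec("ast", "continuous", "IU/L", distribution = dist_normal(25.3, 12.0)),
    feature_spec("alt", "continuous", "IU/L", distribution = dist_normal(25.4, 14.0)),
    feature_spec("egfr", "continuous", "mL/min/1.73m2", distribution = dist_normal(83.8, 27.3)),
    feature_spec("sex", "categorical", "", c("female", "male"), bern(0.554)),
    feature_spec("asa", "categorical", "class", c("1", "2", "3", "4", "5"),
                 dist_multinomial(c(0.2953, 0.5831, 0.1143, 0.0068, 0.0005))),
    feature_spec("emergency", "categorical", "", yn, bern(0.058)),
    feature_spec("hypertension", "categorical", "", yn, bern(0.312)),
    feature_spec("diabetes", "categorical", "", yn, bern(0.152)),
    feature_spec("prior_cva", "categorical", "", yn, bern(0.020)),
    feature_spec("asthma", "categorical", "", yn, bern(0.006)),
    feature_spec("copd", "categorical", "", yn, bern(0.006)),
    feature_spec("liver_disease", "categorical", "", yn, bern(0.039)),
    feature_spec("kidney_disease", "categorical", "", yn, bern(0.032)),
    feature_spec("tuberculosis", "categorical", "", yn, bern(0.010)),
    feature_spec("highrisk_surgery", "categorical", "", yn, bern(0.542))
  )
  schema <- feature_schema(specs)
  effects <- list(
    age = piecewise_effect(c(49, 64), c(0, 0.4, 0.9)),
    albumin = piecewise_effect(c(3.5, 4.1), c(1.1, 0.5, 0)),
    hemoglobin = piecewise_effect(c(11), c(0.8, 0)),
    bmi = piecewise_effect(c(18.6, 20.7), c(0.7, 0.35, 0)),
    glucose = piecewise_effect(c(160), c(0, 0.5)),
    platelet = piecewise_effect(c(120), c(0.6, 0)),
    asa = category_effect(c("1" = 0, "2" = 0.25, "3" = 0.7, "4" = 1.3, "5" = 1.9)),
    emergency = category_effect(c(no = 0, yes = 0.7)),
    prior_cva = category_effect(c(no = 0, yes = 0.8)),
    highrisk_surgery = category_effect(c(no = 0, yes = 0.6))
  )
  risk0 <- risk_spec(0, effects)
  b0 <- calibrate_intercept(schema, risk0, prevalence)
  list(schema = schema, risk = risk_spec(b0, effects))
}

#' Benchmark preset with a single nonlinear feature family
#'
#' A compact five-feature cohort used to validate breakpoint recovery and
#' the nonlinearity advantage of the scorecard over a linear model:
#' `x_bump` has a non-monotone piecewise-constant effect (elevated log-odds
#' on the middle of its range, breakpoints at -0.8 and 0.8), `x_step` a
#' monotone step at 0.5, `x_null1`/`x_null2` are null, and a binary
#' categorical carries a small effect. The outcome prevalence is moderate
#' (default 10%) so that effect recovery is driven by the detector rather
#' than by rare-event estimation noise; the rare-event regime is exercised
#' separately by [default_cohort_preset()].
#'
#' @param prevalence Target outcome prevalence (default `0.10`).
#' @return A list with elements `schema`, `risk`, and `breakpoints` (the
#'   true cut points of `x_bump`).
#' @export
benchmark_preset <- function(prevalence = 0.10) {
  schema <- feature_schema(list(
    feature_spec("x_bump", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("x_step", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("x_null1", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("x_null2", "continuous", distribution = dist_normal(0, 1)),
    feature_spec("flag", "categorical", categories = c("no", "yes"),
                 distribution = dist_multinomial(c(0.7, 0.3)))
  ))
  effects <- list(
    x_bump = piecewise_effect(c(-0.8, 0.8), c(0, 1.6, 0)),
    x_step = piecewise_effect(0.5, c(0, 1.0)),
    flag = category_effect(c(no = 0, yes = 0.3))
  )
  risk0 <- risk_spec(0, effects)
  b0 <- calibrate_intercept(schema, risk0, prevalence)
  list(schema = schema, risk = risk_spec(b0, effects),
       breakpoints = c(-0.8, 0.8))
}
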