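#' Fit the composite metabolic disease score model
#'
#' The score is built from seven fasting blood markers (triglycerides,
#' glucose, insulin, LDL, HDL, leptin, adiponectin): markers are
#' z-scored, the first principal component is extracted, oriented so the
#' triglycerides loading is positive (high score = dyslipidemia and
#' insulin resistance), shifted so its minimum on the fitting panel is
#' 1, and natural-log transformed.  The minimum subject of the fitting
#' panel therefore scores exactly 0.
#'
#' @param markers numeric matrix or data frame, subjects by the seven
#'   markers (columns named as in `marker_names()`).
#' @param cutoff impairment cutoff on the score scale; the default 1.4
#'   is the clinically anchored value (see [derive_cutoff()] for how it
#'   is obtained from marker thresholds).
#' @param clinical_thresholds named list of marker thresholds used by
#'   [derive_cutoff()]; defaults: triglycerides 200 mg/dl, glucose
#'   100 mg/dl, HDL 40 mg/dl, LDL 160 mg/dl.
#' @return a `score_model` list: `center`, `scale`, `loadings` (unit
#'   PC1 vector), `orientation`, `shift`, `log_base`, `cutoff`,
#'   `clinical_thresholds`.
#' @export
fit_score_model <- function(markers, cutoff = 1.4,
                            clinical_thresholds = list(
                              triglycerides = 200, glucose = 100,
                              hdl = 40, ldl = 160)) {
  m <- check_marker_panel(markers)
  if (nrow(m) < 3L) stop("insufficient data: need >= 3 subjects", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate scale: constant marker column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  orientation <- if (loadings["triglycerides"] < 0) -1 else 1
  pc1 <- orientation * pc$x[, 1]
  shift <- 1 - min(pc1)
  structure(list(center = pc$center, scale = pc$scale,
                 loadings = loadings, orientation = orientation,
                 shift = shift, log_base = exp(1), cutoff = cutoff,
                 clinical_thresholds = clinical_thresholds),
            class = "score_model")
}

check_marker_panel <- function(markers) {
  m <- as_num_matrix(markers, "marker panel")
  missing <- setdiff(marker_names(), colnames(m))
  if (length(missing)) {
    stop("schema error: missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- m[, marker_names(), drop = FALSE]
  if (anyNA(m) || any(!is.finite(m))) {
    stop("marker panel contains missing or non-finite values", call. = FALSE)
  }
  m
}

#' Score subjects with a fitted score model
#'
#' `score = log(orientation * (z-scored markers %*% loadings) + shift)`.
#' Subjects below the fitting panel's minimum may score below 0; no
#' clamp is applied (a message notes such subjects).  Classification is
#' `impaired` when score > `model$cutoff`, else `normal`.
#'
#' @param model a [fit_score_model()] result.
#' @param markers marker panel for the subjects to score.
#' @return tibble with `subject`, `score`, `class`.
#' @export
score_subjects <- function(model, markers) {
  stopifnot(inherits(model, "score_model"))
  m <- check_marker_panel(markers)
  zm <- sweep(sweep(m, 2, model$center), 2, model$scale, `/`)
  pc1 <- model$orientation * drop(zm %*% model$loadings)
  arg <- pc1 + model$shift
  if (any(arg <= 0)) {
    stop("score undefined: subject(s) fall at or below the log-domain ",
         "boundary of the fitting panel", call. = FALSE)
  }
  score <- unname(log(arg, base = model$log_base))
  if (any(score < -1e-12)) {
    message(sum(score < 0), " subject(s) scored below the fitting panel's ",
            "minimum (score < 0); not clamped")
  }
  tibble::tibble(
    subject = rownames(m) %||% sprintf("S%03d", seq_len(nrow(m))),
    score = score,
    class = factor(ifelse(score > model$cutoff, "impaired", "normal"),
                   levels = c("normal", "impaired")))
}

#' Derive the impairment cutoff from clinical marker thresholds
#'
#' For each of the four markers with well-defined clinical cutoffs
#' (triglycerides, glucose, HDL, LDL), fits ordinary least squares
#' `score ~ marker` and evaluates the fitted line at the marker's
#' clinical threshold; the impairment cutoff is the mean of the four
#' evaluated scores.
#'
#' @param scores numeric score vector (one per subject).
#' @param markers the matching marker panel.
#' @param clinical_thresholds named list with `triglycerides`,
#'   `glucose`, `hdl`, `ldl` threshold values.
#' @return scalar cutoff on the score scale.
#' @export
derive_cutoff <- function(scores, markers,
                          clinical_thresholds = list(
                            triglycerides = 200, glucose = 100,
                            hdl = 40, ldl = 160)) {
  m <- check_marker_panel(markers)
  need <- c("triglycerides", "glucose", "hdl", "ldl")
  if (!all(need %in% names(clinical_thresholds))) {
    stop("config error: thresholds required for ",
         paste(setdiff(need, names(clinical_thresholds)), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(scores) == nrow(m))
  vals <- vapply(need, function(mk) {
    x <- m[, mk]
    if (stats::sd(x) == 0) {
      stop("regression error: zero-variance marker ", mk, call. = FALSE)
    }
    fit <- stats::lm(scores ~ x)
    unname(stats::predict(fit,
                          newdata = data.frame(x = clinical_thresholds[[mk]])))
  }, numeric(1))
  mean(vals)
}

#' Per-cohort age slopes of the score
#'
#' Fits `score ~ age + cohort + age:cohort` by OLS with treatment coding
#' and reports, for every cohort, the age slope (reference slope plus
#' interaction), its standard error, and a two-sided p-value, so claims
#' of the form "score increases with age only in cohort X" are directly
#' expressible.
#'
#' @param scores numeric score vector.
#' @param age numeric age vector (years).
#' @param cohort factor (or coercible); first level is the reference
#'   unless `reference` is given.
#' @param reference optional reference cohort label.
#' @return tibble with `cohort`, `slope`, `se`, `t`, `p`; the fitted
#'   `lm` object is attached as attribute `model`.
#' @export
age_cohort_model <- function(scores, age, cohort, reference = NULL) {
  cohort <- as.factor(cohort)
  if (!is.null(reference)) cohort <- stats::relevel(cohort, ref = reference)
  if (nlevels(droplevels(cohort)) < 2L) {
    stop("need >= 2 cohorts", call. = FALSE)
  }
  if (any(table(cohort) < 3L)) {
    stop("need >= 3 subjects per cohort", call. = FALSE)
  }
  d <- data.frame(score = scores, age = age, cohort = droplevels(cohort))
  fit <- stats::lm(score ~ age * cohort, data = d)
  if (anyNA(stats::coef(fit))) stop("singular design", call. = FALSE)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  lv <- levels(d$cohort)
  df <- fit$df.residual
  res <- lapply(lv, function(cl) {
    cv <- stats::setNames(rep(0, length(b)), names(b))
    cv["age"] <- 1
    intn <- paste0("age:cohort", cl)
    if (intn %in% names(b)) cv[intn] <- 1
    slope <- sum(cv * b)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tv <- slope / se
    tibble::tibble(cohort = cl, slope = slope, se = se, t = tv,
                   p = 2 * stats::pt(-abs(tv), df))
  })
  out <- do.call(rbind, res)
  attr(out, "model") <- fit
  out
}
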