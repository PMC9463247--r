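#' Calibration curve linking an MRI predictor to LIC
#'
#' For the SIR predictor the curve is log-linear,
#' `ln LIC = a + b * ratio` (slope negative: signal falls as iron rises);
#' for R2* it is linear, `LIC = a + b * R2*`. Acquisition provenance
#' (TE, TR) and the valid LIC range travel with the curve.
#'
#' @param intercept_a,slope_b Coefficients (ln(mg/g) scale for the SIR form).
#' @param form `"log_linear_sir"`, `"exp_sir"` (same ln-linear coefficients,
#'   fitted by nonlinear LS on the LIC scale) or `"linear_r2star"`.
#' @param te_ms,tr_ms Acquisition provenance, ms.
#' @param lic_range Valid LIC interval (mg/g), `c(min, max)`.
#' @param fitted_by Free-text note on the estimator that produced the curve.
#' @return An object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(intercept_a, slope_b,
                              form = c("log_linear_sir", "exp_sir",
                                       "linear_r2star"),
                              te_ms = NA, tr_ms = NA,
                              lic_range = c(0, Inf), fitted_by = "manual") {
  form <- match.arg(form)
  if (form %in% c("log_linear_sir", "exp_sir") && slope_b >= 0)
    stop("SIR calibration slope must be negative (signal falls with iron)")
  if (lic_range[1] >= lic_range[2]) stop("lic_range must have min < max")
  structure(list(intercept_a = intercept_a, slope_b = slope_b, form = form,
                 te_ms = te_ms, tr_ms = tr_ms, lic_range = lic_range,
                 fitted_by = fitted_by),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  eqn <- switch(x$form,
    log_linear_sir = sprintf("ln LIC = %.4f + (%.4f) * ratio", x$intercept_a, x$slope_b),
    exp_sir = sprintf("LIC = exp(%.4f + (%.4f) * ratio)", x$intercept_a, x$slope_b),
    linear_r2star = sprintf("LIC = %.4f + %.4f * R2*", x$intercept_a, x$slope_b))
  cat("Calibration curve (", x$form, ", TE ", x$te_ms, " / TR ", x$tr_ms,
      " ms)\n  ", eqn, "\n  valid LIC range: ",
      sprintf("%.3g to %.3g mg/g", x$lic_range[1], x$lic_range[2]), "\n",
      sep = "")
  invisible(x)
}

#' Fit a calibration curve from examination records
#'
#' SIR form: Passing-Bablok regression of `ln(lic_biopsy)` on the
#' liver/muscle ratio (records must already be censored of background-level
#' signals). The alternative `method = "nls_exp"` fits the exponential model
#' `LIC = exp(a + b * ratio)` by nonlinear least squares on the LIC scale —
#' the two estimators are kept distinct and the curve records which produced
#' it. R2* form: linear Passing-Bablok of `lic_biopsy` on `r2star`.
#'
#' @param records Cohort/exam data frame ([as_exams()]); for the r2star form
#'   a data frame with `r2star` and `lic_biopsy` (see [fit_r2star_table()]).
#' @param predictor `"sir"` or `"r2star"`.
#' @param method `"pb_log"` (default) or `"nls_exp"` (SIR form only).
#' @param ci_level Confidence level for the Passing-Bablok fit.
#' @return List of class `"sir_calibration"` with `curve`
#'   ([calibration_curve()]) and `pb` (the [passing_bablok()] fit, or NULL
#'   for `nls_exp`).
#' @export
fit_calibration <- function(records, predictor = c("sir", "r2star"),
                            method = c("pb_log", "nls_exp"),
                            ci_level = 0.95) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  d <- as_exams(records)
  if (nrow(d) < 3) stop("fewer than 3 usable records")
  if (any(d$lic_biopsy <= 0)) stop("biopsy LIC must be positive")

  te <- if ("te_ms" %in% names(d)) unique(d$te_ms)[1] else NA
  tr <- if ("tr_ms" %in% names(d)) unique(d$tr_ms)[1] else NA
  lic_rng <- range(d$lic_biopsy)

  if (predictor == "sir") {
    if (method == "pb_log") {
      pb <- passing_bablok(d$ratio, log(d$lic_biopsy), ci_level = ci_level)
      curve <- calibration_curve(pb$intercept, pb$slope, "log_linear_sir",
                                 te_ms = te, tr_ms = tr, lic_range = lic_rng,
                                 fitted_by = "Passing-Bablok on ln LIC")
      return(structure(list(curve = curve, pb = pb), class = "sir_calibration"))
    }
    st <- stats::coef(stats::lm(log(d$lic_biopsy) ~ d$ratio))
    fit <- minpack.lm::nlsLM(lic_biopsy ~ exp(a + b * ratio), data = d,
                             start = list(a = st[[1]], b = st[[2]]))
    cf <- stats::coef(fit)
    curve <- calibration_curve(cf[["a"]], cf[["b"]], "exp_sir",
                               te_ms = te, tr_ms = tr, lic_range = lic_rng,
                               fitted_by = "nonlinear LS, exponential model")
    return(structure(list(curve = curve, pb = NULL), class = "sir_calibration"))
  }

  if (!"r2star" %in% names(d)) stop("r2star predictor requires an r2star column")
  pb <- passing_bablok(d$r2star, d$lic_biopsy, ci_level = ci_level)
  curve <- calibration_curve(pb$intercept, pb$slope, "linear_r2star",
                             lic_range = lic_rng,
                             fitted_by = "Passing-Bablok, linear")
  structure(list(curve = curve, pb = pb), class = "sir_calibration")
}

#' @export
print.sir_calibration <- function(x, ...) {
  print(x$curve)
  if (!is.null(x$pb)) print(x$pb)
  invisible(x)
}

#' Predict LIC from a calibration curve
#'
#' Inverts the calibration: `exp(a + b * value)` for the SIR forms, the
#' linear prediction for R2*. Values whose predicted LIC falls outside the
#' curve's calibrated range are flagged (attribute `"extrapolated"`), not
#' refused.
#'
#' @param curve A [calibration_curve()] (or `sir_calibration`).
#' @param value Predictor value(s): ratio, or R2* in 1/ms.
#' @return Predicted LIC (mg/g) with logical attribute `extrapolated`.
#' @export
predict_lic <- function(curve, value) {
  if (inherits(curve, "sir_calibration")) curve <- curve$curve
  stopifnot(inherits(curve, "calibration_curve"))
  lic <- if (curve$form == "linear_r2star")
    curve$intercept_a + curve$slope_b * value
  else exp(curve$intercept_a + curve$slope_b * value)
  extra <- lic < curve$lic_range[1] | lic > curve$lic_range[2]
  attr(lic, "extrapolated") <- extra
  lic
}

#' Upper LIC limit of the measuring range
#'
#' The smallest LIC at which the expected (noiseless) spin-echo liver signal
#' drops to the background floor, found by bisection on the monotone forward
#' model over [0, 1000] mg/g. Shorter echo times push the limit up — the
#' mechanism behind extending the measuring range by reducing TE.
#'
#' @param model A [relaxation_model()] with positive r2.
#' @param params SE [acquisition_params()].
#' @param floor Signal floor (e.g. 25, or [background_floor()]).
#' @param tol Bisection tolerance on LIC, mg/g.
#' @return The limiting LIC (mg/g), or `Inf` if the signal never reaches the
#'   floor within [0, 1000] mg/g.
#' @export
measuring_range <- function(model, params, floor, tol = 1e-6) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(params, "acquisition_params"))
  if (model$r2 <= 0) stop("measuring_range requires a positive r2 relaxivity")
  sig <- function(lic) {
    rx <- relaxation_from_lic(lic, model)
    se_signal(params, rx$T1, rx$T2, model$proton_density)
  }
  if (floor <= 0 || sig(1000) > floor) return(Inf)
  if (sig(0) <= floor) return(0)
  lo <- 0; hi <- 1000
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sig(mid) > floor) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Stratified coefficients of determination per TR
#'
#' Ordinary R-squared of `ln(lic_biopsy)` against the predictor, computed
#' separately in the low (`lic <= cut`) and high (`cut < lic < upper`)
#' strata for every TR present. Records at or above `upper` are excluded.
#' Strata with fewer than 3 points are omitted with a warning.
#'
#' @param records Cohort/exam data ([as_exams()]).
#' @param predictor `"ratio"` or `"si_liver"`.
#' @param cut,upper Stratum boundaries, mg/g (defaults 34 and 115).
#' @return Data frame with columns `stratum`, `tr_ms`, `n`, `r_squared`.
#' @export
stratified_r2 <- function(records, predictor = c("ratio", "si_liver"),
                          cut = 34, upper = 115) {
  predictor <- match.arg(predictor)
  d <- as_exams(records)
  d <- d[d$lic_biopsy < upper, , drop = FALSE]
  d$stratum <- ifelse(d$lic_biopsy <= cut, "low", "high")
  out <- list()
  for (st in c("low", "high")) for (tr in sort(unique(d$tr_ms))) {
    dd <- d[d$stratum == st & d$tr_ms == tr, , drop = FALSE]
    if (nrow(dd) < 3) {
      warning(sprintf("stratum %s at TR %g: fewer than 3 points, omitted",
                      st, tr))
      next
    }
    r2 <- summary(stats::lm(log(dd$lic_biopsy) ~ dd[[predictor]]))$r.squared
    out[[length(out) + 1L]] <- data.frame(stratum = st, tr_ms = tr,
                                          n = nrow(dd), r_squared = r2)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman rho; invariant under monotone transforms of either
#' argument (so rho against LIC equals rho against ln LIC exactly).
#'
#' @param x,y Paired values, n >= 3.
#' @return rho, or `NA` (with a warning) for constant input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Upper limit of normal
#'
#' `mean + 2 * SD` of a reference sample.
#'
#' @param values Numeric, n >= 2.
#' @return The threshold.
#' @export
upper_limit_normal <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  mean(values) + 2 * stats::sd(values)
}
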