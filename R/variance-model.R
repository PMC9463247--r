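#' Heteroscedastic mixed model of ln LIC across repetition times
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' `ln(lic_biopsy) ~ TR * predictor` with a per-subject random intercept
#' (repeated examinations of the same animal are nested) and a residual
#' standard deviation that grows exponentially with the predictor,
#' separately per TR: `SD = sigma * exp(delta_TR * v)`. TR is treated as a
#' categorical factor. The per-TR variance coefficients delta are the
#' quantity of interest: they say at which TR the calibration curve is
#' tightest, and where along the predictor axis the spread sits.
#'
#' @param records Cohort/exam data ([as_exams()]) with at least 2 subjects,
#'   2 TR levels, and positive biopsy LIC.
#' @param predictor `"ratio"` or `"si_liver"`.
#' @return An object of class `"variance_fit"`: `fixed_effects`, `sigma`,
#'   `delta` (named per TR), `random_intercept_sd`, `loglik`, `predictor`,
#'   `tr_levels`, `predictor_range`, and the underlying `nlme::lme` object
#'   as `model`.
#' @export
fit_lme <- function(records, predictor = c("ratio", "si_liver")) {
  predictor <- match.arg(predictor)
  d <- as_exams(records)
  if (any(d$lic_biopsy <= 0)) stop("biopsy LIC must be positive")
  if (length(unique(d$subject_id)) < 2) stop("need at least 2 subjects")
  if (length(unique(d$tr_ms)) < 2) stop("need at least 2 TR levels")
  dd <- data.frame(ln_lic = log(d$lic_biopsy),
                   tr_f = factor(d$tr_ms),
                   v = d[[predictor]],
                   subject = d$subject_id)
  # intermediate optimizer steps can visit near-singular variance weights;
  # those transient warnings say nothing about the converged fit
  fit <- try(withCallingHandlers(
    nlme::lme(ln_lic ~ tr_f * v, random = ~ 1 | subject,
              weights = nlme::varExp(form = ~ v | tr_f),
              data = dd, method = "ML",
              control = nlme::lmeControl(maxIter = 200,
                                         msMaxIter = 200,
                                         opt = "optim")),
    warning = function(w) {
      if (grepl("Singular precision", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("LME fit did not converge: ", attr(fit, "condition")$message)
  delta <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE)
  names(delta) <- sub("^expon\\.", "", names(delta))
  structure(list(fixed_effects = nlme::fixef(fit),
                 sigma = fit$sigma,
                 delta = delta,
                 random_intercept_sd =
                   as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]),
                 loglik = as.numeric(stats::logLik(fit)),
                 predictor = predictor,
                 tr_levels = as.numeric(levels(dd$tr_f)),
                 predictor_range = range(dd$v),
                 model = fit),
            class = "variance_fit")
}

#' @export
print.variance_fit <- function(x, ...) {
  cat(sprintf("Heteroscedastic LME of ln LIC on %s (ML), %d TR levels\n",
              x$predictor, length(x$tr_levels)))
  cat(sprintf("  sigma %.4f, random-intercept SD %.4f, logLik %.1f\n",
              x$sigma, x$random_intercept_sd, x$loglik))
  cat("  variance coefficients delta (per TR):\n")
  print(round(x$delta, 4))
  invisible(x)
}

#' Pointwise residual SD curves per TR
#'
#' Evaluates `sigma * exp(delta_TR * v)` over a predictor grid, one curve
#' per TR level.
#'
#' @param fit A [fit_lme()] result.
#' @param grid Predictor values; defaults to 50 points over the observed
#'   range.
#' @return Data frame with columns `tr_ms`, `v`, `sd`.
#' @export
pointwise_sd <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "variance_fit"))
  if (is.null(grid))
    grid <- seq(fit$predictor_range[1], fit$predictor_range[2],
                length.out = 50)
  out <- lapply(fit$tr_levels, function(tr) {
    delta <- fit$delta[as.character(tr)]
    if (is.na(delta)) delta <- 0   # stratum absent from the variance struct
    data.frame(tr_ms = tr, v = grid,
               sd = fit$sigma * exp(delta * grid))
  })
  do.call(rbind, out)
}

trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Select the repetition time with the lowest calibration variance
#'
#' Integrates each TR's pointwise SD curve over the observed predictor range
#' (trapezoidal rule) and returns the TR with the smallest integrated SD,
#' breaking ties toward the longer TR.
#'
#' @param fit A [fit_lme()] result, or a `pointwise_sd()`-style data frame
#'   with columns `tr_ms`, `v`, `sd`.
#' @param grid Optional predictor grid (when `fit` is a `variance_fit`).
#' @return The selected TR (ms), with the per-TR integrated SDs as
#'   attribute `"integrated_sd"`.
#' @export
select_tr <- function(fit, grid = NULL) {
  curves <- if (inherits(fit, "variance_fit")) pointwise_sd(fit, grid)
            else fit
  stopifnot(all(c("tr_ms", "v", "sd") %in% names(curves)))
  trs <- sort(unique(curves$tr_ms))
  isd <- vapply(trs, function(tr) {
    cc <- curves[curves$tr_ms == tr, ]
    if (nrow(cc) == 1) cc$sd else trapezoid(cc$v, cc$sd)
  }, numeric(1))
  names(isd) <- trs
  best <- trs[isd <= min(isd) + 1e-12]
  out <- max(best)                      # tie -> longest TR
  attr(out, "integrated_sd") <- isd
  out
}
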