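#' TR-adjustment function for the SIR method
#'
#' The clinical SIR software corrects the liver/muscle ratio for repetition
#' times other than the reference T0 = 684 ms, applying no correction at
#' TR = 684 ms. The correction strength alpha is a fourth-degree polynomial
#' in a signal-derived argument x (see [alpha_poly()]). Two evaluation modes
#' are shipped: `additive_identity` (default) computes
#' `ratio + alpha(x) * (T0 - TR)`, which honours the stated no-correction
#' property at TR = T0 exactly; `as_printed` evaluates the published formula
#' literally, `ratio * TR + alpha(x) * (T0 - TR)`, which does *not* reduce
#' to the identity at T0 and is retained only for auditability (its "x TR"
#' term is most plausibly a typesetting artifact).
#'
#' @param t0 Reference TR, ms (default 684).
#' @param coeffs Polynomial coefficients c0..c4 of alpha.
#' @param mode `"additive_identity"` or `"as_printed"`.
#' @param x_arg What to pass as the polynomial argument: `"ratio"` (default)
#'   or `"si_liver"` (raw liver signal; the published coefficient magnitudes
#'   are also consistent with an argument on a raw-signal scale of
#'   hundreds — both interpretations are exposed, neither asserted).
#' @return An object of class `"adjustment_function"`.
#' @export
adjustment_function <- function(t0 = 684,
                                coeffs = c(-1.98e-2, 3.77e-4, -2.40e-6,
                                           4.82e-9, -2.00e-12),
                                mode = c("additive_identity", "as_printed"),
                                x_arg = c("ratio", "si_liver")) {
  stopifnot(t0 > 0, length(coeffs) == 5)
  structure(list(t0 = t0, coeffs = coeffs, mode = match.arg(mode),
                 x_arg = match.arg(x_arg)),
            class = "adjustment_function")
}

#' Quartic correction-strength polynomial
#'
#' `alpha(x) = c0 + c1 x + c2 x^2 + c3 x^3 + c4 x^4`, with the published
#' default coefficients (-1.98e-2, 3.77e-4, -2.40e-6, 4.82e-9, -2.00e-12).
#'
#' @param x Polynomial argument; vectorized.
#' @param coeffs Coefficients c0..c4.
#' @return alpha(x).
#' @export
alpha_poly <- function(x, coeffs = c(-1.98e-2, 3.77e-4, -2.40e-6,
                                     4.82e-9, -2.00e-12)) {
  stopifnot(length(coeffs) == 5)
  coeffs[1] + coeffs[2] * x + coeffs[3] * x^2 + coeffs[4] * x^3 +
    coeffs[5] * x^4
}

#' Adjust an SIR ratio for a non-reference repetition time
#'
#' @param ratio Liver/muscle ratio(s).
#' @param tr Repetition time used at acquisition, ms (> 0).
#' @param fn An [adjustment_function()].
#' @param si_liver Raw liver signal, required when `fn$x_arg = "si_liver"`.
#' @return The adjusted ratio(s). In the default mode the input is returned
#'   unchanged when `tr == fn$t0`.
#' @export
adjust_ratio <- function(ratio, tr, fn = adjustment_function(),
                         si_liver = NULL) {
  stopifnot(inherits(fn, "adjustment_function"), all(tr > 0))
  x <- if (fn$x_arg == "si_liver") {
    if (is.null(si_liver)) stop("si_liver required for x_arg = 'si_liver'")
    si_liver
  } else ratio
  a <- alpha_poly(x, fn$coeffs)
  if (fn$mode == "as_printed") ratio * tr + a * (fn$t0 - tr)
  else ratio + a * (fn$t0 - tr)
}

#' Calibration-transfer correction between two calibrations
#'
#' Passing-Bablok regression of the target calibration's LIC estimates on
#' the source calibration's, stored as the affine correction
#' `source' = slope * source + intercept`.
#'
#' @param source_lic,target_lic Paired LIC estimates, mg/g (n >= 3).
#' @param ci_level Confidence level.
#' @return An object of class `"transfer_correction"`: `slope`, `intercept`,
#'   `source_fit` (the underlying `pb_fit`).
#' @export
fit_transfer <- function(source_lic, target_lic, ci_level = 0.95) {
  pb <- passing_bablok(source_lic, target_lic, ci_level = ci_level)
  structure(list(slope = pb$slope, intercept = pb$intercept,
                 source_fit = pb),
            class = "transfer_correction")
}

#' Apply a transfer correction to new source values
#'
#' @param correction A [fit_transfer()] result.
#' @param source Source-calibration LIC estimates.
#' @return Corrected estimates `slope * source + intercept`.
#' @export
apply_transfer <- function(correction, source) {
  stopifnot(inherits(correction, "transfer_correction"))
  correction$slope * source + correction$intercept
}

#' Verify a transfer correction restores the identity line
#'
#' Applies the fitted correction to the source estimates and re-runs the
#' Passing-Bablok regression of the target on the corrected source. Because
#' the Passing-Bablok estimator is equivariant under the affine map it
#' itself produced (pairwise slopes all scale by 1/slope; residual medians
#' translate), the re-fit returns slope 1 and intercept 0 up to floating
#' rounding whenever the correction was fitted on the same pairs.
#'
#' @param correction A [fit_transfer()] result fitted on these pairs.
#' @param source,target The paired estimates the correction was fitted on.
#' @return The re-fitted `pb_fit` of `target` on the corrected source.
#' @export
apply_and_verify <- function(correction, source, target) {
  passing_bablok(apply_transfer(correction, source), target,
                 ci_level = correction$source_fit$ci_level)
}
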