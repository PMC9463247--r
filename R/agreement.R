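#' Bland-Altman method agreement
#'
#' Differences `d = a - b` on the absolute scale, or
#' `100 * (a - b) / pairwise mean` on the percent scale (pairs with mean 0
#' are excluded with a warning). Bias is `mean(d)`, limits of agreement
#' (LoA) are `bias +/- 1.96 * SD(d)` (the classic large-sample multiplier),
#' the bias CI uses the t distribution, and each LoA's CI uses the standard
#' error `sqrt(3 * SD^2 / n)`.
#'
#' @param a,b Paired measurements (n >= 3).
#' @param scale `"absolute"` or `"percent"`.
#' @param ci_level Confidence level, default 0.95.
#' @param loa_mult LoA multiplier, default 1.96 (config-exposed because some
#'   implementations use the t quantile instead).
#' @return An object of class `"agreement_result"`: `bias`, `bias_ci`,
#'   `loa` (lower, upper), `loa_ci_lower`, `loa_ci_upper`, `sd_diff`,
#'   `scale`, `n`.
#' @export
bland_altman <- function(a, b, scale = c("absolute", "percent"),
                         ci_level = 0.95, loa_mult = 1.96) {
  scale <- match.arg(scale)
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("Bland-Altman needs at least 3 pairs")
  if (scale == "percent") {
    m <- (a + b) / 2
    bad <- m == 0
    if (any(bad)) {
      warning(sum(bad), " pair(s) with zero mean excluded on percent scale")
      a <- a[!bad]; b <- b[!bad]; m <- m[!bad]
    }
    d <- 100 * (a - b) / m
  } else {
    d <- a - b
  }
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- sqrt(3 * s^2 / n)
  loa <- bias + c(-1, 1) * loa_mult * s
  structure(list(bias = bias, bias_ci = bias + c(-1, 1) * tq * se_bias,
                 loa = loa,
                 loa_ci_lower = loa[1] + c(-1, 1) * tq * se_loa,
                 loa_ci_upper = loa[2] + c(-1, 1) * tq * se_loa,
                 sd_diff = s, scale = scale, n = n, ci_level = ci_level),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  unit <- if (x$scale == "percent") "%" else ""
  cat(sprintf("Bland-Altman agreement (%s scale, n = %d)\n", x$scale, x$n))
  cat(sprintf("  bias %.3f%s  (%.0f%% CI %.3f to %.3f)\n", x$bias, unit,
              100 * x$ci_level, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LoA  %.3f to %.3f%s\n", x$loa[1], x$loa[2], unit))
  cat(sprintf("    lower LoA CI %.3f to %.3f; upper LoA CI %.3f to %.3f\n",
              x$loa_ci_lower[1], x$loa_ci_lower[2],
              x$loa_ci_upper[1], x$loa_ci_upper[2]))
  invisible(x)
}

#' Inter-observer reproducibility of the SIR measurement
#'
#' Percent-scale Bland-Altman of two observers' liver/muscle ratios, on all
#' pairs and on the subset whose pairwise mean ratio is at or above the
#' exclusion threshold (disagreement inflates at very low ratios, i.e. at
#' very high LIC, where the liver signal sits near background).
#'
#' @param obs1,obs2 Paired ratio measurements.
#' @param exclusion_ratio Mean-ratio threshold, default 0.2.
#' @param ... Passed to [bland_altman()].
#' @return List with `full` and `restricted` agreement results (`restricted`
#'   is `NULL` with a warning if no pair survives the threshold).
#' @export
interobserver <- function(obs1, obs2, exclusion_ratio = 0.2, ...) {
  full <- bland_altman(obs1, obs2, scale = "percent", ...)
  keep <- (obs1 + obs2) / 2 >= exclusion_ratio
  restricted <- if (sum(keep) >= 3) {
    bland_altman(obs1[keep], obs2[keep], scale = "percent", ...)
  } else {
    warning("restricted subset has fewer than 3 pairs")
    NULL
  }
  list(full = full, restricted = restricted)
}
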