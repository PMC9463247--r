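#' Exact null quantile of the absolute Kendall score
#'
#' For n untied pairs the Kendall score S = (#concordant - #discordant)
#' equals n(n-1)/2 - 2d, with d the number of inversions of a uniformly
#' random permutation. The inversion-count distribution (Mahonian numbers)
#' is built by dynamic programming, giving the smallest c with
#' P(|S| <= c) >= level. Used for the exact small-sample Passing-Bablok
#' confidence bounds.
#'
#' @param n Number of pairs (>= 2).
#' @param level Two-sided coverage, e.g. 0.95.
#' @return The quantile c.
#' @keywords internal
kendall_score_quantile <- function(n, level = 0.95) {
  stopifnot(n >= 2)
  counts <- 1 # permutations of size 1, by inversion count (0)
  for (m in 2:n) {
    new <- numeric(length(counts) + (m - 1))
    for (shift in 0:(m - 1))
      new[seq_along(counts) + shift] <- new[seq_along(counts) + shift] + counts
    counts <- new
  }
  p <- counts / sum(counts)              # P(d = 0 .. n(n-1)/2)
  npairs <- n * (n - 1) / 2
  s <- npairs - 2 * (seq_along(p) - 1)   # score for each inversion count
  for (c_try in sort(unique(abs(s)))) {
    if (sum(p[abs(s) <= c_try]) >= level) return(c_try)
  }
  npairs
}

pairwise_slopes <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- dy / dx
  s[is.finite(s)]
}

offset_median <- function(sorted_s, offset) {
  n <- length(sorted_s)
  idx <- function(i) sorted_s[min(max(i, 1), n)]
  if (n %% 2 == 1) idx((n + 1) / 2 + offset)
  else (idx(n / 2 + offset) + idx(n / 2 + 1 + offset)) / 2
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for method comparison, robust to outliers and to
#' measurement error in both variables. The slope is the shifted median of
#' all pairwise slopes (pairs with equal x excluded): slopes exactly equal
#' to -1 are discarded and the median index is shifted by
#' K = #\{slopes < -1\}, which makes the estimator invariant to exchanging
#' the axes. The intercept is `median(y - slope * x)`. Confidence bounds are
#' the rank-based construction on the ordered slopes: the half-width index
#' comes from the null distribution of the Kendall score, exact
#' (inversion-count DP) for n <= 30, normal approximation
#' `w * sqrt(n(n-1)(2n+5)/18)` above. The Cusum linearity test is run on the
#' fit (see [cusum_linearity()]); a failed test means the linearity premise
#' of the method is questionable.
#'
#' @param x,y Paired measurements (same length, n >= 3; x not all equal).
#' @param ci_level Two-sided confidence level, default 0.95.
#' The K-offset construction presumes a non-negative association (its use
#' case is comparing two methods that measure the same quantity). For
#' negatively associated data — e.g. a falling calibration line — the
#' estimator is applied to `(x, -y)` and the slope and intercept are
#' negated, which is the mirror-symmetric form of the same rule (the -1
#' slope exclusion maps to +1). The orientation is chosen by the sign of
#' Kendall's tau.
#'
#' @return An object of class `"pb_fit"`: `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `n`, `cusum_stat`, `linear`, `ci_level`.
#' @export
passing_bablok <- function(x, y, ci_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Passing-Bablok regression needs at least 3 pairs")
  if (length(unique(x)) == 1) stop("all x values are identical")

  if (stats::cor(x, y, method = "kendall") < 0) {
    flipped <- passing_bablok(x, -y, ci_level = ci_level)
    fit <- structure(list(slope = -flipped$slope,
                          slope_ci = sort(-flipped$slope_ci),
                          intercept = -flipped$intercept,
                          intercept_ci = sort(-flipped$intercept_ci),
                          n = n, ci_level = ci_level,
                          cusum_stat = NA_real_, linear = NA),
                     class = "pb_fit")
    cu <- cusum_linearity(x, y, fit)
    fit$cusum_stat <- cu$statistic
    fit$linear <- cu$linear
    return(fit)
  }

  s <- sort(pairwise_slopes(x, y))
  K <- sum(s < -1)
  s <- s[s != -1]
  N <- length(s)
  if (N == 0) stop("no usable pairwise slopes")

  slope <- offset_median(s, K)
  intercept <- stats::median(y - slope * x)

  C <- if (n <= 30) kendall_score_quantile(n, ci_level)
       else stats::qnorm(1 - (1 - ci_level) / 2) *
            sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  clamp <- function(i) min(max(i, 1), N)
  slope_ci <- c(s[clamp(M1 + K)], s[clamp(M2 + K)])
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))

  fit <- structure(list(slope = slope, slope_ci = slope_ci,
                        intercept = intercept, intercept_ci = sort(intercept_ci),
                        n = n, ci_level = ci_level,
                        cusum_stat = NA_real_, linear = NA),
                   class = "pb_fit")
  cu <- cusum_linearity(x, y, fit)
  fit$cusum_stat <- cu$statistic
  fit$linear <- cu$linear
  fit
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d)\n", x$n))
  cat(sprintf("  slope     %.4f  (%.0f%% CI %.4f to %.4f)\n", x$slope,
              100 * x$ci_level, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  (%.0f%% CI %.4f to %.4f)\n", x$intercept,
              100 * x$ci_level, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  Cusum linearity: stat %.3f -> %s\n", x$cusum_stat,
              if (isTRUE(x$linear)) "linearity not rejected" else "nonlinear"))
  invisible(x)
}

kolmogorov_critical <- function(level = 0.95) {
  # smallest h with K(h) >= level, K the Kolmogorov distribution
  K <- function(h) {
    k <- 1:100
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * h^2))
  }
  stats::uniroot(function(h) K(h) - level, c(0.3, 3))$root
}

#' Cusum test of the linearity assumption
#'
#' Orders the observations along the fitted line by the score `y + x/slope`,
#' assigns standardized signs to the residuals (`+sqrt(n_neg/n_pos)` above
#' the line, `-sqrt(n_pos/n_neg)` below), and takes the maximum absolute
#' cumulative sum, normalized by `sqrt(n_pos + n_neg)`. Under linearity the
#' statistic follows a Kolmogorov-type law; linearity is retained when it
#' stays below the critical value (1.36 at the 5% level).
#'
#' @param x,y The data the fit was computed on.
#' @param fit A `pb_fit` (or any list with `slope` and `intercept`).
#' @param level Test level complement, default 0.95 (i.e. a 5% test).
#' @return List with `statistic`, `critical`, `linear` (logical).
#' @export
cusum_linearity <- function(x, y, fit, level = 0.95) {
  r <- y - (fit$intercept + fit$slope * x)
  score <- if (fit$slope != 0) y + x / fit$slope else x
  r <- r[order(score)]
  pos <- r > 0; neg <- r < 0
  np <- sum(pos); nn <- sum(neg)
  if (np == 0 || nn == 0)
    return(list(statistic = 0, critical = kolmogorov_critical(level),
                linear = TRUE))
  steps <- numeric(length(r))
  steps[pos] <- sqrt(nn / np)
  steps[neg] <- -sqrt(np / nn)
  stat <- max(abs(cumsum(steps))) / sqrt(np + nn)
  crit <- kolmogorov_critical(level)
  list(statistic = stat, critical = crit, linear = stat < crit)
}
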