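# Independent brute-force oracle for the Passing-Bablok estimator:
# explicit double loop over pairs, manual shifted-median indexing, and the
# mirror rule for negative association. Kept deliberately separate from the
# package's vectorized implementation.
pb_oracle <- function(x, y) {
  if (stats::cor(x, y, method = "kendall") < 0) {
    f <- pb_oracle(x, -y)
    return(list(slope = -f$slope, intercept = -f$intercept))
  }
  slopes <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] != x[j]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  slopes <- sort(slopes[slopes != -1])
  N <- length(slopes)
  at <- function(i) slopes[min(max(i, 1), N)]
  slope <- if (N %% 2 == 1) at((N + 1) / 2 + K)
           else (at(N / 2 + K) + at(N / 2 + 1 + K)) / 2
  res <- sort(y - slope * x)
  m <- length(res)
  intercept <- if (m %% 2 == 1) res[(m + 1) / 2]
               else (res[m / 2] + res[m / 2 + 1]) / 2
  list(slope = slope, intercept = intercept)
}

# Horner-free polynomial evaluation oracle
polyval_oracle <- function(coeffs, x) {
  total <- 0
  for (k in seq_along(coeffs)) total <- total + coeffs[k] * x^(k - 1)
  total
}

# A paired dataset on the calibration-transfer scale. The x values are kept
# well separated relative to the noise so that no pairwise slope falls
# between -1 and the fitted slope: under that condition the self-correction
# identity of the rank-based estimator is exact, not just approximate.
transfer_pairs <- function(n = 27, seed = 42, slope = 0.84, intercept = 0.81,
                           noise_sd = 0.15) {
  set.seed(seed)
  dx <- 35 / n
  x <- seq(0.5, 35, length.out = n) + stats::runif(n, -0.1 * dx, 0.1 * dx)
  list(x = x, y = slope * x + intercept + stats::rnorm(n, 0, noise_sd))
}
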