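test_that("alpha polynomial matches an independent evaluation oracle", {
  co <- c(-1.98e-2, 3.77e-4, -2.40e-6, 4.82e-9, -2.00e-12)
  expect_equal(alpha_poly(0), -1.98e-2)
  expect_equal(alpha_poly(100), -1.48e-3, tolerance = 1e-6)
  expect_equal(alpha_poly(5, rep(0, 5)), 0)
  set.seed(51)
  for (x in c(runif(20, 0, 500), -3, 1e3)) {
    expect_equal(alpha_poly(x, co), polyval_oracle(co, x),
                 tolerance = 1e-12)
  }
})

test_that("no correction is applied at the reference TR, for any ratio", {
  fn <- adjustment_function()
  set.seed(52)
  ratios <- runif(1000, 0, 2)
  expect_identical(adjust_ratio(ratios, 684, fn), ratios)
  # ...and for arbitrary coefficient sets in the default mode
  fn2 <- adjustment_function(coeffs = rnorm(5))
  expect_identical(adjust_ratio(ratios, 684, fn2), ratios)
})

test_that("adjustment arithmetic and modes behave as documented", {
  # alpha == 0 -> identity at any TR
  fn0 <- adjustment_function(coeffs = rep(0, 5))
  expect_equal(adjust_ratio(0.8, 300, fn0), 0.8)
  # hand arithmetic with a constant alpha
  fnc <- adjustment_function(coeffs = c(-0.01, 0, 0, 0, 0))
  expect_equal(adjust_ratio(0.8, 560, fnc), 0.8 + (-0.01) * (684 - 560))
  fnd <- adjustment_function(coeffs = c(-0.001, 0, 0, 0, 0))
  expect_equal(adjust_ratio(0.8, 560, fnd), 0.8 - 0.001 * 124)
  expect_equal(adjust_ratio(0.8, 560, fnd), 0.676)
  # literal mode keeps the published "ratio x TR" term
  fnp <- adjustment_function(coeffs = c(-0.01, 0, 0, 0, 0),
                             mode = "as_printed")
  expect_equal(adjust_ratio(0.8, 560, fnp), 0.8 * 560 + (-0.01) * 124)
  # raw-signal argument mode
  fns <- adjustment_function(x_arg = "si_liver")
  expect_equal(adjust_ratio(0.8, 560, fns, si_liver = 100),
               0.8 + alpha_poly(100) * 124)
  expect_error(adjust_ratio(0.8, 560, fns), "si_liver")
})

test_that("transfer correction recovers an exact generating line", {
  x <- seq(1, 30, length.out = 12)
  y <- 0.84 * x + 0.81
  corr <- fit_transfer(x, y)
  expect_equal(corr$slope, 0.84, tolerance = 1e-12)
  expect_equal(corr$intercept, 0.81, tolerance = 1e-12)
  expect_error(fit_transfer(1:2, 1:2), "at least 3")
})

test_that("applying the fitted line as a correction restores identity", {
  # Equivariance of the estimator under its own affine map. The identity is
  # analytically exact when no pairwise slope lies between -1 and the fitted
  # slope (the -1-exclusion / K-offset correction is a discrete rule);
  # well-separated x with modest noise guarantees that, as in real
  # method-comparison data dominated by true between-sample variation.
  set.seed(53)
  for (rep in 1:50) {
    n <- sample(c(10, 27, 100), 1)
    dx <- 40 / n
    x <- seq(0.5, 40, length.out = n) + runif(n, -0.1 * dx, 0.1 * dx)
    y <- runif(1, 0.5, 1.5) * x + runif(1, -2, 2) + rnorm(n, 0, 0.1 * dx)
    corr <- fit_transfer(x, y)
    v <- apply_and_verify(corr, x, y)
    expect_equal(v$slope, 1, tolerance = 1e-9)
    expect_equal(v$intercept, 0, tolerance = 1e-9)
    expect_true(v$slope_ci[1] <= 1 && 1 <= v$slope_ci[2])
  }
  # on arbitrary noisy pairs the discrete exclusion rule can shift the
  # median by a notch: identity then holds to printed precision
  set.seed(54)
  for (rep in 1:20) {
    x <- runif(27, 0.5, 40)
    y <- 0.84 * x + 0.81 + rnorm(27, 0, 1)
    v <- apply_and_verify(fit_transfer(x, y), x, y)
    expect_equal(v$slope, 1, tolerance = 0.01)
    expect_lt(abs(v$intercept), 0.1)
  }
})
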