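test_that("textbook lines are reproduced exactly", {
  f <- passing_bablok(1:3, 1:3)
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  f2 <- passing_bablok(1:3, c(2, 4, 6))
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 0)
  # worked small case: 6 pairwise slopes, one -1 excluded, K = 0
  f3 <- passing_bablok(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(f3$slope, 4 / 3)
  expect_equal(f3$intercept, -1 / 3)
})

test_that("estimator agrees exactly with the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    x <- round(runif(n, 0, 10), 2)
    while (length(unique(x)) == 1) x <- round(runif(n, 0, 10), 2)
    b <- sample(c(-4, -1.5, -0.5, 0.5, 1, 2.5), 1)
    y <- b * x + rnorm(n, 0, 2)
    f <- passing_bablok(x, y)
    o <- pb_oracle(x, y)
    expect_identical(f$slope, o$slope)
    expect_identical(f$intercept, o$intercept)
  }
  # datasets engineered to contain exact -1 pairwise slopes
  f <- passing_bablok(c(0, 1, 2, 3, 5), c(3, 2, 4, 0, 6))
  o <- pb_oracle(c(0, 1, 2, 3, 5), c(3, 2, 4, 0, 6))
  expect_identical(f$slope, o$slope)
  expect_identical(f$intercept, o$intercept)
})

test_that("confidence bounds bracket the estimate and shrink with n", {
  set.seed(32)
  widths <- vapply(c(10, 30, 200), function(n) {
    x <- runif(n, 0, 10); y <- 2 * x + 1 + rnorm(n, 0, 0.5)
    f <- passing_bablok(x, y)
    expect_true(f$slope_ci[1] <= f$slope && f$slope <= f$slope_ci[2])
    expect_true(f$intercept_ci[1] <= f$intercept &&
                f$intercept <= f$intercept_ci[2])
    diff(f$slope_ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("negative-association data fit the mirrored construction", {
  set.seed(33)
  x <- runif(40, 0, 1)
  y <- 4.5 - 3.8 * x + rnorm(40, 0, 0.1)
  f <- passing_bablok(x, y)
  expect_equal(f$slope, -3.8, tolerance = 0.15)
  expect_true(f$slope_ci[1] < f$slope & f$slope < f$slope_ci[2])
})

test_that("degenerate inputs are rejected", {
  expect_error(passing_bablok(1:2, 1:2), "at least 3")
  expect_error(passing_bablok(c(2, 2, 2), 1:3), "identical")
})

test_that("Cusum retains clearly linear data and rejects a strong parabola", {
  set.seed(34)
  x <- seq(0, 10, length.out = 40)
  y_lin <- 2 * x + 1 + rep(c(0.01, -0.01), 20)
  f <- passing_bablok(x, y_lin)
  expect_true(f$linear)
  x2 <- seq(0, 10, length.out = 50)
  y2 <- x2^2
  f2 <- passing_bablok(x2, y2)
  cu <- cusum_linearity(x2, y2, f2)
  expect_false(cu$linear)
  expect_gt(cu$statistic, cu$critical)
  # degenerate size still yields a computable statistic and flag
  f3 <- passing_bablok(1:3, c(1, 2.1, 2.9))
  expect_true(is.finite(f3$cusum_stat))
  expect_true(f3$linear %in% c(TRUE, FALSE))
})

test_that("exact Kendall-score quantile matches enumeration for small n", {
  # n = 3: scores over the 6 permutations are {3, 1, 1, -1, -1, -3}
  # P(|S| <= 1) = 4/6 < 0.95, P(|S| <= 3) = 1
  expect_equal(sirlic:::kendall_score_quantile(3, 0.95), 3)
  expect_equal(sirlic:::kendall_score_quantile(3, 0.6), 1)
  # n = 4: 24 permutations, scores in {-6,...,6}; enumerate directly
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  score <- apply(perms, 1, function(p) {
    s <- 0
    for (i in 1:3) for (j in (i + 1):4) s <- s + sign(p[j] - p[i])
    s
  })
  want <- function(level) {
    for (c_try in sort(unique(abs(score))))
      if (mean(abs(score) <= c_try) >= level) return(c_try)
  }
  for (lev in c(0.5, 0.8, 0.95))
    expect_equal(sirlic:::kendall_score_quantile(4, lev), want(lev))
})
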