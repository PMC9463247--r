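make_records <- function(n, a = 2.5, b = -3.76, noise_cv = 0, seed = 1,
                         ratio_range = c(0.1, 1.2)) {
  set.seed(seed)
  ratio <- runif(n, ratio_range[1], ratio_range[2])
  lic <- exp(a + b * ratio)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    lic <- lic * exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  data.frame(ratio = ratio, lic_biopsy = lic, te_ms = 25, tr_ms = 560)
}

test_that("noiseless log-linear records return the generating curve exactly", {
  rec <- make_records(20)
  cal <- fit_calibration(rec, "sir")
  expect_equal(cal$curve$intercept_a, 2.5, tolerance = 1e-9)
  expect_equal(cal$curve$slope_b, -3.76, tolerance = 1e-9)
  expect_equal(cal$curve$form, "log_linear_sir")
  # round trip: predictions reproduce the generating LIC
  expect_equal(as.numeric(predict_lic(cal, rec$ratio)), rec$lic_biopsy,
               tolerance = 1e-8)
})

test_that("noisy parameter recovery lands within a few percent", {
  rec <- make_records(200, noise_cv = 0.10, seed = 2)
  cal <- fit_calibration(rec, "sir")
  expect_equal(cal$curve$intercept_a, 2.5, tolerance = 0.05)
  expect_equal(cal$curve$slope_b, -3.76, tolerance = 0.05)
})

test_that("the two SIR estimators are distinct but consistent", {
  rec <- make_records(100, noise_cv = 0.05, seed = 3)
  pb <- fit_calibration(rec, "sir", method = "pb_log")
  nl <- fit_calibration(rec, "sir", method = "nls_exp")
  expect_equal(pb$curve$form, "log_linear_sir")
  expect_equal(nl$curve$form, "exp_sir")
  expect_null(nl$pb)
  expect_equal(nl$curve$slope_b, pb$curve$slope_b, tolerance = 0.1)
})

test_that("non-positive biopsy LIC and tiny samples are rejected", {
  rec <- make_records(10)
  rec$lic_biopsy[3] <- 0
  expect_error(fit_calibration(rec, "sir"), "positive")
  expect_error(fit_calibration(make_records(2), "sir"), "fewer than 3")
})

test_that("prediction flags extrapolation beyond the calibrated range", {
  cv <- calibration_curve(2.5, -3.76, "log_linear_sir", lic_range = c(1, 30))
  p <- predict_lic(cv, c(0.4, -0.5))  # second ratio implies LIC ~ 45
  expect_equal(as.numeric(p[1]), exp(2.5 - 3.76 * 0.4), tolerance = 1e-12)
  expect_equal(as.numeric(p[1]), 2.7077, tolerance = 1e-4)
  expect_false(attr(p, "extrapolated")[1])
  expect_true(attr(p, "extrapolated")[2])
  # exp(0) = 1 mg/g when a + b*ratio = 0
  expect_equal(as.numeric(predict_lic(cv, 2.5 / 3.76)), 1, tolerance = 1e-12)
})

test_that("measuring range matches the closed form when T1 weighting is off", {
  m <- relaxation_model(proton_density = 1000, R1_0 = 1.7, R2_0 = 25,
                        R2s_0 = 40, r1 = 0, r2 = 4.5, r2s = 20,
                        muscle_T1 = 870, muscle_T2 = 45, noise_sigma = 0)
  # TR so long that the saturation-recovery factor is exactly 1
  closed <- function(te) (1000 * log(1000 / 25) / te - 25) / 4.5
  r25 <- measuring_range(m, acquisition_params("SE", 25, 1e9), 25)
  r12 <- measuring_range(m, acquisition_params("SE", 12, 1e9), 25)
  expect_equal(r25, closed(25), tolerance = 1e-4)
  expect_equal(r12, closed(12), tolerance = 1e-4)
  expect_equal(r25, 27.23, tolerance = 1e-3)
  expect_equal(r12, 62.76, tolerance = 1e-3)
  expect_gt(r12, r25)
  # floor <= 0 (or unreachable) -> unbounded sentinel
  expect_identical(measuring_range(m, acquisition_params("SE", 25, 1e9), 0),
                   Inf)
})

test_that("measuring range falls with echo time and with the floor", {
  m <- default_relaxation_model()
  tes <- c(5, 12, 25)
  r <- vapply(tes, function(te)
    measuring_range(m, acquisition_params("SE", te, 560), 25), numeric(1))
  expect_true(all(diff(r) < 0))
  fl <- c(10, 25, 60)
  rf <- vapply(fl, function(f)
    measuring_range(m, acquisition_params("SE", 12, 560), f), numeric(1))
  expect_true(all(diff(rf) < 0))
})

test_that("stratified R2 partitions records and flags perfect collinearity", {
  d <- data.frame(ratio = rep(seq(0.1, 1.3, length.out = 16), 2),
                  tr_ms = rep(c(600, 1200), each = 16))
  d$lic_biopsy <- exp(5.2 - 3.7 * d$ratio)   # spans both strata, tops > 115
  out <- suppressWarnings(stratified_r2(d, "ratio", cut = 34, upper = 115))
  expect_true(all(out$r_squared > 0.999))   # collinear within strata
  expect_equal(sum(out$n), sum(d$lic_biopsy < 115))
  w <- capture_warnings(stratified_r2(d[c(1:16, 20, 22), ], "ratio"))
  expect_true(any(grepl("omitted", w)))
  # permuted predictor carries no information
  set.seed(41)
  d2 <- data.frame(ratio = runif(200), tr_ms = 600)
  d2$lic_biopsy <- exp(runif(200, 0, 4))
  out2 <- stratified_r2(d2, "ratio")
  expect_true(all(out2$r_squared < 0.05))
})

test_that("Spearman rho: monotone invariance and a hand-ranked fixture", {
  x <- c(3, 1, 4, 1.5, 5); y <- c(9, 2, 11, 3, 20)
  # hand ranks: x -> 3 1 4 2 5, y -> 3 1 4 2 5 -> perfect agreement
  expect_equal(spearman_rho(x, y), 1)
  set.seed(42)
  a <- runif(30, 1, 10); b <- a * 2 + rnorm(30, 0, 1)
  expect_equal(spearman_rho(a, log(b)), spearman_rho(a, b))
  expect_equal(spearman_rho(1:10, 10:1), -1)
  expect_warning(rho <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rho))
  # small fixture against the brute-force rank formula (no ties)
  x5 <- c(10, 20, 30, 40, 50); y5 <- c(1, 3, 2, 5, 4)
  d <- rank(x5) - rank(y5)
  expect_equal(spearman_rho(x5, y5), 1 - 6 * sum(d^2) / (5 * (5^2 - 1)))
})

test_that("upper limit of normal is mean + 2 SD with its equivariance", {
  expect_equal(upper_limit_normal(c(0, 2)), 1 + 2 * sqrt(2))
  expect_equal(upper_limit_normal(rep(5, 4)), 5)
  set.seed(43)
  v <- rnorm(50)
  expect_equal(upper_limit_normal(v + 10), upper_limit_normal(v) + 10)
  expect_error(upper_limit_normal(1), "at least 2")
})
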