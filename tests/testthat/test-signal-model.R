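test_that("relaxation times follow the linear-relaxivity closure", {
  m <- relaxation_model(proton_density = 1000, R1_0 = 1, R2_0 = 25,
                        R2s_0 = 40, r1 = 0.02, r2 = 4.5, r2s = 20,
                        muscle_T1 = 870, muscle_T2 = 45, noise_sigma = 0)
  expect_equal(relaxation_from_lic(0, m)$T2, 40)          # 1000/25
  expect_equal(relaxation_from_lic(10, m)$T2, 1000 / 70)  # 1000/(25+45)
  # zero relaxivity -> no LIC dependence
  m0 <- relaxation_model(1000, 1, 25, 40, 0.02, 0, 20, 870, 45, 0)
  expect_equal(relaxation_from_lic(50, m0)$T2,
               relaxation_from_lic(0, m0)$T2)
  # strictly decreasing in lic for positive relaxivities
  lic <- seq(0, 100, by = 5)
  rx <- relaxation_from_lic(lic, m)
  expect_true(all(diff(rx$T1) < 0))
  expect_true(all(diff(rx$T2) < 0))
  expect_true(all(diff(rx$T2s) < 0))
  expect_error(relaxation_from_lic(-1, m), "non-negative")
})

test_that("relaxation model enforces its physical invariants", {
  expect_error(relaxation_model(1000, 1, 50, 40, 0, 0, 0, 870, 45, 0),
               "R2s_0")
  expect_error(relaxation_model(1000, -1, 25, 40, 0, 0, 0, 870, 45, 0),
               "non-negative")
})

test_that("spin-echo signal equation matches hand evaluation and identities", {
  p <- acquisition_params("SE", te = 25, tr = 560)
  expect_equal(se_signal(p, t1 = 400, t2 = 40, pd = 1000),
               1000 * (1 - exp(-560 / 400)) * exp(-25 / 40))
  expect_equal(se_signal(p, 400, 40, 1000), 403.2676, tolerance = 1e-4)
  # half-recovery at TR = T1 ln 2, decay disabled by a huge T2
  ph <- acquisition_params("SE", te = 1e-9, tr = 400 * log(2))
  expect_equal(se_signal(ph, 400, 1e12, 1000), 500, tolerance = 1e-6)
  # monotone: increasing in TR, decreasing in TE
  sig_tr <- vapply(c(300, 560, 800, 1200), function(tr)
    se_signal(acquisition_params("SE", 12, tr), 400, 40, 1000), numeric(1))
  expect_true(all(diff(sig_tr) > 0))
  sig_te <- vapply(c(5, 12, 25), function(te)
    se_signal(acquisition_params("SE", te, 560), 400, 40, 1000), numeric(1))
  expect_true(all(diff(sig_te) < 0))
  expect_error(se_signal(p, -1, 40, 1000), "positive")
})

test_that("signal falls with iron, and faster at the longer echo time", {
  m <- default_relaxation_model()
  lic <- seq(0, 40, by = 2)
  rx <- relaxation_from_lic(lic, m)
  s25 <- se_signal(acquisition_params("SE", 25, 560), rx$T1, rx$T2,
                   m$proton_density)
  s12 <- se_signal(acquisition_params("SE", 12, 560), rx$T1, rx$T2,
                   m$proton_density)
  expect_true(all(diff(s25) < 0))
  expect_true(all(s12 > s25))
})

test_that("gradient-echo series is mono-exponential with edge cases", {
  expect_equal(gre_series(10, 500, 0.1), 500 * exp(-1))
  expect_equal(gre_series(c(1, 5, 9), 500, 0), rep(500, 3))
  tes <- gre_echo_times()
  expect_equal(gre_series(tes, 300, 0.2), 300 * exp(-0.2 * tes))
  expect_error(gre_series(c(5, 2), 500, 0.1), "increasing")
  expect_error(gre_series(numeric(0), 500, 0.1), "non-empty")
})

test_that("Rician ROI mean: noiseless limit, noise floor, determinism", {
  expect_identical(rician_roi_mean(123.4, 0, 16), 123.4)
  # zero-signal expectation is the Rayleigh mean sigma*sqrt(pi/2)
  m <- rician_roi_mean(0, 10, 1e4, rng_seed = 99)
  expect_equal(m, 10 * sqrt(pi / 2), tolerance = 0.02)
  expect_identical(rician_roi_mean(50, 5, 100, rng_seed = 7),
                   rician_roi_mean(50, 5, 100, rng_seed = 7))
  # a seeded call must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(rician_roi_mean(10, 5, 10, rng_seed = 3))
  expect_identical(runif(1), r1)
})
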