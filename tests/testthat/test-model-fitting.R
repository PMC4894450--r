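test_that("exponential fits recover exact inputs and degenerate cases", {
  t <- seq(0, 100, by = 2)
  f <- fit_exponential(t, 2.4 * exp(0.008 * t))
  expect_equal(f$kappa, 0.008, tolerance = 1e-8)
  expect_true(f$converged)
  fc <- fit_exponential(t, rep(2.4, length(t)))
  expect_equal(fc$kappa, 0, tolerance = 1e-10)
  expect_error(fit_exponential(t, -2.4 * exp(0.008 * t)), "positive")
  expect_error(fit_exponential(1:3, c(1, 2, 3)), ">= 5")
})

test_that("the growth-rate estimator tightens as cells are added", {
  est <- vapply(c(10, 50, 200), function(n) {
    set.seed(n)
    ks <- vapply(seq_len(n), function(i) {
      t <- 0:72
      l <- 2.4 * exp(t / 125) * exp(rnorm(73, 0, 0.02))
      fit_exponential(t, l)$kappa
    }, numeric(1))
    abs(mean(ks) - 1 / 125)
  }, numeric(1))
  expect_lt(est[3], 2e-5)
  expect_lt(est[3], est[1] + 2e-5)
})

test_that("constriction fit round-trips printed parameters exactly", {
  phi <- seq(0, 0.9, length.out = 74)
  w <- constriction_model(phi, 0.805, 0.016, 1 / 125, 73)
  f <- fit_constriction(phi, w, tau = 73)
  expect_equal(f$w_max, 0.805, tolerance = 1e-4)
  expect_equal(f$kappa0, 0.016, tolerance = 1e-4)
  expect_equal(f$kappa_d, 1 / 125, tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("constriction fit is robust to measurement noise", {
  phi <- seq(0, 0.9, length.out = 74)
  w0 <- constriction_model(phi, 0.805, 0.016, 1 / 125, 73)
  dmax <- vapply(1:100, function(s) {
    set.seed(s)
    f <- fit_constriction(phi, w0 + rnorm(74, 0, 0.02), tau = 73)
    abs(f$w_max - 0.805)
  }, numeric(1))
  expect_lt(stats::median(dmax), 0.02)
})

test_that("flat input is reported as unconstricted, not fitted", {
  f <- fit_constriction(seq(0, 0.9, length.out = 20), rep(0.72, 20),
                        tau = 73)
  expect_true(f$flat_input)
  expect_equal(f$kappa0, 0)
})

test_that("the leading flat segment can be excluded from the fit", {
  phi <- seq(0, 0.9, length.out = 90)
  w_true <- constriction_model(phi, 0.805, 0.016, 1 / 125, 73)
  w_obs <- pmin(0.67, w_true)   # inherited birth dip hides the early part
  f <- fit_constriction(phi, w_obs, tau = 73, active_only = TRUE)
  expect_true(f$converged)
  expect_equal(f$w_max, 0.805, tolerance = 0.15)
})

test_that("summary reports are partial-tolerant and deterministic", {
  rep0 <- summary_report()
  expect_true(length(rep0$warnings) >= 2)
  t <- seq(0, 100, by = 2)
  gf <- fit_exponential(t, 2.4 * exp(t / 125))
  r1 <- summary_report(growth_fit = gf)
  r2 <- summary_report(growth_fit = gf)
  expect_identical(r1, r2)
  expect_equal(r1$kappa_inv_min, 125, tolerance = 1e-6)
})
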