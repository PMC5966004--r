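test_that("phase integration follows the trapezoid/exponential branch rule", {
  # constant activity: trapezoid, 5 MBq over 10 h
  expect_equal(integrate_phase(0.5, 10.5, 5, 5), 5 * 10 * 3600)
  # rising activity: trapezoid
  expect_equal(integrate_phase(1, 4, 2, 6), (2 + 6) / 2 * 3 * 3600)

  # decreasing activity: monoexponential through both points, checked
  # against dense numerical quadrature of the fitted exponential
  A1 <- 8; A2 <- 4; t1 <- 24; t2 <- 48
  got <- integrate_phase(t1, t2, A1, A2)
  lam <- log(A1 / A2) / ((t2 - t1) * 3600)
  f <- function(t_s) A1 * exp(-lam * (t_s - t1 * 3600))
  quad <- stats::integrate(f, t1 * 3600, t2 * 3600, rel.tol = 1e-12)$value
  expect_equal(got, quad, tolerance = 1e-9)
  expect_equal(got, (A1 - A2) / lam, tolerance = 1e-12)

  # washout to zero: exponential fit undefined, trapezoid limit
  expect_equal(integrate_phase(1, 4, 6, 0), 6 / 2 * 3 * 3600)

  expect_error(integrate_phase(4, 4, 1, 1), "ordering error")
  expect_error(integrate_phase(1, 4, -1, 1), "negative")
})

test_that("phase integration is vectorised per voxel", {
  A1 <- array(c(2, 8, 5, 0), dim = c(4, 1, 1))
  A2 <- array(c(6, 4, 5, 0), dim = c(4, 1, 1))
  got <- integrate_phase(1, 4, A1, A2)
  expect_equal(got[1, 1, 1], integrate_phase(1, 4, 2, 6))
  expect_equal(got[2, 1, 1], integrate_phase(1, 4, 8, 4))
  expect_equal(got[3, 1, 1], integrate_phase(1, 4, 5, 5))
  expect_equal(got[4, 1, 1], 0)
})

test_that("head and tail rules behave as defined", {
  expect_equal(head_integral(1, 10), 10 / 2 * 3600)
  expect_equal(head_integral(1, 0), 0)
  expect_equal(head_integral(1, 10, "flat"), 2 * head_integral(1, 10))

  lam_day <- log(2) / 86400
  expect_equal(tail_integral(1, lam_day), 86400 / log(2))
  expect_equal(tail_integral(0, lam_day), 0)
  expect_error(tail_integral(1, 0), "invalid parameter")
  # a final phase halving over 24 h implies lambda = ln2 per day
  lam_fit <- log(2 / 1) / (24 * 3600)
  expect_equal(tail_integral(1, lam_fit), 86400 / log(2))
})

test_that("series integration matches the closed form for monoexponentials", {
  # across the clinical effective half-life range, a monoexponential truth
  # sampled at the 5 scan times must integrate to within 2% of A0/lambda
  for (teff_d in c(0.66, 0.93, 1.6, 2.7, 3.9, 13, 29)) {
    lam <- lambda_per_second(teff_d)
    times <- c(1, 4, 24, 48, 72)
    A0 <- 20
    vals <- sample_monoexponential(A0, lam, times)
    maps <- lapply(vals, function(v) array(v, dim = c(3, 3, 3)))
    s <- scan_series(times, maps, 4.67)
    closed <- A0 / lam
    # default zero-start head assumes a rise the pure exponential does not
    # have; the residual equals the analytic (0, 1 h] discrepancy exactly
    total_rise <- integrate_series(s, lam, tail_rule = "fit")$values[1, 1, 1]
    head_true <- A0 / lam * (1 - exp(-lam * 3600))
    head_used <- vals[1] / 2 * 3600
    expect_equal(total_rise, closed - head_true + head_used, tolerance = 1e-6)
    # with the flat head rule (consistent with monoexponential truth) the
    # piecewise rule recovers the closed form within 2%
    total <- integrate_series(s, lam, head_rule = "flat",
                              tail_rule = "fit")$values[1, 1, 1]
    expect_lt(abs(total - closed) / closed, 0.02)
  }
})

test_that("series integration is linear, monotone and deterministic", {
  set.seed(5)
  times <- c(1, 4, 24, 48, 72)
  lam <- lambda_per_second(2.7)
  maps <- lapply(sample_monoexponential(1, lam, times), function(f) {
    array(f * runif(4^3, 0, 10), dim = c(4, 4, 4))
  })
  s <- scan_series(times, maps, 4.67)
  cum1 <- integrate_series(s, lam)
  cum2 <- integrate_series(s, lam)
  expect_identical(cum1$values, cum2$values)

  # linearity
  s2 <- scan_series(times, lapply(maps, function(m) 2 * m), 4.67)
  expect_equal(integrate_series(s2, lam)$values, 2 * cum1$values,
               tolerance = 1e-12)

  # all-zero series integrates to zero
  s0 <- scan_series(times, lapply(maps, function(m) m * 0), 4.67)
  expect_true(all(integrate_series(s0, lam)$values == 0))

  # pointwise monotonicity: raising one sample never lowers the integral
  maps_hi <- maps
  maps_hi[[3]] <- maps[[3]] * 1.5
  s_hi <- scan_series(times, maps_hi, 4.67)
  expect_true(all(integrate_series(s_hi, lam)$values >= cum1$values - 1e-12))
})

test_that("tail rule preference is honoured and recorded", {
  times <- c(1, 4, 24)
  lam_true <- lambda_per_second(1)
  vals <- sample_monoexponential(10, lam_true, times)
  s <- scan_series(times, lapply(vals, function(v) array(v, c(2, 2, 2))), 4.67)
  lam_fallback <- lambda_per_second(5)
  cum_fit <- integrate_series(s, lam_fallback, tail_rule = "fit")
  cum_eff <- integrate_series(s, lam_fallback, tail_rule = "effective")
  # fitted tail uses the final-phase rate, not the fallback
  expect_equal(cum_fit$values[1, 1, 1] - cum_eff$values[1, 1, 1],
               vals[3] / lam_true - vals[3] / lam_fallback,
               tolerance = 1e-9)
  expect_equal(cum_fit$provenance$tail_rule, "fit")
  expect_equal(cum_eff$provenance$tail_rule, "effective")

  # rising final phase: fit unavailable, falls back
  s_rise <- scan_series(times,
                        lapply(c(1, 2, 3), function(v) array(v, c(2, 2, 2))),
                        4.67)
  cum_rise <- integrate_series(s_rise, lam_fallback, tail_rule = "fit")
  expect_equal(cum_rise$values[1, 1, 1] -
                 integrate_series(s_rise, lam_fallback,
                                  tail_rule = "effective")$values[1, 1, 1],
               0, tolerance = 1e-12)
})
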