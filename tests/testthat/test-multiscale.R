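ms_adjusted <- function(eps = 0.1) {
  p <- adjusted_params()
  multiscale_params(p$r, p$K, delta = 0.0016, Delta = 0.001, epsilon = eps,
                    delta_units = "fraction")
}

test_that("periodic coefficients oscillate about their base values", {
  ms <- ms_adjusted()
  at0 <- periodic_coefficients(ms, 0)
  expect_equal(at0$K_t, ms$K0)
  expect_equal(at0$r_t, ms$r0)
  peak <- periodic_coefficients(ms, (pi / 2) / ms$epsilon)
  expect_equal(peak$K_t, ms$K0 + ms$delta)
  expect_equal(peak$r_t, ms$r0 + ms$Delta)
  t <- 13.7
  period <- 2 * pi / ms$epsilon
  expect_equal(periodic_coefficients(ms, t)$K_t,
               periodic_coefficients(ms, t + period)$K_t)
})

test_that("fast time accumulates the growth rate", {
  ms0 <- multiscale_params(0.04, 1e8, delta = 0, Delta = 0, epsilon = 0.1)
  expect_equal(fast_time(ms0, 25), 0.04 * 25)   # Delta = 0: linear
  ms <- multiscale_params(0.0374286, 1e8, delta = 0, Delta = 0.002,
                          epsilon = 0.1)
  expect_equal(fast_time(ms, 0), 0)
  ref <- stats::integrate(function(s) 0.0374286 + 0.002 * sin(0.1 * s),
                          0, 48, rel.tol = 1e-12)$value
  expect_equal(fast_time(ms, 48), ref, tolerance = 1e-10)
  # degenerate slow time: coefficients frozen
  frozen <- multiscale_params(0.03, 1e8, delta = 0, Delta = 0.001, epsilon = 0)
  expect_equal(fast_time(frozen, 10), 0.3)
})

test_that("expansion collapses to the constant-parameter sigmoid when amplitudes vanish", {
  set.seed(11)
  for (i in 1:10) {
    r0 <- runif(1, 0.01, 0.2)
    K0 <- 10^runif(1, 6, 9)
    N0 <- K0 * runif(1, 0.05, 0.7)
    t <- runif(1, 0, 100)
    ms <- multiscale_params(r0, K0, delta = 0, Delta = 0, epsilon = 0.1)
    expect_equal(multiscale_approx(ms, N0, t),
                 logistic_exact(logistic_params(r0, K0, N0), t),
                 tolerance = 1e-12)
  }
})

test_that("expansion honours the initial condition to machine precision", {
  # analytically exact: the correction numerator vanishes at t = 0
  # because r(0) = r0; floating-point grouping leaves rounding at ulp level
  expect_equal(multiscale_approx(ms_adjusted(), 76398000, 0), 76398000,
               tolerance = 1e-12)
})

test_that("expansion error shrinks with the slow-time scale at slope >= 1", {
  p <- adjusted_params()
  eps_grid <- c(0.2, 0.1, 0.05, 0.025)
  ts <- seq(0, 48, by = 1)
  errs <- vapply(eps_grid, function(eps) {
    ms <- ms_adjusted(eps)
    r_fn <- function(t) ms$r0 + ms$Delta * sin(eps * t)
    K_fn <- function(t) ms$K0 + ms$delta * sin(eps * t)
    ref <- ode_oracle(r_fn, K_fn, p$N0, ts)
    max(abs(multiscale_approx(ms, p$N0, ts) - ref) / ref)
  }, numeric(1))
  expect_gte(loglog_slope(eps_grid, errs), 1)
})

test_that("trajectories settle inside the band swept by the oscillating capacity", {
  ms <- ms_adjusted()
  p <- adjusted_params()
  ts <- seq(200, 600, by = 2)  # far past the transient: t0 >> 1
  vals <- multiscale_approx(ms, p$N0, ts)
  # o(1) margin covers the O(eps) correction, whose late-time magnitude
  # is about eps*delta/r0 on top of the +/- delta capacity band
  margin <- 1.5 * ms$epsilon * abs(ms$delta) / ms$r0 / ms$K0
  expect_true(all(vals > (ms$K0 - abs(ms$delta)) * (1 - margin)))
  expect_true(all(vals < (ms$K0 + abs(ms$delta)) * (1 + margin)))
})

test_that("expansion breakdown in the decay regime raises an error", {
  # engineered so the leading-order denominator crosses zero:
  # N0 >> K0 with a capacity peak while the fast time is still small
  ms <- multiscale_params(r0 = 0.001, K0 = 100, delta = 15, Delta = 0,
                          epsilon = 0.1)
  expect_error(multiscale_approx(ms, 1000, seq(0, 40, by = 0.5)),
               "breakdown")
})

test_that("forecast sweep of the base growth rate orders final sizes", {
  p <- adjusted_params()
  ms <- ms_adjusted()
  fps <- multiscale_fps_table(ms, p$N0, c(0.01, 0.02, 0.03, p$r),
                              horizon_t = 106)
  expect_true(all(diff(fps$fps) > 0))
  expect_equal(fps$fps_million, round(fps$fps / 1e6, 3))
  # deterministic re-run
  fps2 <- multiscale_fps_table(ms, p$N0, c(0.01, 0.02, 0.03, p$r),
                               horizon_t = 106)
  expect_identical(fps, fps2)
})

test_that("amplitude bounds on the coefficient perturbations are enforced", {
  expect_error(multiscale_params(0.03, 1e8, delta = 2e8, Delta = 0,
                                 epsilon = 0.1), "delta")
  expect_error(multiscale_params(0.03, 1e8, delta = 0, Delta = 0.05,
                                 epsilon = 0.1), "Delta")
})
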