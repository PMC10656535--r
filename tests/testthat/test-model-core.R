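test_that("logistic right-hand side has the textbook fixed points and maximum", {
  for (p in list(adjusted_params(), logistic_params(0.5, 1000, 10))) {
    expect_identical(logistic_rhs(p, 0), 0)
    expect_equal(logistic_rhs(p, p$K), 0)
    expect_equal(logistic_rhs(p, p$K / 2), p$r * p$K / 4)
  }
  expect_error(logistic_rhs(adjusted_params(), -1), "non-negative")
})

test_that("closed-form solution honours its initial condition and asymptote", {
  p <- adjusted_params()
  expect_equal(logistic_exact(p, 0), p$N0)
  # carrying-capacity limit once r*t is large
  expect_equal(logistic_exact(p, 60 / p$r), p$K, tolerance = 1e-9)
})

test_that("closed-form solution is monotone and bounded in both regimes", {
  tt <- seq(0, 200, by = 2.5)
  growth <- logistic_exact(logistic_params(0.05, 1e8, 3e7), tt)
  expect_true(all(diff(growth) > 0))
  expect_true(all(growth < 1e8))
  decay <- logistic_exact(logistic_params(0.05, 1e8, 2e8), tt)
  expect_true(all(diff(decay) < 0))
  expect_true(all(decay > 1e8))
  expect_identical(logistic_params(0.05, 1e8, 2e8)$regime, "decay")
})

test_that("three-point estimation inverts the closed form exactly", {
  set.seed(42)
  for (i in 1:20) {
    r <- runif(1, 0.01, 0.2)
    K <- 10^runif(1, 6, 9)
    N0 <- K * runif(1, 0.05, 0.6)
    T <- runif(1, 5, 30)
    p <- logistic_params(r, K, N0)
    N <- logistic_exact(p, c(0, T, 2 * T))
    est <- verhulst_estimate(N[1], N[2], N[3], T)
    expect_equal(est$K, K, tolerance = 1e-9)
    expect_equal(est$r, r, tolerance = 1e-9)
  }
})

test_that("degenerate three-point configurations are rejected", {
  # geometric triple: pure exponential, K undefined
  expect_error(verhulst_estimate(100, 200, 400, 10), "degenerate")
  # equilibrium triple: growth rate indeterminate
  expect_error(verhulst_estimate(500, 500, 500, 10))
  expect_error(verhulst_estimate(-1, 2, 3, 10), "positive")
})

test_that("time-varying explicit solution reduces to the constant-parameter sigmoid", {
  set.seed(7)
  for (i in 1:20) {
    r <- runif(1, 0.01, 0.15)
    K <- 10^runif(1, 6, 9)
    N0 <- K * runif(1, 0.05, 0.7)
    t <- runif(1, 1, 80)
    p <- logistic_params(r, K, N0)
    got <- timevarying_exact(function(q) r, function(q) K, N0, t)
    expect_equal(got, logistic_exact(p, t), tolerance = 1e-10)
  }
})

test_that("time-varying solution hits the Malthusian limit for huge capacity", {
  N0 <- 76398000
  got <- timevarying_exact(function(q) 0.03, function(q) 1e15 * N0, N0, 30)
  expect_equal(got, N0 * exp(0.03 * 30), tolerance = 1e-6)
})

test_that("time-varying solution matches an ODE oracle for periodic coefficients", {
  p <- adjusted_params()
  eps <- 0.1
  r_fn <- function(t) p$r + 1e-3 * sin(eps * t)
  K_fn <- function(t) p$K + 1e6 * sin(eps * t)
  got <- timevarying_exact(r_fn, K_fn, p$N0, 48)
  ref <- ode_oracle(r_fn, K_fn, p$N0, c(0, 48))[2]
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("predictor-corrector integration converges to the closed form at order >= 2", {
  p <- adjusted_params()
  hs <- c(0.2, 0.1, 0.05, 0.025)
  errs <- vapply(hs, function(h) {
    tr <- pece_solve(p, time_grid(0, h, round(48 / h)))
    abs(tail(tr$population, 1) - logistic_exact(p, 48)) / logistic_exact(p, 48)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gte(loglog_slope(hs, errs), 2)
})

test_that("zero growth gives a constant predictor-corrector trajectory", {
  # r = 0 is outside the parameter constructor's domain, so approximate
  # the zero field with the equilibrium initial condition instead
  p <- logistic_params(0.5, 1e6, 1e6)
  tr <- pece_solve(p, time_grid(0, 0.1, 50))
  expect_true(all(abs(tr$population - 1e6) < 1e-6))
})

test_that("predictor-corrector and embedded Runge-Kutta agree closely", {
  p <- adjusted_params()
  pece <- pece_solve(p, time_grid(0, 0.01, 4800))
  rkf <- rkf_solve(p, 48, tol = 1e-10)
  expect_equal(tail(pece$population, 1), tail(rkf$population, 1),
               tolerance = 1e-8)
})

test_that("embedded Runge-Kutta tracks the closed form within its tolerance", {
  for (tol in c(1e-6, 1e-9)) {
    p <- logistic_params(0.08, 5e7, 1e7)
    tr <- rkf_solve(p, 60, tol = tol)
    rel <- abs(tr$population - logistic_exact(p, tr$t)) /
      logistic_exact(p, tr$t)
    expect_lt(max(rel), 10 * tol)
  }
  expect_error(rkf_solve(adjusted_params(), 10, tol = 1e-2), "tol")
})

test_that("constructors enforce their invariants", {
  expect_error(logistic_params(-0.1, 1e8, 1e7), "'r'")
  expect_error(logistic_params(0.1, 1e8, 0), "'N0'")
  expect_error(time_grid(0, -0.1, 10), "'h'")
  expect_error(time_grid(0, 0.1, 0), "n_steps")
  expect_error(census_series(c(2000, 2000), c(1, 2)), "increasing")
  expect_error(trajectory(c(1, 2), c(3, -1), "x"), "non-negative")
})
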