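test_that("Mittag-Leffler kernel generalises the exponential", {
  z <- seq(-5, 5, by = 0.5)
  expect_equal(mittag_leffler(1, z), exp(z), tolerance = 1e-10)
  expect_equal(mittag_leffler(2, 1), cosh(1), tolerance = 1e-12)
  expect_equal(mittag_leffler(0.7, 0), 1)
  # large-argument fallback stays consistent with exp at alpha = 1-ish
  expect_equal(mittag_leffler(0.999999, 20) * 0.999999, exp(20^(1 / 0.999999)),
               tolerance = 1e-3)
})

test_that("fractional integral of a constant matches its closed form", {
  cfg1 <- frac_config(alpha = 1, normalization = 1)
  expect_equal(abc_integral_constant(1, cfg1, 2), 2)  # classical integral of 1
  expect_equal(abc_integral_constant(0, cfg1, 5), 0)
  cfg5 <- frac_config(alpha = 0.5, normalization = 1)
  expect_equal(abc_integral_constant(1, cfg5, 1), 0.5 + 1 / gamma(0.5),
               tolerance = 1e-12)
  # quadrature path of the operator agrees with the closed form ...
  expect_equal(abc_integral(function(v) 1, cfg5, 1),
               abc_integral_constant(1, cfg5, 1), tolerance = 1e-9)
  # ... and with direct numerical quadrature for a non-constant input
  f <- function(v) sin(v)
  direct <- (1 - 0.5) * f(2) +
    0.5 / gamma(0.5) * stats::integrate(function(v) (2 - v)^(-0.5) * f(v),
                                        0, 2, rel.tol = 1e-12)$value
  expect_equal(abc_integral(f, cfg5, 2), direct, tolerance = 1e-8)
})

test_that("two-step Lagrange weights match quadrature of their defining integrals", {
  # A1 = int_{t_k}^{t_{k+1}} (v - t_{k-1}) (t_{n+1} - v)^(a-1) dv, etc.
  # The substitution u = (t_{n+1} - v)^alpha regularises the integrable
  # endpoint singularity met when k = n and alpha < 1.
  quad_weights <- function(alpha, h, n, k) {
    tk <- k * h
    tn1 <- (n + 1) * h
    quad <- function(g) {
      (1 / alpha) * stats::integrate(
        function(u) g(tn1 - u^(1 / alpha)),
        ((n - k) * h)^alpha, ((n + 1 - k) * h)^alpha,
        rel.tol = 1e-12)$value
    }
    list(A1 = quad(function(v) v - (k - 1) * h),
         A2 = quad(function(v) v - tk))
  }
  for (alpha in c(0.3, 0.5, 0.8, 1)) {
    for (h in c(0.1, 0.5)) {
      for (n in c(0L, 3L, 7L)) {
        for (k in 0:n) {
          got <- abc_weights(alpha, h, n, k)
          ref <- quad_weights(alpha, h, n, k)
          expect_equal(got$A1, ref$A1, tolerance = 1e-9)
          expect_equal(got$A2, ref$A2, tolerance = 1e-9)
          expect_gt(got$A1, 0)
          expect_gte(got$A2, 0)
        }
      }
    }
  }
})

test_that("weights at the current step reduce to the classical pair", {
  for (h in c(0.01, 0.3, 2)) {
    w <- abc_weights(1, h, n = 6, k = 6)
    expect_equal(w$A1, 3 * h^2 / 2)
    expect_equal(w$A2, h^2 / 2)
  }
  expect_error(abc_weights(0.8, 0.1, n = 4, k = 5), "history index")
})

test_that("a single fractional step matches the hand-expanded recursion", {
  # n = 0, alpha = 1/2, h = 1, constant-extension history (N_{-1} = N0):
  # b1 = 1^a (2 + a) - 0 = 2.5, b2 = 1^(a+1) - 0 = 1, and
  # N_1 = N0 + (1-a) f0 + [a h^a / Gamma(a+2)] (2.5 f0 - 1 f0)
  p <- logistic_params(0.5, 1000, 100)
  f0 <- 0.5 * 100 * (1 - 100 / 1000)
  hand <- 100 + 0.5 * f0 + (0.5 / gamma(2.5)) * 1.5 * f0
  tr <- abc_solve(p, frac_config(alpha = 0.5, h = 1), time_grid(0, 1, 1))
  expect_equal(tr$population[2], hand, tolerance = 1e-12)
})

test_that("equilibrium start yields a flat fractional trajectory at any order", {
  p <- logistic_params(0.3, 5e5, 5e5)  # f identically zero on the trajectory
  for (a in c(0.6, 0.85, 1)) {
    tr <- abc_solve(p, frac_config(alpha = a, h = 0.5), time_grid(0, 0.5, 40))
    expect_true(all(abs(tr$population - 5e5) < 1e-7))
  }
})

test_that("classical-limit trajectory converges to the closed form as h shrinks", {
  p <- adjusted_params()
  tr <- abc_solve(p, frac_config(alpha = 1, h = 0.01),
                  time_grid(0, 0.01, 1000))
  rel <- abs(tail(tr$population, 1) - logistic_exact(p, 10)) /
    logistic_exact(p, 10)
  expect_lt(rel, 1e-3)
})

test_that("fractional trajectories stay positive and below the capacity", {
  p <- adjusted_params()
  for (a in c(0.8, 0.9, 1)) {
    tr <- abc_solve(p, frac_config(alpha = a, h = 0.05),
                    time_grid(0, 0.05, 960))
    expect_true(all(tr$population > 0))
    expect_true(all(tr$population < p$K * (1 + 1e-6)))
  }
})

test_that("forecast sweep shares its grid and keeps trajectories bracketed", {
  p <- adjusted_params()
  cfg <- frac_config(alpha = 1, h = 0.25)
  fc <- abc_forecast(p, c(1, 0.8), cfg, horizon = 100)
  expect_named(fc, c("abc(alpha=1)", "abc(alpha=0.8)"))
  expect_equal(fc[[1]]$t, fc[[2]]$t)
  # alpha = 1 entry identical to the plain solver path
  direct <- abc_solve(p, frac_config(alpha = 1, h = 0.25),
                      time_grid(0, 0.25, 400))
  expect_equal(fc[[1]]$population, direct$population)
  for (tr in fc) {
    final <- tail(tr$population, 1)
    expect_gt(final, p$N0)
    expect_lt(final, p$K)
  }
})

test_that("smaller fractional order slows the approach to capacity", {
  p <- adjusted_params()
  cfg <- frac_config(alpha = 1, h = 0.25)
  fc <- abc_forecast(p, c(1, 0.95, 0.9, 0.85, 0.8), cfg, horizon = 106)
  finals <- vapply(fc, function(tr) tail(tr$population, 1), numeric(1))
  expect_true(all(diff(finals) < 0))  # listed in decreasing alpha order
})
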