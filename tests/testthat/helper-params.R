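# Shared fixtures: the adjusted-census fitted parameter set used across
# the suite, and a small ODE oracle for the slowly varying logistic
# equation (independent of timevarying_exact / multiscale_approx, which
# never integrate this equation directly).

adjusted_params <- function() {
  logistic_params(r = 0.0374286, K = 225062093.9465337, N0 = 76398000)
}

# High-accuracy reference solution of dN/dt = r(t) N (1 - N/K(t)).
ode_oracle <- function(r_fn, K_fn, N0, times, rtol = 1e-12) {
  sol <- deSolve::lsoda(c(N = N0), times,
                        function(t, y, p) list(r_fn(t) * y * (1 - y / K_fn(t))),
                        parms = NULL, rtol = rtol, atol = rtol * N0)
  sol[, "N"]
}

# log-log slope of error against a scale parameter
loglog_slope <- function(scale, err) {
  unname(stats::coef(stats::lm(log(err) ~ log(scale)))[2])
}

make_tempdir <- function() {
  d <- tempfile("fraclogis-test-")
  dir.create(d)
  d
}
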