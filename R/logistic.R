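#' Logistic right-hand side
#'
#' Growth rate dN/dt = r N (1 - N/K) of the Verhulst model, in
#' individuals per year.
#'
#' @param params A [logistic_params()].
#' @param N Population, non-negative; vectorised.
#' @return Growth rate(s), individuals/year.
#' @examples
#' p <- logistic_params(0.03, 2e8, 7.6e7)
#' logistic_rhs(p, p$K)       # 0 at the carrying capacity
#' logistic_rhs(p, p$K / 2)   # maximum r*K/4
#' @export
logistic_rhs <- function(params, N) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(N))
  if (any(N < 0)) stop("'N' must be non-negative")
  params$r * N * (1 - N / params$K)
}

#' Closed-form logistic solution
#'
#' Evaluates N(t) = K / (1 + (K/N0 - 1) exp(-r t)).  Continuous and
#' monotone in `t` when `N0 < K`.  Negative `t` is permitted and amounts
#' to backward extrapolation of the sigmoid.
#'
#' @param params A [logistic_params()].
#' @param t Time(s) in years since the epoch; vectorised.
#' @return Population value(s), individuals.
#' @examples
#' p <- logistic_params(0.0374286, 225062093.9465337, 76398000)
#' logistic_exact(p, 48)
#' @export
logistic_exact <- function(params, t) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(t))
  params$K / (1 + (params$K / params$N0 - 1) * exp(-params$r * t))
}

#' Verhulst three-point parameter estimation
#'
#' Recovers the carrying capacity and growth rate from three population
#' values taken at equally spaced times 0, T, 2T:
#' \deqn{K = (N_0 N_1^2 + N_1^2 N_2 - 2 N_0 N_1 N_2) / (N_1^2 - N_0 N_2)}
#' \deqn{r = (1/T) \log[(1/N_0 - 1/K) / (1/N_1 - 1/K)]}
#' The round trip through [logistic_exact()] is exact on noiseless
#' logistic triples.
#'
#' A geometric triple (`N1^2 = N0*N2`, detected with relative tolerance
#' `1e-12`) is pure exponential growth with undefined K and is rejected,
#' as is any triple whose K produces a non-positive log argument.
#'
#' @param N0,N1,N2 Positive populations at times 0, T, 2T.
#' @param T Spacing of the observations, years; positive.
#' @return A list with components `K` and `r`.
#' @examples
#' p <- logistic_params(0.03, 2e8, 76398000)
#' N <- logistic_exact(p, c(0, 24, 48))
#' verhulst_estimate(N[1], N[2], N[3], T = 24)
#' @export
verhulst_estimate <- function(N0, N1, N2, T) {
  stopifnot(is.numeric(N0), is.numeric(N1), is.numeric(N2), is.numeric(T))
  if (N0 <= 0 || N1 <= 0 || N2 <= 0) stop("populations must be positive")
  if (T <= 0) stop("'T' must be positive")
  det <- N1^2 - N0 * N2
  if (abs(det) <= 1e-12 * N1^2)
    stop("degenerate triple: N1^2 = N0*N2 (pure exponential growth, ",
         "carrying capacity undefined)")
  K <- (N0 * N1^2 + N1^2 * N2 - 2 * N0 * N1 * N2) / det
  if (K <= 0) stop("three-point estimate produced non-positive K")
  arg_num <- 1 / N0 - 1 / K
  arg_den <- 1 / N1 - 1 / K
  if (!is.finite(arg_num / arg_den) || arg_num / arg_den <= 0)
    stop("non-positive log argument in the growth-rate estimate ",
         "(K does not exceed the observed populations)")
  r <- (1 / T) * log(arg_num / arg_den)
  if (!is.finite(r) || r == 0)
    stop("growth rate indeterminate for this triple (equilibrium data)")
  list(K = K, r = r)
}

#' Explicit solution of the logistic model with time-varying coefficients
#'
#' Evaluates
#' \deqn{N(t) = \frac{N_0 e^{\int_0^t r(q) dq}}
#'   {1 + N_0 \int_0^t \frac{r(q)}{K(q)} e^{\int_0^q r(s) ds} dq}}
#' for user-supplied coefficient functions.  Both integrals are obtained
#' by adaptive integration of their antiderivative system
#' \eqn{R'(q) = r(q)}, \eqn{J'(q) = r(q) e^{R(q)} / K(q)} with
#' `deSolve::lsoda` at absolute/relative tolerance `tol`, which avoids
#' nested-quadrature blow-up; the achieved tolerance is reported on
#' failure.  The default 1e-12 leaves margin on the function's 1e-10
#' relative accuracy contract.
#'
#' @param r_fn Function of time returning the growth rate; continuous and
#'   positive on `[0, max(t)]`.
#' @param K_fn Function of time returning the carrying capacity;
#'   continuous and positive on `[0, max(t)]`.
#' @param N0 Initial population, positive.
#' @param t Evaluation time(s), years, non-negative; vectorised.
#' @param tol Integration tolerance (absolute and relative), default 1e-12.
#' @return Population value(s), individuals.
#' @examples
#' # constant coefficients reduce to the closed-form sigmoid
#' timevarying_exact(function(t) 0.03, function(t) 2e8, 7.6e7, 48)
#' @export
timevarying_exact <- function(r_fn, K_fn, N0, t, tol = 1e-12) {
  stopifnot(is.function(r_fn), is.function(K_fn),
            is.numeric(N0), N0 > 0, is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  ord <- order(t)
  ts <- t[ord]
  out_times <- sort(unique(c(0, ts)))
  if (length(out_times) == 1L) return(rep(N0, length(t)))
  # J is integrated pre-scaled by N0 so both states are O(1) and the
  # absolute tolerance is meaningful for each.
  deriv <- function(q, y, parms) {
    rq <- r_fn(q)
    Kq <- K_fn(q)
    list(c(rq, N0 * rq * exp(y[1]) / Kq))
  }
  sol <- deSolve::lsoda(c(R = 0, J = 0), out_times, deriv, parms = NULL,
                        rtol = tol, atol = tol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf(paste0("integration of the coefficient antiderivatives did ",
                        "not converge at the requested tolerance %g"), tol))
  R <- sol[match(ts, out_times), "R"]
  J <- sol[match(ts, out_times), "J"]
  N <- unname(N0 * exp(R) / (1 + J))
  N[ord] <- N
  N
}

#' Adams-Bashforth-Moulton predictor-corrector (PECE) integration
#'
#' Fixed-step multistep integration of the logistic equation with the
#' classical 4th-order Adams-Bashforth predictor and Adams-Moulton
#' corrector in PECE mode.  The first three steps are seeded with
#' classical 4th-order Runge-Kutta one-step integration.  Converges to
#' [logistic_exact()] as the grid step shrinks.
#'
#' @param params A [logistic_params()].
#' @param grid A [time_grid()]; its `h` is the PECE step.
#' @return A [trajectory()] labelled `"pece"` with `grid$n_steps + 1`
#'   points.
#' @export
pece_solve <- function(params, grid) {
  stopifnot(inherits(params, "logistic_params"), inherits(grid, "time_grid"))
  h <- grid$h
  n <- grid$n_steps
  f <- function(N) params$r * N * (1 - N / params$K)
  N <- numeric(n + 1)
  N[1] <- params$N0
  fv <- numeric(n + 1)
  fv[1] <- f(N[1])
  # RK4 bootstrap for the first min(3, n) steps
  for (k in seq_len(min(3L, n))) {
    y <- N[k]
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    N[k + 1] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    fv[k + 1] <- f(N[k + 1])
  }
  if (n >= 4L) {
    for (k in 4:n) {
      # AB4 predictor, AM4 corrector (PECE)
      pred <- N[k] + h / 24 *
        (55 * fv[k] - 59 * fv[k - 1] + 37 * fv[k - 2] - 9 * fv[k - 3])
      fp <- f(pred)
      N[k + 1] <- N[k] + h / 24 *
        (9 * fp + 19 * fv[k] - 5 * fv[k - 1] + fv[k - 2])
      fv[k + 1] <- f(N[k + 1])
    }
  }
  trajectory(grid$times, N, "pece")
}

#' Adaptive Runge-Kutta-Fehlberg integration
#'
#' Integrates the logistic equation with the embedded Runge-Kutta-Fehlberg
#' 4(5) pair (`deSolve::rkMethod("rk45f")`, adaptive step control).  This
#' is the package's in-repo oracle for the integer-order solvers.
#'
#' @param params A [logistic_params()].
#' @param t_end End time, years; positive.
#' @param tol Relative (and absolute, scaled by `N0`) tolerance, in
#'   (0, 1e-3].
#' @param n_out Number of output points (default 101).
#' @return A [trajectory()] labelled `"rkf45"`.
#' @export
rkf_solve <- function(params, t_end, tol = 1e-8, n_out = 101L) {
  stopifnot(inherits(params, "logistic_params"),
            is.numeric(t_end), t_end > 0, is.numeric(tol))
  if (tol <= 0 || tol > 1e-3) stop("'tol' must be in (0, 1e-3]")
  times <- seq(0, t_end, length.out = as.integer(n_out))
  deriv <- function(t, y, parms) list(params$r * y * (1 - y / params$K))
  sol <- deSolve::ode(c(N = params$N0), times, deriv, parms = NULL,
                      method = deSolve::rkMethod("rk45f"),
                      rtol = tol, atol = tol * params$N0)
  if (nrow(sol) < length(times))
    stop("step-size underflow: adaptive integration stopped before t_end")
  trajectory(sol[, "time"], sol[, "N"], "rkf45")
}
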