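#' Logistic model parameters
#'
#' Bundle of the Verhulst logistic triple: intrinsic growth rate `r`
#' (per year), carrying capacity `K` (individuals) and initial population
#' `N0` (individuals at model time t = 0).  The triple fully determines a
#' constant-parameter logistic trajectory.
#'
#' With `N0 < K` the trajectory is the standard sigmoid growth regime; a
#' triple with `N0 >= K` is accepted but flagged as the decay/saturated
#' regime via the `regime` field.
#'
#' @param r Intrinsic growth rate, per year. Must be positive.
#' @param K Carrying capacity, individuals. Must be positive.
#' @param N0 Initial population at t = 0, individuals. Must be positive.
#' @return An object of class `logistic_params`.
#' @examples
#' logistic_params(r = 0.03, K = 2e8, N0 = 7.6e7)
#' @export
logistic_params <- function(r, K, N0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(N0), length(N0) == 1L, is.finite(N0))
  if (r <= 0) stop("'r' must be positive")
  if (K <= 0) stop("'K' must be positive")
  if (N0 <= 0) stop("'N0' must be positive")
  structure(
    list(r = r, K = K, N0 = N0,
         regime = if (N0 < K) "growth" else "decay"),
    class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic parameters (%s regime)\n", x$regime))
  cat(sprintf("  r  = %.10g per year\n", x$r))
  cat(sprintf("  K  = %.10g individuals\n", x$K))
  cat(sprintf("  N0 = %.10g individuals\n", x$N0))
  invisible(x)
}

#' Uniform time grid
#'
#' Discretisation `t_start + k*h`, `k = 0..n_steps`, in years offset from
#' the epoch year.
#'
#' @param t_start Start time, years (offset from the epoch year).
#' @param h Step size, years; positive.
#' @param n_steps Number of steps; at least 1.
#' @return An object of class `time_grid` with a `times` vector of length
#'   `n_steps + 1`.
#' @export
time_grid <- function(t_start = 0, h, n_steps) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L,
            is.numeric(h), length(h) == 1L,
            is.numeric(n_steps), length(n_steps) == 1L)
  if (h <= 0) stop("'h' must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  structure(
    list(t_start = t_start, h = h, n_steps = n_steps,
         times = t_start + h * (0:n_steps)),
    class = "time_grid")
}

#' Population trajectory
#'
#' A solver output: strictly increasing times (years), non-negative
#' population values and the label of the producing scheme.  Stored as a
#' data frame with columns `t`, `population`, `scheme` so trajectories
#' write directly to CSV.
#'
#' @param t Times in years, strictly increasing.
#' @param population Population counts, non-negative, same length as `t`.
#' @param scheme Identifier of the producing solver, e.g. `"logistic"`.
#' @return A data frame of class `trajectory`.
#' @export
trajectory <- function(t, population, scheme) {
  stopifnot(length(t) == length(population), is.character(scheme))
  if (any(diff(t) <= 0)) stop("trajectory times must be strictly increasing")
  if (any(population < 0)) stop("trajectory values must be non-negative")
  structure(
    data.frame(t = as.numeric(t), population = as.numeric(population),
               scheme = scheme, stringsAsFactors = FALSE),
    class = c("trajectory", "data.frame"))
}

#' Census time series
#'
#' Observed (year, count) pairs with the calendar year mapped to model
#' time t = 0.  Model time for an observation is `year - epoch_year`.
#'
#' @param years Calendar years, strictly increasing.
#' @param counts Population counts, positive, same length as `years`.
#' @param epoch_year Calendar year mapped to t = 0; defaults to the first
#'   census year.
#' @return An object of class `census_series`.
#' @export
census_series <- function(years, counts, epoch_year = years[1]) {
  stopifnot(is.numeric(years), is.numeric(counts),
            length(years) == length(counts), length(years) >= 1L)
  if (any(diff(years) <= 0)) stop("census years must be strictly increasing")
  if (any(counts <= 0)) stop("census counts must be positive")
  structure(
    list(years = as.numeric(years), counts = as.numeric(counts),
         epoch_year = as.numeric(epoch_year)),
    class = "census_series")
}

#' @export
print.census_series <- function(x, ...) {
  cat(sprintf("Census series: %d observations, %d-%d (epoch %d)\n",
              length(x$years), as.integer(min(x$years)),
              as.integer(max(x$years)), as.integer(x$epoch_year)))
  invisible(x)
}

#' Model time of census observations
#'
#' @param census A [census_series()].
#' @return Numeric vector of times in years since the epoch year.
#' @export
census_times <- function(census) {
  stopifnot(inherits(census, "census_series"))
  census$years - census$epoch_year
}

#' Fractional-scheme configuration
#'
#' Settings for the Atangana-Baleanu-Caputo solver and the stability
#' criteria: fractional order `alpha`, time horizon `b` (years) entering
#' the existence-uniqueness and Hyers-Ulam bounds, the normalization
#' ABC(alpha), and step size `h` (years).
#'
#' The normalization defaults to 1 for all alpha, consistent with its
#' endpoint constraint ABC(0) = ABC(1) = 1 and the worked stability
#' computation at alpha = 1/2.
#'
#' @param alpha Fractional order, in (0, 1].
#' @param b Time horizon for the stability criteria, years; positive.
#' @param normalization Value of ABC(alpha); positive, default 1.
#' @param h Step size, years; positive.
#' @return An object of class `frac_config`.
#' @export
frac_config <- function(alpha = 1, b = 10, normalization = 1, h = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(b), length(b) == 1L,
            is.numeric(normalization), length(normalization) == 1L,
            is.numeric(h), length(h) == 1L)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (b <= 0) stop("'b' must be positive")
  if (normalization <= 0) stop("'normalization' must be positive")
  if (h <= 0) stop("'h' must be positive")
  structure(list(alpha = alpha, b = b, normalization = normalization, h = h),
            class = "frac_config")
}

#' Slowly varying (multiple-scales) model parameters
#'
#' Parameters of the periodically perturbed logistic model with
#' `K(eps*t) = K0 + delta*sin(eps*t)` and `r(eps*t) = r0 + Delta*sin(eps*t)`:
#' base growth rate `r0` (per year), base carrying capacity `K0`
#' (individuals), oscillation amplitudes `delta` (capacity) and `Delta`
#' (rate), and the slow-time scale `epsilon` (per year).
#'
#' `delta` may be given in absolute individuals (`delta_units =
#' "absolute"`) or as a fraction of `K0` (`delta_units = "fraction"`);
#' it is stored internally in absolute units.
#'
#' @param r0 Base growth rate, per year; positive.
#' @param K0 Base carrying capacity, individuals; positive.
#' @param delta Amplitude of the carrying-capacity oscillation.
#' @param Delta Amplitude of the growth-rate oscillation, per year.
#' @param epsilon Slow-time scale, per year; non-negative.
#' @param delta_units Units of `delta`: `"absolute"` individuals or
#'   `"fraction"` of `K0`.
#' @return An object of class `multiscale_params`.
#' @examples
#' multiscale_params(r0 = 0.0374286, K0 = 225062093.9465337,
#'                   delta = 0.0016, Delta = 0.001, epsilon = 0.1,
#'                   delta_units = "fraction")
#' @export
multiscale_params <- function(r0, K0, delta = 0, Delta = 0, epsilon = 0,
                              delta_units = c("absolute", "fraction")) {
  delta_units <- match.arg(delta_units)
  stopifnot(is.numeric(r0), is.numeric(K0), is.numeric(delta),
            is.numeric(Delta), is.numeric(epsilon))
  if (r0 <= 0) stop("'r0' must be positive")
  if (K0 <= 0) stop("'K0' must be positive")
  if (epsilon < 0) stop("'epsilon' must be non-negative")
  if (delta_units == "fraction") delta <- delta * K0
  if (abs(delta) >= K0)
    stop("|delta| must be smaller than K0 (coefficients must stay positive)")
  if (abs(Delta) >= r0)
    stop("|Delta| must be smaller than r0 (coefficients must stay positive)")
  structure(list(r0 = r0, K0 = K0, delta = delta, Delta = Delta,
                 epsilon = epsilon),
            class = "multiscale_params")
}

#' @export
print.multiscale_params <- function(x, ...) {
  cat("Multiple-scales logistic parameters\n")
  cat(sprintf("  r0 = %.10g, K0 = %.10g\n", x$r0, x$K0))
  cat(sprintf("  delta = %.10g, Delta = %.10g, epsilon = %.10g\n",
              x$delta, x$Delta, x$epsilon))
  invisible(x)
}
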