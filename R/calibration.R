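#' Fit the logistic model to a census series
#'
#' Minimises the sum of squared residuals between observed counts and the
#' closed-form sigmoid over (r, K) by bounded nonlinear least squares
#' (Levenberg-Marquardt, `minpack.lm::nlsLM`), with the initial
#' population fixed to the first observation.  The starting point is the
#' Verhulst three-point estimate on the first, middle and last
#' observations unless `seed_estimate` is supplied.
#'
#' Bounds keep the sigmoid identifiable on short series:
#' r in (1e-4, 1) and K in (max observed count, 20 x max observed
#' count).  Counts are fitted on the raw scale by default (matching the
#' magnitude of typical fitted capacities); `log_scale = TRUE` fits
#' log-counts instead.
#'
#' @param census A [census_series()] with at least 3 observations.
#' @param seed_estimate Optional list with components `K` and `r` used as
#'   the starting point.
#' @param log_scale Fit log-counts instead of raw counts; default FALSE.
#' @return An object of class `fit_result`: `params`
#'   ([logistic_params()] with the fitted r, K and the input N0),
#'   `residuals` (observed - fitted, individuals), `regression_r`
#'   (Pearson correlation of observed and modelled series), `r_squared`,
#'   `converged`, `n_iter`, `at_bounds` (TRUE when an estimate sits on a
#'   box bound, flagging model mismatch such as a decreasing series) and
#'   `message`.
#' @examples
#' p <- logistic_params(0.0374286, 225062093.9465337, 76398000)
#' cen <- generate_census(p, 1974, seq(1974, 2022, by = 2))
#' fit_logistic(cen)$params
#' @export
fit_logistic <- function(census, seed_estimate = NULL, log_scale = FALSE) {
  stopifnot(inherits(census, "census_series"))
  n_obs <- length(census$counts)
  if (n_obs < 3L) stop("at least 3 observations are required to fit (r, K)")
  tt <- census_times(census)
  y <- census$counts
  N0 <- y[1]
  lo <- c(r = 1e-4, K = max(y) * (1 + 1e-9))
  up <- c(r = 1, K = 20 * max(y))
  if (is.null(seed_estimate)) {
    mid <- (n_obs + 1L) %/% 2L
    seed_estimate <- tryCatch(
      verhulst_estimate(y[1], y[mid], y[n_obs], T = (tt[n_obs] - tt[1]) / 2),
      error = function(e) list(K = 2 * max(y), r = 0.03))
  }
  start <- c(r = min(max(seed_estimate$r, lo["r"] * 2), up["r"] / 2),
             K = min(max(seed_estimate$K, lo["K"] * (1 + 1e-6)), up["K"] * 0.99))
  model_fn <- function(r, K) N0 * K / (N0 + (K - N0) * exp(-r * tt))
  obs <- if (log_scale) log(y) else y
  pred_fn <- if (log_scale) {
    function(r, K) log(model_fn(r, K))
  } else {
    model_fn
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(obs ~ pred_fn(r, K),
                      start = as.list(start), lower = lo, upper = up,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(
      list(params = NULL, residuals = rep(NA_real_, n_obs),
           regression_r = NA_real_, r_squared = NA_real_,
           converged = FALSE, n_iter = 0L, at_bounds = NA,
           message = conditionMessage(fit)),
      class = "fit_result"))
  }
  est <- stats::coef(fit)
  fitted_counts <- model_fn(est["r"], est["K"])
  stats_out <- regression_stats(y, fitted_counts)
  rel <- function(x, b) abs(x - b) / max(abs(b), 1e-300)
  at_bounds <- rel(est["r"], lo["r"]) < 1e-6 || rel(est["r"], up["r"]) < 1e-6 ||
    rel(est["K"], lo["K"]) < 1e-6 || rel(est["K"], up["K"]) < 1e-6
  structure(
    list(params = logistic_params(unname(est["r"]), unname(est["K"]), N0),
         residuals = y - fitted_counts,
         regression_r = stats_out$regression_r,
         r_squared = stats_out$r_squared,
         converged = isTRUE(fit$convInfo$isConv),
         n_iter = fit$convInfo$finIter,
         at_bounds = unname(at_bounds),
         message = fit$convInfo$stopMessage),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Logistic fit",
      if (isTRUE(x$converged)) "(converged)\n" else "(NOT converged)\n")
  if (!is.null(x$params)) {
    cat(sprintf("  r = %.10g, K = %.10g (N0 fixed at %.10g)\n",
                x$params$r, x$params$K, x$params$N0))
    cat(sprintf("  regression r = %.4f, R^2 = %.4f, iterations = %d\n",
                x$regression_r, x$r_squared, x$n_iter))
    if (isTRUE(x$at_bounds))
      cat("  warning: an estimate sits on a box bound (model mismatch?)\n")
  } else {
    cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' Goodness-of-fit statistics
#'
#' Pearson correlation between observed and modelled series, and the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` with the
#' modelled series as the prediction of the observed.  A 95% confidence
#' interval on the correlation is attached via the Fisher z
#' transformation (a normal-approximation interpretation of
#' "correlation at 95% CI level").
#'
#' The correlation component is symmetric in its arguments and invariant
#' to affine rescaling; R^2 is not (it is a prediction score).
#'
#' @param observed Observed series, length >= 2 with nonzero variance.
#' @param modeled Modelled series of the same length.
#' @return A list with `regression_r`, `r_squared`, and `conf_int`
#'   (length-2 vector, 95% Fisher-z interval for the correlation; NA
#'   when fewer than 4 points).
#' @examples
#' regression_stats(c(1, 2, 3), c(3, 2, 1))  # r = -1, R^2 = -3
#' @export
regression_stats <- function(observed, modeled) {
  stopifnot(is.numeric(observed), is.numeric(modeled))
  if (length(observed) != length(modeled))
    stop("'observed' and 'modeled' must have equal length")
  if (length(observed) < 2L) stop("at least 2 points are required")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed series has zero variance")
  r_val <- if (stats::sd(modeled) == 0) 0 else stats::cor(observed, modeled)
  ss_res <- sum((observed - modeled)^2)
  ci <- c(NA_real_, NA_real_)
  n <- length(observed)
  if (n >= 4L && abs(r_val) < 1) {
    z <- atanh(r_val)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(regression_r = r_val, r_squared = 1 - ss_res / ss_tot, conf_int = ci)
}

#' Per-year absolute errors and target-year percent error
#'
#' Compares a model trajectory with a census series on their overlapping
#' years: absolute errors |observed - modelled| per year, and the percent
#' error |modelled - observed| / observed x 100 at a target year.  The
#' trajectory is interpolated linearly at the census years (model
#' trajectories are dense relative to census spacing).
#'
#' @param census A [census_series()].
#' @param traj A [trajectory()] on the same epoch (its `t` is years since
#'   `census$epoch_year`).
#' @param target_year Calendar year at which the headline percent error
#'   is reported; must be covered by both series.
#' @return An object of class `error_report`: `years`, `absolute_errors`
#'   (individuals), `percent_error_at_target` (raw value, %),
#'   `percent_error_formatted` (two decimals, scientific below 1e-3) and
#'   `target_year`.
#' @export
error_report <- function(census, traj, target_year) {
  stopifnot(inherits(census, "census_series"), inherits(traj, "trajectory"))
  traj_years <- census$epoch_year + traj$t
  overlap <- census$years[census$years >= min(traj_years) - 1e-9 &
                          census$years <= max(traj_years) + 1e-9]
  if (length(overlap) == 0L)
    stop("census series and trajectory share no overlapping years")
  modeled <- stats::approx(traj_years, traj$population, xout = overlap)$y
  observed <- census$counts[match(overlap, census$years)]
  if (!(target_year %in% overlap))
    stop(sprintf("target year %s is not covered by both series", target_year))
  i <- match(target_year, overlap)
  pct <- abs(modeled[i] - observed[i]) / observed[i] * 100
  structure(
    list(years = overlap,
         absolute_errors = stats::setNames(abs(observed - modeled), overlap),
         percent_error_at_target = pct,
         percent_error_formatted = format_percent_error(pct),
         target_year = target_year),
    class = "error_report")
}

#' Format a percent error for reports
#'
#' Two decimals by default; scientific notation below 1e-3 (mirroring the
#' conventional comparison-table layout).
#'
#' @param pct Percent error value(s).
#' @param digits Decimals used on the fixed-point branch, default 2.
#' @return Character vector such as `"0.09%"` or `"3.0e-08%"`.
#' @export
format_percent_error <- function(pct, digits = 2) {
  vapply(pct, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p != 0 && p < 1e-3) sprintf("%.1e%%", p)
    else sprintf(paste0("%.", digits, "f%%"), p)
  }, character(1))
}
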