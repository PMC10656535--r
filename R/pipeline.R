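#' Calendar-year / model-time conversion
#'
#' All calendar-to-model-time arithmetic is centralised here to avoid
#' off-by-one-year drift: model time is `year - epoch_year`, so 2022
#' maps to t = 48 for epoch 1974.
#'
#' @param year Calendar year(s).
#' @param epoch_year Calendar year mapped to t = 0.
#' @return Model time(s), years.
#' @export
year_to_time <- function(year, epoch_year) year - epoch_year

#' @rdname year_to_time
#' @param t Model time(s), years.
#' @export
time_to_year <- function(t, epoch_year) epoch_year + t

#' Analysis configuration
#'
#' A single configuration object drives calibration, scheme comparison,
#' stability checks and forecasting.  Exactly one census source must be
#' given: a CSV path, a synthetic specification, or a
#' [census_series()] object.
#'
#' @param census Census source: a path to a `year,population` CSV, a
#'   [census_series()], or a list of arguments for [generate_census()]
#'   (fields `params`, `census_years`, plus optional `annualize`,
#'   `noise`, `N0`).
#' @param epoch_year Calendar year mapped to t = 0; defaults to the
#'   first census year once the census is loaded.
#' @param target_year Year of the scheme-comparison table; must lie
#'   within (or immediately adjacent to) the census span.
#' @param horizon_year Forecast horizon; must exceed `target_year`.
#' @param params Optional [logistic_params()]; when supplied, fitting is
#'   skipped and these parameters drive every scheme.
#' @param target_census_value Optional observed count at `target_year`
#'   used for the percent-error column (overrides the census series
#'   value; the published comparison tables quote an adjusted census
#'   figure at the target year).
#' @param alphas Fractional orders of the forecast sweep.
#' @param alpha_analysis Fractional order of the comparison-table
#'   fractional row; default 0.95 (an analysis choice, see the methods
#'   vignette).
#' @param alpha_stability Fractional order of the stability report,
#'   default 0.5.
#' @param h_analysis Step size (years) of the PECE/ABC analysis runs.
#' @param h_forecast Step size (years) of the forecast runs.
#' @param b Stability horizon, years (always explicit).
#' @param normalization ABC normalization, default 1.
#' @param multiscale A [multiscale_params()] or NULL: NULL derives one
#'   from the (fitted or fixed) logistic parameters with the package's
#'   default amplitudes (epsilon 0.1, delta 0.0016*K0, Delta 0.001).
#' @param r0_sweep Base growth rates of the multiscale forecast sweep.
#' @param interpolation Census interpolation, `"monotone"` or
#'   `"linear"`; recorded in every report.
#' @param seed Integer seed for every source of randomness.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(census,
                            target_year,
                            horizon_year,
                            epoch_year = NULL,
                            params = NULL,
                            target_census_value = NULL,
                            alphas = c(1, 0.95, 0.9, 0.85, 0.8),
                            alpha_analysis = 0.95,
                            alpha_stability = 0.5,
                            h_analysis = 0.01,
                            h_forecast = 0.05,
                            b = 10,
                            normalization = 1,
                            multiscale = NULL,
                            r0_sweep = NULL,
                            interpolation = c("monotone", "linear"),
                            seed = 1L) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.numeric(target_year), is.numeric(horizon_year))
  if (horizon_year <= target_year)
    stop("'horizon_year' must exceed 'target_year'")
  if (!is.null(params)) stopifnot(inherits(params, "logistic_params"))
  if (!is.null(multiscale)) stopifnot(inherits(multiscale, "multiscale_params"))
  structure(
    list(census = census, epoch_year = epoch_year,
         target_year = target_year, horizon_year = horizon_year,
         params = params, target_census_value = target_census_value,
         alphas = alphas, alpha_analysis = alpha_analysis,
         alpha_stability = alpha_stability,
         h_analysis = h_analysis, h_forecast = h_forecast,
         b = b, normalization = normalization,
         multiscale = multiscale, r0_sweep = r0_sweep,
         interpolation = interpolation, seed = as.integer(seed)),
    class = "analysis_config")
}

load_census <- function(config) {
  cen <- config$census
  if (inherits(cen, "census_series")) {
    out <- cen
  } else if (is.character(cen)) {
    out <- read_census_csv(cen)
  } else if (is.list(cen)) {
    args <- cen
    args$epoch_year <- args$epoch_year %||%
      config$epoch_year %||% args$census_years[1]
    args$interpolation <- args$interpolation %||% config$interpolation
    if (!is.null(args$noise) && !inherits(args$noise, "noise_model"))
      args$noise <- do.call(noise_model, args$noise)
    out <- do.call(generate_census, args)
  } else {
    stop("'census' must be a path, a census_series or a synthetic spec list")
  }
  if (!is.null(config$epoch_year) && out$epoch_year != config$epoch_year)
    out$epoch_year <- config$epoch_year
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_multiscale <- function(params) {
  multiscale_params(r0 = params$r, K0 = params$K,
                    delta = 0.0016, Delta = 0.001, epsilon = 0.1,
                    delta_units = "fraction")
}

#' Run the scheme-comparison analysis
#'
#' Fits the logistic parameters to the census (or accepts fixed ones),
#' evaluates all four schemes at the target year -- closed-form
#' logistic, PECE predictor-corrector, ABC fractional-order, and the
#' multiple-scales approximation -- computes per-scheme percent errors
#' against the observed target-year count, goodness-of-fit statistics
#' over the full overlap, and the stability report.  Fully
#' deterministic given the configuration and seed.
#'
#' @param config An [analysis_config()].
#' @return An object of class `comparison_report`: `schemes` (data
#'   frame with `scheme`, `population`, `percent_error`,
#'   `percent_error_formatted`), `fit`, `regression`, `stability`,
#'   `target_year`, `observed_target`, `interpolation`, `config_echo`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  census <- load_census(config)
  t_target <- year_to_time(config$target_year, census$epoch_year)
  span <- range(census$years)
  if (config$target_year < span[1] - 1 || config$target_year > span[2] + 1)
    stop("'target_year' must lie within or adjacent to the census span")
  observed_target <- config$target_census_value %||%
    census$counts[match(config$target_year, census$years)]
  if (is.na(observed_target))
    stop("no observed count at the target year; supply 'target_census_value'")

  fit <- NULL
  params <- config$params
  if (is.null(params)) {
    fit <- fit_logistic(census)
    if (!isTRUE(fit$converged))
      stop("logistic calibration did not converge: ", fit$message)
    params <- fit$params
  }

  h <- config$h_analysis
  n_steps <- ceiling(t_target / h)
  grid <- time_grid(0, h, n_steps)
  cfg_abc <- frac_config(alpha = config$alpha_analysis, b = config$b,
                         normalization = config$normalization, h = h)
  ms <- config$multiscale %||% default_multiscale(params)

  at_target <- function(traj) {
    stats::approx(traj$t, traj$population, xout = t_target)$y
  }
  preds <- c(
    logistic_exact = logistic_exact(params, t_target),
    pece = at_target(pece_solve(params, grid)),
    abc = at_target(abc_solve(params, cfg_abc, grid)),
    multiscale = multiscale_approx(ms, params$N0, t_target))
  pct <- abs(preds - observed_target) / observed_target * 100
  schemes <- data.frame(
    scheme = names(preds),
    population = unname(preds),
    percent_error = unname(pct),
    percent_error_formatted = format_percent_error(unname(pct)),
    stringsAsFactors = FALSE)

  modeled_overlap <- logistic_exact(params, census_times(census))
  reg <- regression_stats(census$counts, modeled_overlap)

  cfg_stab <- frac_config(alpha = config$alpha_stability, b = config$b,
                          normalization = config$normalization, h = h)
  structure(
    list(schemes = schemes,
         fit = fit,
         params = params,
         regression = reg,
         stability = stability_report(params, cfg_stab),
         target_year = config$target_year,
         observed_target = observed_target,
         interpolation = config$interpolation,
         multiscale = ms,
         seed = config$seed),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Scheme comparison at %d (observed %.4f)\n",
              as.integer(x$target_year), x$observed_target))
  df <- x$schemes
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-16s %20.4f   %s\n", df$scheme[i], df$population[i],
                df$percent_error_formatted[i]))
  cat(sprintf("  regression r = %.4f, R^2 = %.4f\n",
              x$regression$regression_r, x$regression$r_squared))
  print(x$stability)
  invisible(x)
}

#' Run the forecast sweeps
#'
#' Produces forecast trajectories to the horizon year for the
#' closed-form logistic scheme, each fractional order in the sweep, and
#' the multiple-scales scheme, plus a final-population-size table over
#' the base-growth-rate sweep (millions, 3 decimals).
#'
#' @param config An [analysis_config()]; its `params` are used directly
#'   when given, otherwise the census is calibrated first.
#' @return A list of class `forecast_bundle` with `trajectories` (named
#'   list of [trajectory()] objects), `fps_table`, `horizon_year`,
#'   `epoch_year`.
#' @export
run_forecast <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  census <- load_census(config)
  params <- config$params
  if (is.null(params)) {
    fit <- fit_logistic(census)
    if (!isTRUE(fit$converged))
      stop("logistic calibration did not converge: ", fit$message)
    params <- fit$params
  }
  t_hor <- year_to_time(config$horizon_year, census$epoch_year)
  cfg <- frac_config(alpha = 1, b = config$b,
                     normalization = config$normalization,
                     h = config$h_forecast)
  times <- seq(0, t_hor, by = 1)
  trajs <- list(
    logistic = trajectory(times, logistic_exact(params, times), "logistic"))
  trajs <- c(trajs, abc_forecast(params, config$alphas, cfg, t_hor))
  ms <- config$multiscale %||% default_multiscale(params)
  trajs$multiscale <- multiscale_forecast(ms, params$N0, times)
  r0s <- config$r0_sweep %||% c(params$r, 0.03, 0.02, 0.01)
  fps <- multiscale_fps_table(ms, params$N0, sort(unique(r0s)), t_hor)
  structure(
    list(trajectories = trajs, fps_table = fps,
         horizon_year = config$horizon_year,
         epoch_year = census$epoch_year, params = params),
    class = "forecast_bundle")
}

#' Read a census CSV
#'
#' Two columns `year,population`, header required, UTF-8; populations
#' are parsed permissively (thousands separators and spaces stripped).
#' Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A [census_series()] with the first year as epoch.
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8", strip.white = TRUE)
  if (!identical(tolower(names(df))[1:2], c("year", "population")))
    stop("census CSV must have header 'year,population'")
  years <- suppressWarnings(as.numeric(df[[1]]))
  counts <- suppressWarnings(as.numeric(gsub("[ ,]", "", df[[2]])))
  bad <- which(is.na(years) | is.na(counts))
  if (length(bad) > 0)
    stop(sprintf("non-numeric census entr%s at line %s of %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad + 1L, collapse = ", "), path))
  census_series(years, counts)
}

#' Write a census series to CSV
#'
#' @param census A [census_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  stopifnot(inherits(census, "census_series"))
  utils::write.csv(
    data.frame(year = census$years, population = census$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `t,year,population,scheme`; the calendar year is derived from
#' the epoch year.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param epoch_year Calendar year at t = 0.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, epoch_year) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(
    data.frame(t = traj$t, year = time_to_year(traj$t, epoch_year),
               population = traj$population, scheme = traj$scheme),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a comparison report or forecast bundle to disk
#'
#' Emits a JSON report (populations to 4 decimals on the table surface,
#' raw values alongside; percent errors formatted to 2 decimals or
#' scientific below 1e-3), CSV tables for the scheme comparison /
#' final-population-size sweep, trajectory CSVs for forecasts, and a
#' human-readable summary recording every interpolation and scheme
#' toggle in effect.  No timestamps are written, so identical inputs
#' yield byte-identical files.
#'
#' @param report A `comparison_report` or `forecast_bundle`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(report, "comparison_report")) {
    json_path <- file.path(dir, "comparison_report.json")
    payload <- list(
      target_year = report$target_year,
      observed_target = report$observed_target,
      interpolation = report$interpolation,
      seed = report$seed,
      schemes = transform(report$schemes,
                          population = round(population, 4)),
      params = list(r = report$params$r, K = report$params$K,
                    N0 = report$params$N0),
      regression = list(r = report$regression$regression_r,
                        r_squared = report$regression$r_squared),
      stability = unclass(report$stability),
      fitted = !is.null(report$fit),
      multiscale = unclass(report$multiscale))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    csv_path <- file.path(dir, "scheme_comparison.csv")
    utils::write.csv(report$schemes, csv_path, row.names = FALSE)
    txt_path <- file.path(dir, "summary.txt")
    con <- file(txt_path, open = "wt")
    sink(con); print(report); sink(); close(con)
    files <- c(json_path, csv_path, txt_path)
  } else if (inherits(report, "forecast_bundle")) {
    fps_path <- file.path(dir, "fps_table.csv")
    utils::write.csv(report$fps_table, fps_path, row.names = FALSE)
    traj_paths <- vapply(names(report$trajectories), function(nm) {
      p <- file.path(dir, paste0("forecast_", gsub("[^A-Za-z0-9._-]", "_", nm),
                                 ".csv"))
      write_trajectory_csv(report$trajectories[[nm]], p, report$epoch_year)
      p
    }, character(1))
    json_path <- file.path(dir, "forecast_report.json")
    finals <- vapply(report$trajectories, function(tr)
      tr$population[nrow(tr)], numeric(1))
    jsonlite::write_json(
      list(horizon_year = report$horizon_year,
           epoch_year = report$epoch_year,
           params = list(r = report$params$r, K = report$params$K,
                         N0 = report$params$N0),
           final_population = as.list(finals),
           fps_table = report$fps_table),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(fps_path, unname(traj_paths), json_path)
  } else {
    stop("'report' must be a comparison_report or forecast_bundle")
  }
  invisible(files)
}
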