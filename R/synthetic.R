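#' Observation-noise model for synthetic census data
#'
#' Census counts are positive and their errors roughly proportional to
#' the count, so the generator's noise is multiplicative lognormal:
#' each count is multiplied by `exp(sigma*Z - sigma^2/2)` with
#' `Z ~ N(0,1)`, a mean-one perturbation whose log-ratio to truth has
#' expectation `-sigma^2/2`.  Real census processes do not advertise an
#' error model; this is an explicit artifact choice for simulation
#' studies.
#'
#' @param kind `"none"` or `"multiplicative_lognormal"`.
#' @param sigma Relative noise scale, non-negative; ignored when
#'   `kind = "none"`. Default 0.005.
#' @param seed Integer seed; mandatory for reproducible pipelines.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_lognormal"),
                        sigma = 0.005, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# Interpolate (years, counts) onto out_years.  Monotone piecewise-cubic
# (Fritsch-Carlson via splinefun "monoH.FC") by default -- census series
# are monotone and overshoot-free interpolation preserves that -- with
# linear as the config option.  The choice is recorded in every report.
interpolate_series <- function(years, counts, out_years,
                               method = c("monotone", "linear")) {
  method <- match.arg(method)
  if (method == "monotone") {
    stats::splinefun(years, counts, method = "monoH.FC")(out_years)
  } else {
    stats::approx(years, counts, xout = out_years)$y
  }
}

#' Generate a census-like series from a forward model
#'
#' Emulates a decennial-census series: the chosen forward model
#' (constant-parameter logistic or slowly varying multiple-scales) is
#' evaluated at the census years; with `annualize = TRUE` the census
#' points are filled to annual resolution by the configured
#' interpolation (mirroring the calibration pathway, so synthetic and
#' real data follow identical plumbing); multiplicative lognormal noise
#' is then applied with the model's seed.  Deterministic given inputs
#' and seed; the caller's RNG state is left untouched.
#'
#' @param params A [logistic_params()] or [multiscale_params()].
#' @param epoch_year Calendar year mapped to t = 0; must equal the first
#'   census year.
#' @param census_years Increasing calendar years of the census waves.
#' @param annualize Fill intermediate years by interpolation; default
#'   FALSE.
#' @param noise A [noise_model()]; default noiseless.
#' @param interpolation `"monotone"` (default) or `"linear"`.
#' @param N0 Initial population; required for a
#'   [multiscale_params()] model (which does not carry one), ignored for
#'   a logistic model.
#' @return A [census_series()].
#' @examples
#' p <- logistic_params(0.0374286, 225062093.9465337, 76398000)
#' generate_census(p, 1974, c(1974, 1981, 1991, 2001, 2011, 2022))
#' @export
generate_census <- function(params, epoch_year, census_years,
                            annualize = FALSE, noise = noise_model("none"),
                            interpolation = c("monotone", "linear"),
                            N0 = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.numeric(census_years), length(census_years) >= 2L,
            inherits(noise, "noise_model"))
  if (any(diff(census_years) <= 0)) stop("census years must be increasing")
  if (census_years[1] != epoch_year)
    stop("the first census year must equal the epoch year")
  tt <- census_years - epoch_year
  truth <- if (inherits(params, "logistic_params")) {
    logistic_exact(params, tt)
  } else if (inherits(params, "multiscale_params")) {
    if (is.null(N0)) stop("'N0' is required for a multiscale model")
    multiscale_approx(params, N0, tt)
  } else {
    stop("'params' must be logistic_params or multiscale_params")
  }
  if (annualize) {
    years <- seq(census_years[1], census_years[length(census_years)])
    counts <- interpolate_series(census_years, truth, years, interpolation)
  } else {
    years <- census_years
    counts <- truth
  }
  if (noise$kind == "multiplicative_lognormal" && noise$sigma > 0) {
    counts <- counts * with_local_seed(noise$seed, {
      exp(noise$sigma * stats::rnorm(length(counts)) - noise$sigma^2 / 2)
    })
  }
  census_series(years, counts, epoch_year)
}

# Run expr under a seeded RNG without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

ref_constants_env <- new.env(parent = emptyenv())

#' Published reference constants of the Bangladesh / Sri Lanka analyses
#'
#' Returns printed constants of the published census analyses that this
#' package's validation suite compares against -- fitted parameter sets,
#' the 2022 census values, scheme-comparison table cells, the
#' final-population-size sweep, and the (typographically ambiguous,
#' flagged) multiple-scales amplitude settings.  Values are stored
#' verbatim in a versioned JSON constants file under `extdata` and are
#' never computed.
#'
#' Dotted names address nested slices, e.g. `"census_2022.adjusted"`.
#' Call with no argument to get the full list.
#'
#' @param name Identifier such as `"adjusted_params"`,
#'   `"census_2022.adjusted"`, `"fps_table"`, `"scheme_tables.bd_adjusted"`,
#'   `"sri_lanka_2020"`, `"stability"`, `"table2_flagged"`; or `NULL` for
#'   everything.
#' @return The requested constant(s).
#' @examples
#' reference_constants("adjusted_params")
#' @export
reference_constants <- function(name = NULL) {
  if (is.null(ref_constants_env$data)) {
    path <- system.file("extdata", "reference_constants.json",
                        package = "fraclogis", mustWork = TRUE)
    ref_constants_env$data <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- ref_constants_env$data
  if (is.null(name)) return(out)
  for (part in strsplit(name, ".", fixed = TRUE)[[1]]) {
    if (!is.list(out) || is.null(out[[part]]))
      stop(sprintf("unknown reference constant '%s'", name))
    out <- out[[part]]
  }
  out
}
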