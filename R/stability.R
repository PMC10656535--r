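#' Lipschitz constant of the logistic right-hand side
#'
#' On trajectories bounded by the initial population, the logistic
#' right-hand side satisfies a Lipschitz condition with constant
#' \deqn{\Psi = r + 2 r N_0 / K,}
#' the quantity entering both the existence-uniqueness and Hyers-Ulam
#' criteria of the fractional model.
#'
#' @param params A [logistic_params()].
#' @return The constant Psi, per year.
#' @examples
#' lipschitz_psi(logistic_params(0.0374286, 225062093.9465337, 76398000))
#' @export
lipschitz_psi <- function(params) {
  stopifnot(inherits(params, "logistic_params"))
  params$r + 2 * params$r * params$N0 / params$K
}

#' Existence-uniqueness criterion of the fractional model
#'
#' The fractional logistic model has a unique solution on `[0, b]` when
#' \deqn{\Omega = \frac{1-\alpha}{ABC(\alpha)}\Psi +
#'   \frac{\alpha b^\alpha}{\Gamma(\alpha) ABC(\alpha)}\Psi < 1.}
#' At alpha = 1 (Gamma(1) = 1, first term vanishing) this reduces to
#' `Omega = b * Psi`.
#'
#' @param psi Lipschitz constant, positive (see [lipschitz_psi()]).
#' @param cfg A [frac_config()] supplying `alpha`, `b`, `normalization`.
#' @return A list with `omega` and `uniqueness_ok` (`omega < 1`).
#' @export
uniqueness_criterion <- function(psi, cfg) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi > 0,
            inherits(cfg, "frac_config"))
  a <- cfg$alpha
  B <- cfg$normalization
  omega <- (1 - a) / B * psi + a * cfg$b^a / (gamma(a) * B) * psi
  list(omega = omega, uniqueness_ok = omega < 1)
}

#' Hyers-Ulam stability criterion of the fractional model
#'
#' Computes the stability constant of the worked criterion
#' \deqn{\eta = \frac{\Gamma(\alpha) + b^\alpha}
#'   {\Gamma(\alpha) ABC(\alpha)} \Psi,}
#' flagged stable when `eta < 1`: every approximate solution then lies
#' within a bounded multiple of its defect of an exact solution.
#'
#' The literature states the theorem-form condition with the same
#' structure as the uniqueness bound; both appear with the Lipschitz
#' constant in the role of the generic constant, and the worked
#' computation's form above carries the verifiable numbers, so it is the
#' default.  `form = "theorem"` computes the alternative
#' \eqn{[(1-\alpha)/ABC(\alpha) + \alpha b^\alpha /
#' (\Gamma(\alpha) ABC(\alpha))]\,\Psi} instead.
#'
#' @param psi Lipschitz constant, positive.
#' @param cfg A [frac_config()] supplying `alpha`, `b`, `normalization`.
#' @param form `"worked"` (default) or `"theorem"`.
#' @return A list with `eta` and `hyers_ulam_ok` (`eta < 1`).
#' @examples
#' cfg <- frac_config(alpha = 0.5, b = 10, normalization = 1)
#' hyers_ulam_criterion(0.06283730012, cfg)
#' @export
hyers_ulam_criterion <- function(psi, cfg, form = c("worked", "theorem")) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi > 0,
            inherits(cfg, "frac_config"))
  form <- match.arg(form)
  a <- cfg$alpha
  B <- cfg$normalization
  eta <- switch(form,
    worked  = (gamma(a) + cfg$b^a) / (gamma(a) * B) * psi,
    theorem = ((1 - a) / B + a * cfg$b^a / (gamma(a) * B)) * psi)
  list(eta = eta, hyers_ulam_ok = eta < 1)
}

#' Stability report for a model configuration
#'
#' Bundles the computable stability constants for a logistic parameter
#' set and fractional configuration: the Lipschitz constant Psi, the
#' uniqueness criterion value Omega with its flag, and the Hyers-Ulam
#' constant eta with its flag.
#'
#' The horizon `b` is always an explicit part of `cfg`: it is an
#' analysis choice, not derivable from the data span.
#'
#' @param params A [logistic_params()].
#' @param cfg A [frac_config()].
#' @return An object of class `stability_report` with fields `psi`,
#'   `omega`, `eta`, `uniqueness_ok`, `hyers_ulam_ok`, `alpha`, `b`,
#'   `normalization`.
#' @export
stability_report <- function(params, cfg) {
  psi <- lipschitz_psi(params)
  uq <- uniqueness_criterion(psi, cfg)
  hu <- hyers_ulam_criterion(psi, cfg)
  structure(
    list(psi = psi, omega = uq$omega, eta = hu$eta,
         uniqueness_ok = uq$uniqueness_ok,
         hyers_ulam_ok = hu$hyers_ulam_ok,
         alpha = cfg$alpha, b = cfg$b, normalization = cfg$normalization),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report (alpha = %g, b = %g, ABC = %g)\n",
              x$alpha, x$b, x$normalization))
  cat(sprintf("  Psi   = %.11g (Lipschitz)\n", x$psi))
  cat(sprintf("  Omega = %.11g  -> uniqueness %s\n", x$omega,
              if (x$uniqueness_ok) "OK (< 1)" else "NOT satisfied"))
  cat(sprintf("  eta   = %.11g  -> Hyers-Ulam %s\n", x$eta,
              if (x$hyers_ulam_ok) "stable (< 1)" else "NOT satisfied"))
  invisible(x)
}
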