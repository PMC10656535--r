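Package: fraclogis
Title: Fractional-Order and Multi-Scale Logistic Models for Population
    Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates the Verhulst logistic growth model to census time
    series and propagates it forward with four schemes: the closed-form
    logistic solution, Adams-Bashforth-Moulton predictor-corrector (PECE)
    integration, an Atangana-Baleanu-Caputo (ABC) fractional-order solver
    built on the Mittag-Leffler kernel with two-step Lagrange weights, and
    a two-term multiple-scales approximation with slowly varying, periodic
    growth rate and carrying capacity.  Includes Verhulst three-point
    parameter estimation, bounded nonlinear least-squares calibration,
    existence-uniqueness and Hyers-Ulam stability constants, a synthetic
    decennial-census generator with multiplicative lognormal noise, and a
    pipeline producing scheme-comparison and forecast reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
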