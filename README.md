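# fraclogis

Logistic population-growth analysis and forecasting with four
propagation schemes: the closed-form Verhulst sigmoid, classical
Adams–Bashforth–Moulton predictor–corrector (PECE) integration, an
Atangana–Baleanu–Caputo (ABC) fractional-order solver built on the
Mittag–Leffler kernel, and a two-term multiple-scales approximation for
slowly varying, periodically perturbed growth rate and carrying
capacity.

The package is aimed at demographers and applied modellers who want to
calibrate

$$\frac{dN}{dt} = r\,N\Big(1 - \frac{N}{K}\Big), \qquad
N(t) = \frac{K}{1 + (K/N_0 - 1)\,e^{-rt}},$$

to a census series (year, count), compare how the four schemes
reproduce a held-out census value, verify the fractional model's
computable existence–uniqueness constant
$\Omega = \tfrac{1-\alpha}{ABC(\alpha)}\Psi +
\tfrac{\alpha b^\alpha}{\Gamma(\alpha)ABC(\alpha)}\Psi$
and Hyers–Ulam constant
$\eta = \tfrac{\Gamma(\alpha)+b^\alpha}{\Gamma(\alpha)ABC(\alpha)}\Psi$
(with Lipschitz constant $\Psi = r + 2rN_0/K$), and forecast forward
across sweeps of the fractional order $\alpha$ and the base growth rate
$r_0$.  It also ships a synthetic decennial-census generator
(logistic or slowly varying truth, annualising interpolation,
multiplicative lognormal noise) so the whole pipeline is testable
without any external data, plus the published Bangladesh / Sri Lanka
reference constants as a versioned fixture
(`reference_constants()`).

## Worked example

Calibrate on a census series generated from the adjusted-census fitted
parameters (six census waves, annualised by monotone interpolation),
compare all four schemes at 2022 against the adjusted census value
170,000,000, and sweep the multiple-scales forecast to 2080:

```r
library(fraclogis)

p <- logistic_params(r = 0.0374286, K = 225062093.9465337, N0 = 76398000)
cen <- generate_census(p, 1974, c(1974, 1981, 1991, 2001, 2011, 2022),
                       annualize = TRUE)
cfg <- analysis_config(census = cen, target_year = 2022,
                       horizon_year = 2080,
                       target_census_value = 170000000)
run_analysis(cfg)
#> Scheme comparison at 2022 (observed 170000000.0000)
#>   logistic_exact         169949530.8038   0.03%
#>   pece                   169949530.8038   0.03%
#>   abc                    153710005.5049   9.58%
#>   multiscale             170074741.5750   0.04%
#>   regression r = 1.0000, R^2 = 1.0000
#> Stability report (alpha = 0.5, b = 10, ABC = 1)
#>   Psi   = 0.063213806633 (Lipschitz)
#>   Omega = 0.08799754176  -> uniqueness OK (< 1)
#>   eta   = 0.17599508352  -> Hyers-Ulam stable (< 1)

run_forecast(cfg)$fps_table
#>           r0       fps fps_million
#> 1 0.01000000 135194466     135.194
#> 2 0.02000000 182523754     182.524
#> 3 0.03000000 207678976     207.679
#> 4 0.03758118 216381760     216.382
```

Reading the comparison table: each row is one propagation scheme
evaluated at the target year, with its percent error against the
observed census value.  The integer-order schemes (closed form and
PECE) agree to every printed digit; the ABC row uses the analysis
default $\alpha = 0.95$, whose heavier memory slows the approach to the
carrying capacity; the multiple-scales row allows the growth rate and
capacity to oscillate slowly about their fitted values.  The stability
block confirms both fractional criteria sit well below 1 at
$\alpha = 1/2$, $b = 10$.  The forecast table shows the 2080 final
population size (FPS) rising strictly with the base growth rate — the
policy-relevant ordering.

When parameters are supplied directly (`params =`), calibration is
skipped and the comparison reproduces the published adjusted-census
table row exactly: logistic 170,145,565.0601 at 2022, percent error
0.09%.

A thin command-line wrapper with subcommands `fit`, `analyze`,
`forecast`, `simulate` and `stability` lives at
`inst/cli/fraclogis.R`:

```sh
Rscript inst/cli/fraclogis.R stability --r 0.0374286 \
    --K 225062093.9465337 --N0 76398000 --alpha 0.5 --b 10
```

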