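# lakebnm

Hierarchical Bayesian network modelling of how climate (air temperature,
precipitation) and agricultural land use affect annual lake fish catches
through three lake-environmental mediators: water temperature, water-level
change and chlorophyll-a. The package is aimed at quantitative ecologists
and fisheries scientists working with long, gappy, multi-lake monitoring
panels, where a network of per-lake conditional regressions — estimated
jointly so that every coefficient borrows strength from all variables —
extracts more from limited data than independent regressions would.

## The model

For lake *i*, four conditional Gaussian regressions form a recursive
network (year-by-year independence; downstream equations consume upstream
*predicted means* μ, never noisy observations):

    WT_i        ~ N(β0 + β1·AT,                                   σ_WT)
    ΔWL_i       ~ N(β0 + β1·PRE + β2·PE + β3·PE·LUag,             σ_ΔWL)
    log CHL_i   ~ N(β0 + β1·log PRE + β2·log LUag + β3·μ_ΔWL + β4·μ_WT, σ_CHL)
    log CATCH_i ~ N(β0 + β1·μ_WT + β2·μ_ΔWL + β3·μ_CHL
                       + β4·log ST + β5·log EFF,                  σ_CATCH)

where the stocking term β4·log ST is present only for stocking-eligible
lakes (stocked species >20% of catch in >10 years). Priors are per-lake
multivariate normals anchored at each lake's least-squares fit with
covariance g·(X'X)⁻¹; the scale g is shared across lakes per equation
with a noninformative hyperprior and is the pooling channel. Estimation
is by a block-conjugate Gibbs sampler with split Gelman–Rubin
diagnostics. Downstream stages classify the 13 variable-pair effects by
one-tailed 75% credible intervals, characterize driver changes associated
with a 25% catch decrease by Monte-Carlo acceptance sampling (catch ratio
in [0.74, 0.76]), and correlate the resulting vulnerability magnitudes
with lake characteristics (access to clean water, shoreline population
density, depth, shoreline development index). A synthetic multi-lake
generator with known ground truth makes every stage testable end to end.

See `vignettes/lakebnm-methods.Rmd` for the full methods account.

## Worked example

```r
library(lakebnm)

scenario <- generate_scenario(n_lakes = 4, n_years = 45, seed = 7)
panel    <- forward_simulate(scenario, seed = 8)
validate_panel(panel)
#> panel OK

priors <- build_priors(panel, stocking = scenario_stocking(scenario))
draws  <- run_mcmc(panel, priors,
                   bnm_config(chains = 3, burnin = 500, retained = 2000,
                              seed = 9))
max_rhat(draws)
#> 1.0025            # split Gelman-Rubin over all coefficients: converged

effects_table(draws)
#>    predictor response positive negative mixed
#> 1         AT       WT        4        0     0
#> 2         AT       WL        0        4     0
#> 3        PRE       WL        4        0     0
#> ...
#> 13       EFF    CATCH        4        0     0
```

Every row counts lakes whose one-tailed 75% credible interval puts the
pair's coefficient strictly above (positive) or below (negative) zero;
air temperature warms water in all four lakes, and effort raises catch
in all four, while other links differ in direction across lakes.

```r
a <- run_driver_assessment(draws, panel, lake = "L02", driver = "AT",
                           n_accepted = 2000, seed = 10)
a
#> driver_assessment L02/AT: 2000 accepted of 8650000 proposals (rate 0.000231)
#>   delta AT: median -3.96 [q25 -4.07, q75 -3.85] -> positive

summary(a)$mediator_important
#>    WT    WL   CHL
#>  TRUE FALSE FALSE

magnitude_of_change(a)
#> 3.956
```

For lake L02 a 25% catch decrease is associated with roughly 4 °C of
*cooling* (a positive AT–catch association under the labeling
convention), carried almost entirely by the water-temperature mediator —
its share of the decrease exceeds the 9.1% equal-share cutoff
(`importance_cutoff(3)`) in at least 75% of accepted samples. The
magnitude, 3.96 °C, is the lake's vulnerability index for this driver
(smaller = more vulnerable); `vulnerability_correlations()` relates
these magnitudes to lake characteristics.

`run_pipeline(pipeline_config(seed = 1))` chains all stages —
simulate → priors → fit → classify → assess → correlate — into one
reproducible run with CSV outputs and a hash manifest.

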