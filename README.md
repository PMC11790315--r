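# didpm25

Difference-in-differences (DiD) estimation of the effect of long-term
PM2.5 exposure on annual all-cause mortality from district-level panel
data, with population-weighted exposure harmonisation, sensitivity
analyses, and attributable-burden calculation under counterfactual
air-quality thresholds.

The package is written for environmental epidemiologists and health-impact
analysts working with administrative mortality registries (district-year
death counts), gridded exposure surfaces, and covariates observed at mixed
spatial and temporal resolutions. It also ships a fully self-contained
synthetic-data generator with known ground truth, so the whole chain can
be validated by parameter recovery.

## The model

District-year death counts are modelled with a quasi-Poisson log-linear
regression with a log-population offset:

```
log E[Y_dt] = log P_dt + b0 + b1 * PM_dt + division indicators
              + ns(year, 3 df) per division + covariates
```

The per-division natural-spline time trends are the interactive fixed
effects of an extended DiD design: confounders that are constant within a
division, or drift smoothly over time within it, are removed by
construction, and `b1` is identified from year-to-year exposure changes
around those trends. Inference is dispersion-scaled (Pearson
`phi = X^2/(n-p)`, covariance `phi * (X'WX)^{-1}`), and the headline
estimate is the percent change in mortality per 10 ug/m3,
`100 * (exp(10*b1) - 1)`. A 4-df spline exposure term replaces the linear
one to trace the exposure–response curve.

Attributable burden under a counterfactual threshold `x0` (Indian NAAQS
40 ug/m3, WHO guideline 5 ug/m3) uses, per district-year,
`dX = max(0, x - x0)`, `AF = 1 - exp(-b1 * dX)`, `M = AF * deaths`.

## Worked example

```r
library(didpm25)

cfg   <- sim_config(seed = 1)       # 6 states / 30 divisions / 150 districts,
                                    # years 2008-2019, true PC 8.6% per 10 ug/m3
inp   <- simulate_panel_inputs(cfg)
panel <- build_panel(inp$grid, inp$covariates, inp$deaths, inp$hierarchy)

fit <- fit_did(panel)
fit
#> <did_fit> linear exposure, 1650 obs, 134 params, phi = 1.279, 5 IRLS iterations
#>   percent change per 10 ug/m3: 8.68% (95% CI 8.53 to 8.83)
```

The estimate recovers the generator's true 8.6% per 10 ug/m3 within its
confidence interval. The sensitivity suite refits the same specification
under completeness calibration, extreme-exposure exclusion, and lagged
exposures:

```r
sensitivity_table(run_sensitivity_suite(panel))
#>                  analysis    n pc_per_10   lo   hi  phi
#> 1                    main 1650      8.68 8.53 8.83 1.28
#> 2 completeness_calibrated 1650      8.66 8.52 8.80 1.98
#> 3       extremes_excluded 1616      8.70 8.54 8.86 1.27
#> 4                    lag1 1650      6.84 6.53 7.15 5.87
#> 5                   lag01 1650      8.73 8.51 8.96 2.53
```

(The lag1 estimate is attenuated by design here: the generator's exposure
effect is contemporaneous, so last year's exposure is a noisy proxy.)

```r
burden_ci(fit, panel, counterfactual_threshold("WHO"))
#> <burden_result> threshold WHO (5.0 ug/m3), 11 years
#>   total attributable deaths: 417421 (411870-422936)
#>   mean per year: 37947 (37443-38449)
#>   attributable fraction: 29.4% (29.0-29.8)
```

So on this synthetic panel, 29.4% of all deaths are attributable to PM2.5
above the WHO guideline; totals are in the synthetic population's scale.
`run_pipeline(default_run_config(...))` executes the same chain end to end
and writes every artifact (tables as CSV, fits and burden as JSON) plus a
manifest with the seed, configuration hash, and headline estimates;
`inst/scripts/run_pipeline.R` wraps it for the shell.

See the vignette (`vignettes/did-pm25-mortality.Rmd`) for the model's
assumptions, the generator's design, and the numerical choices.

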