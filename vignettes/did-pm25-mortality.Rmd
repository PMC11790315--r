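---
title: "Difference-in-differences estimation of long-term PM2.5 effects on mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference-in-differences estimation of long-term PM2.5 effects on mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Long-term exposure to fine particulate matter (PM2.5) and all-cause
mortality are both strongly patterned in space and time, so a naive
regression of district mortality rates on district exposure confounds the
exposure effect with everything else that differs between regions and
drifts over a decade: age structure, socioeconomic change, registration
practices, secular mortality decline. The design implemented here is an
extended difference-in-differences (DiD): rather than comparing high- and
low-exposure districts, it compares *changes* in mortality against
*changes* in exposure, within administrative divisions, around
division-specific smooth time trends. Any confounder that is constant
within a division, or that evolves smoothly over time within a division, is
absorbed by design; identification comes from year-to-year exposure
fluctuations around those trends.

## The model

For district $d$ in division $v(d)$, year $t$, with death count $Y_{dt}$
and population $P_{dt}$, the estimator is a quasi-Poisson log-linear model

$$
\log E[Y_{dt}] \;=\; \log P_{dt} + \beta_0 + \beta_1\, x_{dt}
 + \sum_{v} \mathbf{1}\{v(d)=v\}\,\big(\alpha_v + f_v(t)\big)
 + \gamma' W_{dt},
$$

where

* $x_{dt}$ is the district's population-weighted annual mean PM2.5
  ($\mu g/m^3$), aggregated from grid cells with cell populations as
  weights;
* $f_v$ is a separate natural cubic spline of calendar year, 3 df per
  division — the interactive-fixed-effects component;
* $\alpha_v$ are division indicators (reference-coded, first division
  dropped);
* $W_{dt}$ are 13 district-level covariates: quarterly temperature means
  and SDs (from monthly series; quarters Dec–Feb, Mar–May, Jun–Aug,
  Sep–Nov), GDP per capita, % aged 60+, clean-cooking-fuel %, women's
  literacy %, and (state-level) median age;
* $\log P_{dt}$ is an offset, so coefficients describe rates rather than
  counts.

Variance is modelled as $\phi\,\mu$; $\phi$ is estimated from the Pearson
statistic, $\hat\phi = X^2_P/(n-p)$, the covariance is
$\hat\phi\,(X'WX)^{-1}$, and intervals use normal critical values
(quasi-likelihood asymptotics at thousands of observations). The headline
quantity is the percent change per 10 $\mu g/m^3$,
$100\,(e^{10\hat\beta_1}-1)$.

A nonlinear exposure–response function replaces the linear term with a
4-df natural spline; `erf_curve()` reports the log relative rate against a
reference exposure (default: the observed minimum) on a grid truncated at
the 99th exposure percentile, with delta-method pointwise bounds.

### Fitting and numerical choices

* The fit is iteratively reweighted least squares with the log-population
  offset, run to a relative coefficient change below $10^{-8}$ (the
  denominator is floored at $10^{-2}$ so coefficients that are genuinely
  zero are judged on an absolute $10^{-10}$ scale instead of stalling the
  iteration), capped at 100 iterations with a hard failure otherwise.
* Natural spline bases put boundary knots at the data range and interior
  knots at equally spaced quantiles; the basis is linear beyond the
  boundary knots.
* Calendar year is mapped to $[0,1]$ across the panel before the trend
  spline is built.
* The per-division spline blocks are centred within division. This only
  reparameterises against the division indicators and intercept; the
  exposure coefficient is invariant (tested).
* Covariates are centred and scaled for conditioning; the exposure column
  is never rescaled, so $\beta_1$ stays per $\mu g/m^3$.
* Rank deficiency and non-convergence are hard errors naming the offending
  columns; there is no silent dropping.

## The synthetic-data generator

The package is exercised end-to-end on synthetic panels whose statistical
structure matches what the estimator assumes, with known ground truth:

* a district → division → state hierarchy (default 150/30/6; a
  "paper-scale" preset with 640 districts and 136 divisions exists for
  larger experiments);
* gridded exposure: district log-normal means (division + district
  components; national median 38.9 $\mu g/m^3$, log-sd ≈ 0.37, so the
  pooled 5th–95th percentile spans roughly 20–72 $\mu g/m^3$), a small
  national drift, independent district-year deviations (log-sd 0.12), and
  cell-level noise, clipped to 11.2–119 $\mu g/m^3$; cell populations are
  log-normal with linear drift;
* covariates at their realistic observation frequencies — GDP annually,
  temperatures monthly, age structure at a single census anchor,
  clean-fuel at three anchors, women's literacy at two survey anchors,
  median age at state level at three anchors — leaving non-anchor years
  missing so harmonisation has real work to do;
* deaths drawn from a gamma-Poisson mixture with variance $\phi\mu$
  (default $\phi=2$) around the log-linear rate model, with the
  population-weighted exposure itself in the linear predictor (so the
  generating exposure is exactly the analysis exposure);
* state-level registration completeness in 30–100%; reported deaths are
  true deaths scaled by the completeness fraction and rounded.

One pre-study year is always generated so lagged-exposure analyses need no
special-casing. Division time trends are random *cubic polynomials*
(orthogonal-polynomial coefficients with decaying weights 1, 0.5, 0.25,
standardised to sd `trend_amplitude` = 0.1 on the log-rate scale): a cubic
is deliberately outside the span of the 3-df natural spline, so the fitted
trends must approximate, not reproduce, the truth. District baseline
variation is routed through the observed age-structure covariate; the
`district_baseline_sd` knob adds *unobserved* persistent heterogeneity and
defaults to zero (see Limitations).

The confounder channel (`confounding_strength`, default 0) makes
log-exposure track each division's standardised trend shape and shifts
division baselines with division mean exposure. At strength 0.35 the crude
model (intercept + exposure + offset) overstates the percent change per
10 $\mu g/m^3$ by several standard errors while the full DiD model stays
on target — the canonical crude-versus-adjusted contrast this design
exists to demonstrate. That value was fixed by matching the size of the
crude-vs-adjusted gap reported in comparable national analyses.

What the generator does *not* emulate: geographic coordinates or spatial
adjacency (membership is tabular; "spatial autocorrelation" is a shared
division component), migration, age-specific mortality, exposure
measurement error (the analysis sees the exact exposure that generated the
counts), and reporting artefacts beyond multiplicative completeness.
Passing tests therefore demonstrate correctness of the estimator and
pipeline under the model's own assumptions, not robustness to the many
ways real registry data violate them.

## Sensitivity analyses

`run_sensitivity_suite()` refits the main model under:

1. **Completeness calibration** — reported deaths divided by the state
   completeness fraction, fed to the fit unrounded (quasi-likelihood does
   not need integer counts). The source description of this step says
   deaths were "multiplied by completeness expressed as a percentage";
   multiplying registered counts by a factor ≤ 1 would shrink
   already-incomplete counts, so division — which moves reported counts
   toward the registry-estimated totals — is what is implemented. If
   completeness is one constant everywhere, the calibration multiplies all
   counts by a scalar, which the log link absorbs into the intercept: the
   exposure estimate is unchanged (tested exactly).
2. **Extreme-exposure exclusion** — rows strictly below the pooled 1st or
   strictly above the pooled 99th exposure percentile are dropped
   (linear-interpolation percentiles; rows exactly at a bound are kept).
   Pooled national percentiles were chosen over per-division ones;
   `by_division = TRUE` switches.
3. **Lagged exposure** — the exposure column is swapped to the prior-year
   value (lag1) or the two-year mean (lag0–1), using the pre-study year's
   exposure for the first outcome year.

## Attributable burden

For a counterfactual threshold $x_0$ (Indian NAAQS 40, WHO guideline 5
$\mu g/m^3$), each district-year contributes
$\Delta X = \max(0, x - x_0)$,
$AF = 1 - e^{-\beta_1 \Delta X}$, and $M = AF \cdot N$ attributable deaths.
Choices made where the formula alone is silent:

* $\Delta X$ is clamped at zero — a counterfactual that only lowers
  exposure to the standard cannot produce negative attributable deaths.
* The aggregate attributable fraction divides by **all** deaths in the
  panel, including below-threshold district-years, so it reads as a share
  of total mortality; one denominator definition is used for every
  threshold.
* Interval bounds substitute $\beta_1$'s confidence limits into the
  formula ($AF$ is monotone in $\beta_1$, so endpoint substitution is
  exact); uncertainty in deaths and exposures is not propagated.
* Burden uses reported deaths by default, matching the main analysis;
  `use_calibrated = TRUE` switches to completeness-calibrated counts.

On the generator's expected counts the formula is exact: the counterfactual
rate is $\lambda e^{-\beta\Delta X}$ under the log-linear model, so
formula-based attributable deaths equal the generator's excess over the
clamped counterfactual identically (tested to 5% on realised draws).

## Problem sizes and reproducibility

The default scale — 6 states, 30 divisions, 150 districts, 4 cells per
district, years 2008–2019 — keeps a full simulate–harmonise–fit–burden
cycle around one second, so the test suite's replication experiments (200
seeded panels for parameter recovery, 100 for the confounding contrast)
run in minutes. Every dataset is a pure function of its configuration,
including the seed; `run_pipeline()` writes a manifest (seed, package
version, configuration hash, per-stage row counts, headline estimates)
sufficient to reproduce a run exactly.

The parameter-recovery and confounding experiments generate counts with
completeness scaling turned off, i.e. from the exact quasi-Poisson model
whose Wald intervals are being checked. This is deliberate: scaling counts
by state-varying completeness multiplies the observation-level dispersion
by the state's completeness fraction, so no single $\phi$ is correct and
model-based intervals are mildly anticonservative — a property of
common-dispersion quasi-likelihood inference, not of this implementation.
The completeness channel stays on by default everywhere else and is
exercised by the pipeline and sensitivity paths.

## Limitations

* Inference is model-based quasi-likelihood: no sandwich/cluster
  correction is offered. Persistent *unobserved* district heterogeneity
  (`district_baseline_sd > 0`) induces within-district correlation that
  these standard errors do not capture, and state-varying completeness
  induces state-varying dispersion (previous section). Both are inherent
  to the estimator, which is implemented as specified.
* The design absorbs confounding only at division level and smoother than
  the trend basis; confounders moving differently across districts within
  a division, year by year, must be covered by the covariate block.
* Residuals are assumed independent across space; no spatial correlation
  modelling.
* The burden calculation is ecological and age-blind, and treats the
  fitted log-linear slope as causal over the whole exposure range.
* The December-to-February quarter takes December from the same calendar
  year by default (`december_from = "previous_year"` spans calendar years
  at the cost of the first year).
* Anchored covariates are extrapolated flat outside their anchor range —
  percentages stay bounded, at the cost of ignoring pre-anchor trends.
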