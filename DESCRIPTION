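Package: didpm25
Title: Difference-in-Differences Estimation of Long-Term PM2.5 Effects on
    District-Level Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of long-term fine particulate
    matter (PM2.5) exposure on annual all-cause mortality from district-level
    panel data using an extended difference-in-differences design: a
    quasi-Poisson log-linear model with a log-population offset and separate
    natural-spline time trends per administrative division (interactive fixed
    effects). Includes population-weighted harmonisation of gridded exposure
    to district-year means, anchor-year covariate interpolation, a synthetic
    panel generator with known ground truth for parameter-recovery studies,
    the standard sensitivity analyses (registration-completeness calibration,
    extreme-exposure exclusion, lagged exposure), and attributable-mortality
    calculations under counterfactual air-quality thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
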