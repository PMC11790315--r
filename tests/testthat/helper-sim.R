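# Shared small-scale fixtures, generated in code at load time.

tiny_config <- function(...) {
  defaults <- list(n_states = 2L, n_divisions = 4L, n_districts = 12L,
                   cells_per_district = 3L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

TINY_CFG <- tiny_config()
TINY <- simulate_panel_inputs(TINY_CFG)
TINY_PANEL <- build_panel(TINY$grid, TINY$covariates, TINY$deaths,
                          TINY$hierarchy)

# One full replicate at the default study-scale conditions: returns the
# DiD and crude exposure coefficients and their standard errors. Counts are
# generated from the exact quasi-Poisson model the estimator assumes
# (completeness scaling off): scaling counts by state-varying registration
# completeness makes the observation-level dispersion vary by state, which
# the common-dispersion Wald intervals under study here do not model.
replicate_fit <- function(seed, confounding_strength = 0, crude = FALSE) {
  cfg <- sim_config(seed = seed, confounding_strength = confounding_strength,
                    apply_completeness = FALSE)
  inp <- simulate_panel_inputs(cfg)
  panel <- build_panel(inp$grid, inp$covariates, inp$deaths, inp$hierarchy)
  fit <- fit_did(panel)
  b <- coef_and_se(fit)
  out <- c(beta = b[["estimate"]], se = b[["se"]])
  if (crude) {
    bc <- coef_and_se(fit_crude(panel))
    out <- c(out, beta_crude = bc[["estimate"]], se_crude = bc[["se"]])
  }
  out
}

coef_and_se <- function(fit) {
  col <- fit$exposure_cols[1]
  c(estimate = unname(fit$coefficients[col]), se = unname(fit$se[col]))
}

# A hand-built linear-exposure fit object, for exercising the reporting
# transforms without running a regression.
stub_fit <- function(beta, se = 0, col = "pm25_pw", ci_level = 0.95) {
  structure(list(coefficients = stats::setNames(beta, col),
                 se = stats::setNames(se, col),
                 vcov = matrix(se^2, 1, 1, dimnames = list(col, col)),
                 phi = 1, n_obs = NA_integer_, n_params = NA_integer_,
                 converged = TRUE, iterations = 0L, ci_level = ci_level,
                 exposure_form = "linear", exposure_cols = col),
            class = "did_fit")
}

TRUE_BETA <- log(1.086) / 10
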