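#' Configuration for the synthetic panel generator
#'
#' Collects every tunable of the synthetic data generator into one validated
#' object. The defaults describe a mid-sized national vital-registration
#' setting: a district/division/state hierarchy, gridded annual PM2.5 with
#' spatial and temporal structure, covariates observed only at anchor years,
#' and overdispersed death counts generated from the same log-linear model
#' the estimator assumes. One pre-study year (the first element of
#' \code{years}) is always generated so lagged-exposure analyses need no
#' special-casing; mortality is generated for the remaining (study) years.
#'
#' @param n_states,n_divisions,n_districts hierarchy sizes; must satisfy
#'   \code{n_districts >= n_divisions >= n_states}.
#' @param years inclusive integer range of generated years. The first year is
#'   exposure-only (pre-study); the rest are study years. Must span >= 3 years.
#' @param cells_per_district number of exposure-grid cells per district.
#' @param true_beta true log-rate coefficient per ug/m3 of PM2.5. The default
#'   corresponds to an 8.6\% rate increase per 10 ug/m3,
#'   \code{log(1.086)/10}.
#' @param baseline_rate deaths per person-year at the centring exposure
#'   (\code{exposure_median}); default 0.007 (7 per 1000, a typical national
#'   crude death rate).
#' @param dispersion_phi quasi-Poisson dispersion of the generated counts
#'   (variance = phi * mean); must be >= 1.
#' @param trend_amplitude standard deviation, on the log-rate scale, of each
#'   division's smooth secular mortality trend across the study years.
#' @param confounding_strength strength of the optional confounder channel:
#'   log-exposure deviations gain \code{confounding_strength} times the
#'   division's standardised trend shape, and division baseline log-rates
#'   gain \code{confounding_strength} times the division's standardised mean
#'   log-exposure. 0 disables confounding.
#' @param exposure_median national median district PM2.5 in ug/m3.
#' @param exposure_sd_division,exposure_sd_district log-scale spatial spread
#'   of division / district mean exposure.
#' @param exposure_sd_temporal log-scale sd of independent district-year
#'   exposure deviations.
#' @param exposure_trend national log-exposure drift per year.
#' @param cell_noise_sd within-district cell-level noise, ug/m3.
#' @param exposure_range cells are clipped to this range (ug/m3); the default
#'   spans 11.2-119.0.
#' @param pop_meanlog,pop_sdlog log-normal parameters of per-cell population.
#' @param pop_growth linear per-year relative population drift.
#' @param district_baseline_sd sd of the \emph{unobserved} residual in
#'   district baseline log-rates. District baseline variation is otherwise
#'   carried by the observed age structure, which the estimator adjusts
#'   for; a nonzero residual makes units heterogeneous in a way no
#'   covariate explains (a stress test for the inference, which assumes
#'   independent quasi-Poisson errors). Default 0.
#' @param completeness_range state-level death-registration completeness is
#'   drawn uniformly on this percentage range (default 30-100).
#' @param apply_completeness logical; if \code{TRUE} reported deaths are
#'   true deaths scaled by the state completeness fraction and rounded.
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration including the seed.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso \code{\link{sim_config_paper_scale}} for a preset at the scale of
#'   a full national registry (136 divisions, 640 districts).
#' @export
sim_config <- function(n_states = 6L,
                       n_divisions = 30L,
                       n_districts = 150L,
                       years = 2008:2019,
                       cells_per_district = 4L,
                       true_beta = log(1.086) / 10,
                       baseline_rate = 0.007,
                       dispersion_phi = 2,
                       trend_amplitude = 0.1,
                       confounding_strength = 0,
                       exposure_median = 38.9,
                       exposure_sd_division = 0.20,
                       exposure_sd_district = 0.31,
                       exposure_sd_temporal = 0.12,
                       exposure_trend = 0.005,
                       cell_noise_sd = 3,
                       exposure_range = c(11.2, 119.0),
                       pop_meanlog = log(3e4),
                       pop_sdlog = 0.7,
                       pop_growth = 0.015,
                       district_baseline_sd = 0,
                       completeness_range = c(30, 100),
                       apply_completeness = TRUE,
                       seed = 1L) {
  config <- list(
    n_states = as.integer(n_states),
    n_divisions = as.integer(n_divisions),
    n_districts = as.integer(n_districts),
    years = as.integer(years),
    cells_per_district = as.integer(cells_per_district),
    true_beta = true_beta,
    baseline_rate = baseline_rate,
    dispersion_phi = dispersion_phi,
    trend_amplitude = trend_amplitude,
    confounding_strength = confounding_strength,
    exposure_median = exposure_median,
    exposure_sd_division = exposure_sd_division,
    exposure_sd_district = exposure_sd_district,
    exposure_sd_temporal = exposure_sd_temporal,
    exposure_trend = exposure_trend,
    cell_noise_sd = cell_noise_sd,
    exposure_range = exposure_range,
    pop_meanlog = pop_meanlog,
    pop_sdlog = pop_sdlog,
    pop_growth = pop_growth,
    district_baseline_sd = district_baseline_sd,
    completeness_range = completeness_range,
    apply_completeness = isTRUE(apply_completeness),
    seed = as.integer(seed)
  )
  errors <- validate_sim_config(config)
  if (length(errors)) {
    stop("invalid sim_config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  class(config) <- "sim_config"
  config
}

#' @rdname sim_config
#' @details \code{sim_config_paper_scale} returns a preset at full national
#'   registry scale (36 states, 136 divisions, 640 districts). It is provided
#'   for users who want simulations at realistic administrative granularity;
#'   the package's own tests use the smaller default scale.
#' @param ... overrides passed on to \code{sim_config}.
#' @export
sim_config_paper_scale <- function(...) {
  defaults <- list(n_states = 36L, n_divisions = 136L, n_districts = 640L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Returns a character vector of violations (empty when valid).
validate_sim_config <- function(config) {
  errors <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(config$n_states >= 1L, "n_states must be a positive integer")
  chk(config$n_divisions >= config$n_states,
      "n_divisions must be >= n_states")
  chk(config$n_districts >= config$n_divisions,
      "n_districts must be >= n_divisions")
  chk(config$cells_per_district >= 1L,
      "cells_per_district must be a positive integer")
  chk(length(config$years) >= 3L &&
        all(diff(config$years) == 1L), "years must be >= 3 consecutive years")
  chk(is.finite(config$true_beta), "true_beta must be finite")
  chk(config$baseline_rate > 0, "baseline_rate must be > 0")
  chk(config$dispersion_phi >= 1, "dispersion_phi must be >= 1")
  chk(config$trend_amplitude >= 0, "trend_amplitude must be >= 0")
  chk(config$confounding_strength >= 0,
      "confounding_strength must be >= 0")
  chk(config$exposure_median > 0, "exposure_median must be > 0")
  chk(config$cell_noise_sd >= 0, "cell_noise_sd must be >= 0")
  chk(length(config$exposure_range) == 2L &&
        config$exposure_range[1] >= 0 &&
        diff(config$exposure_range) > 0,
      "exposure_range must be an increasing nonnegative pair")
  chk(length(config$completeness_range) == 2L &&
        config$completeness_range[1] > 0 &&
        config$completeness_range[2] <= 100 &&
        diff(config$completeness_range) >= 0,
      "completeness_range must lie in (0, 100]")
  chk(config$district_baseline_sd >= 0,
      "district_baseline_sd must be >= 0")
  errors
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d states / %d divisions / %d districts, years %d-%d\n",
    x$n_states, x$n_divisions, x$n_districts, min(x$years), max(x$years)))
  cat(sprintf(
    "  true PC per 10 ug/m3: %.2f%%, phi = %.2f, confounding = %.2f, seed = %d\n",
    100 * (exp(10 * x$true_beta) - 1), x$dispersion_phi,
    x$confounding_strength, x$seed))
  invisible(x)
}

# Study years: all generated years except the pre-study (first) one.
study_years <- function(config) config$years[-1L]
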