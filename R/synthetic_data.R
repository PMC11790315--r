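#' Generate a district/division/state hierarchy
#'
#' Districts are assigned to divisions, and divisions to states, round-robin,
#' so counts are as balanced as possible. Membership is purely tabular; no
#' geographic coordinates are involved.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A data.frame with one row per district and columns
#'   \code{district_id}, \code{division_id}, \code{state_id}.
#' @export
generate_hierarchy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  state_ids <- sprintf("S%02d", seq_len(config$n_states))
  division_ids <- sprintf("V%03d", seq_len(config$n_divisions))
  district_ids <- sprintf("D%04d", seq_len(config$n_districts))
  div_state <- state_ids[((seq_len(config$n_divisions) - 1L) %%
                            config$n_states) + 1L]
  dist_div <- division_ids[((seq_len(config$n_districts) - 1L) %%
                              config$n_divisions) + 1L]
  data.frame(
    district_id = district_ids,
    division_id = dist_div,
    state_id = div_state[match(dist_div, division_ids)],
    stringsAsFactors = FALSE
  )
}

#' Draw the generator's ground truth
#'
#' Samples everything the mortality generator conditions on and that
#' parameter-recovery tests need to score against: district baseline
#' log-rates, division-specific smooth time trends, the spatial components
#' of log-exposure, state completeness, and the (fixed) covariate effects.
#'
#' Division trends are random cubic polynomials: coefficients on the
#' orthonormal polynomial basis of degree 1-3 with decaying weights
#' (1, 0.5, 0.25), then standardised to unit variance across years and scaled
#' by \code{trend_amplitude}. A cubic is deliberately outside the span of the
#' estimator's default 3-df natural spline, so the fitted trends must
#' approximate rather than reproduce the truth.
#'
#' District baseline log-rates combine an observed component (a fixed
#' log-linear effect of the district's percentage aged 60+, which the
#' estimator's covariate block can absorb) with an optional unobserved
#' residual of sd \code{district_baseline_sd}; the \code{-sd^2/2}
#' correction keeps the expected rate across districts at
#' \code{baseline_rate}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param hierarchy output of \code{\link{generate_hierarchy}}.
#' @return An object of class \code{sim_truth}: a list with elements
#'   \code{true_beta}, \code{dispersion_phi}, \code{seed},
#'   \code{baseline_log_rate} (named per district), \code{trend_coefs}
#'   (divisions x 3), \code{trend_matrix} (divisions x years, log-rate
#'   units), \code{trend_shape} (standardised, unit variance),
#'   \code{exposure_division}, \code{exposure_district} (log-scale spatial
#'   components), \code{completeness} (named per state, \%), and
#'   \code{gamma_temp} (log-rate per degree C for the four quarterly mean
#'   temperatures).
#' @export
generate_sim_truth <- function(config, hierarchy) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  divisions <- sort(unique(hierarchy$division_id))
  states <- sort(unique(hierarchy$state_id))
  n_div <- length(divisions)
  years <- config$years

  # Smooth division trends on a 0-1 time axis spanning all generated years;
  # standardisation uses the study years (the ones mortality is generated for).
  t01 <- (years - min(years)) / diff(range(years))
  pb <- stats::poly(t01, degree = 3)
  weights <- c(1, 0.5, 0.25)
  coefs <- matrix(stats::rnorm(n_div * 3), n_div, 3) * rep(weights, each = n_div)
  shape <- coefs %*% t(pb)                       # divisions x years
  study_idx <- seq_along(years)[-1L]
  sds <- apply(shape[, study_idx, drop = FALSE], 1, stats::sd)
  sds[sds == 0] <- 1
  shape <- shape / sds
  shape <- shape - rowMeans(shape[, study_idx, drop = FALSE])
  dimnames(shape) <- list(divisions, years)

  # District baseline log-rates: variation is routed through the observed
  # age structure (so the estimator's covariate block can absorb it) plus an
  # optional unobserved residual. Persistent unobserved unit heterogeneity
  # induces serial correlation that quasi-likelihood inference ignores,
  # which is why the residual defaults to zero; the knob exists for stress
  # tests. The -sd^2/2 correction keeps the expected rate at baseline_rate.
  pct_age60 <- stats::runif(config$n_districts, 4, 9)
  gamma_age <- 0.015
  baseline <- log(config$baseline_rate) + gamma_age * (pct_age60 - 6.5) +
    stats::rnorm(config$n_districts,
                 mean = -config$district_baseline_sd^2 / 2,
                 sd = config$district_baseline_sd)
  names(baseline) <- hierarchy$district_id
  names(pct_age60) <- hierarchy$district_id

  u_div <- stats::rnorm(n_div, 0, config$exposure_sd_division)
  names(u_div) <- divisions
  u_dist <- stats::rnorm(config$n_districts, 0, config$exposure_sd_district)
  names(u_dist) <- hierarchy$district_id

  # Cross-sectional confounder channel: divisions with higher mean exposure
  # get systematically shifted baseline rates.
  z_div <- if (config$exposure_sd_division > 0) {
    u_div / config$exposure_sd_division
  } else {
    u_div * 0
  }
  if (config$confounding_strength > 0) {
    shift <- config$confounding_strength * config$trend_amplitude * z_div
    baseline <- baseline + shift[hierarchy$division_id]
  }

  completeness <- stats::runif(length(states),
                               config$completeness_range[1],
                               config$completeness_range[2])
  names(completeness) <- states

  truth <- list(
    true_beta = config$true_beta,
    dispersion_phi = config$dispersion_phi,
    seed = config$seed,
    baseline_log_rate = baseline,
    pct_age60 = pct_age60,
    gamma_age = gamma_age,
    trend_coefs = coefs,
    trend_matrix = config$trend_amplitude * shape,
    trend_shape = shape,
    exposure_division = u_div,
    exposure_district = u_dist,
    completeness = completeness,
    gamma_temp = c(temp_q1 = 0.004, temp_q2 = -0.003,
                   temp_q3 = 0.003, temp_q4 = 0.002),
    exposure_center = config$exposure_median
  )
  class(truth) <- "sim_truth"
  truth
}

#' Simulate the gridded annual exposure surface
#'
#' Each district receives a log-normal mean exposure built from a division
#' component (spatial autocorrelation across districts of one division), a
#' district component, a national annual drift, and independent district-year
#' deviations; when the confounder channel is on, district-year log-exposure
#' additionally follows the division's standardised mortality-trend shape.
#' Cells scatter around the district-year mean with Gaussian noise and are
#' clipped to \code{config$exposure_range}. Cell populations are log-normal,
#' constant over time apart from a linear drift.
#'
#' @param config a \code{\link{sim_config}}.
#' @param hierarchy output of \code{\link{generate_hierarchy}}.
#' @param truth output of \code{\link{generate_sim_truth}}; required whenever
#'   \code{confounding_strength > 0} and recommended always (it carries the
#'   spatial exposure components).
#' @return A data.frame of grid cell-years: \code{cell_id},
#'   \code{district_id}, \code{year}, \code{pm25_ugm3}, \code{population}.
#' @export
simulate_exposure_grid <- function(config, hierarchy, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    if (config$confounding_strength > 0) {
      stop("truth is required when confounding_strength > 0", call. = FALSE)
    }
    truth <- generate_sim_truth(config, hierarchy)
  }
  set.seed(config$seed + 1L)
  years <- config$years
  n_years <- length(years)
  n_dist <- config$n_districts
  n_cells <- config$cells_per_district

  log_mu_d <- log(config$exposure_median) +
    truth$exposure_division[hierarchy$division_id] +
    truth$exposure_district[hierarchy$district_id]

  # district-year log deviations
  dev <- matrix(stats::rnorm(n_dist * n_years, 0, config$exposure_sd_temporal),
                n_dist, n_years)
  drift <- config$exposure_trend * (years - min(years))
  log_mean <- outer(log_mu_d, drift, `+`) + dev
  if (config$confounding_strength > 0) {
    log_mean <- log_mean + config$confounding_strength *
      truth$trend_shape[hierarchy$division_id, as.character(years)]
  }
  district_year_mean <- exp(log_mean)              # districts x years, ug/m3

  base_pop <- stats::rlnorm(n_dist * n_cells, config$pop_meanlog,
                            config$pop_sdlog)

  cell_idx <- rep(seq_len(n_cells), times = n_dist)
  dist_idx <- rep(seq_len(n_dist), each = n_cells)
  grid <- data.frame(
    cell_id = rep(sprintf("%s_c%02d", hierarchy$district_id[dist_idx],
                          cell_idx), times = n_years),
    district_id = rep(hierarchy$district_id[dist_idx], times = n_years),
    year = rep(years, each = n_dist * n_cells),
    stringsAsFactors = FALSE
  )
  year_pos <- match(grid$year, years)
  mean_for_cell <- district_year_mean[cbind(rep(dist_idx, times = n_years),
                                            year_pos)]
  noise <- if (config$cell_noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, config$cell_noise_sd)
  } else {
    0
  }
  grid$pm25_ugm3 <- pmin(pmax(mean_for_cell + noise,
                              config$exposure_range[1]),
                         config$exposure_range[2])
  grid$population <- rep(base_pop, times = n_years) *
    (1 + config$pop_growth * (grid$year - min(years)))
  grid
}

#' Simulate covariates with anchor-year gaps
#'
#' Emits the covariates the analysis adjusts for, at the spatio-temporal
#' resolution they are realistically observed at, leaving non-anchor years
#' missing so the harmonisation step has real work to do:
#' \itemize{
#'   \item \code{gdp_pc}: district, annual (2017 USD per capita);
#'   \item \code{temp_monthly}: district, 12 monthly mean temperatures per
#'     year (degrees C), from which quarterly means/SDs are later computed;
#'   \item \code{pct_age60}: district, a single census anchor year;
#'   \item \code{clean_fuel}: district, three anchors (census + two
#'     household-survey waves);
#'   \item \code{women_lit}: district, two household-survey anchors;
#'   \item \code{median_age}: state, three anchors (identical for all
#'     districts of a state by construction);
#'   \item \code{completeness}: state, annual, drawn within
#'     \code{completeness_range}.
#' }
#' Anchored series carry explicit \code{NA} rows for the in-between study
#' years.
#'
#' @param config a \code{\link{sim_config}}.
#' @param hierarchy output of \code{\link{generate_hierarchy}}.
#' @param truth optional \code{\link{generate_sim_truth}} output; when given,
#'   state completeness is taken from it (keeping the whole dataset a pure
#'   function of config + seed when generated through
#'   \code{\link{simulate_panel_inputs}}).
#' @return A long data.frame: \code{level} ("district" or "state"),
#'   \code{unit_id}, \code{variable}, \code{year}, \code{month} (NA except
#'   for \code{temp_monthly}), \code{value}.
#' @export
simulate_covariates <- function(config, hierarchy, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sy <- study_years(config)
  districts <- hierarchy$district_id
  states <- sort(unique(hierarchy$state_id))
  n_d <- length(districts)

  long <- function(level, unit, variable, year, month, value) {
    data.frame(level = level, unit_id = unit, variable = variable,
               year = year, month = month, value = value,
               stringsAsFactors = FALSE)
  }

  # District GDP per capita: log-normal base, national growth, annual noise.
  gdp_base <- stats::rlnorm(n_d, log(4000), 0.4)
  gdp <- long("district", rep(districts, times = length(sy)), "gdp_pc",
              rep(sy, each = n_d), NA_integer_,
              rep(gdp_base, times = length(sy)) *
                exp(0.02 * rep(sy - min(sy), each = n_d) +
                      stats::rnorm(n_d * length(sy), 0, 0.05)))

  # Monthly temperatures: a tropical seasonal cycle plus district offset and
  # month-level weather noise.
  season <- c(18, 20, 24, 28, 30, 30, 29, 28.5, 27.5, 26, 22, 19)
  dist_offset <- stats::rnorm(n_d, 0, 2)
  tm <- expand.grid(unit_id = districts, year = sy, month = 1:12,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tm_value <- season[tm$month] + dist_offset[match(tm$unit_id, districts)] +
    stats::rnorm(nrow(tm), 0, 1)
  temp <- long("district", tm$unit_id, "temp_monthly", tm$year,
               as.integer(tm$month), tm_value)

  # Anchored district covariates: explicit NA rows off-anchor.
  anchored_series <- function(variable, anchors, values_by_anchor) {
    out <- long("district", rep(districts, times = length(sy)), variable,
                rep(sy, each = n_d), NA_integer_, NA_real_)
    for (i in seq_along(anchors)) {
      out$value[out$year == anchors[i]] <- values_by_anchor[, i]
    }
    out
  }
  age60 <- if (!is.null(truth)) {
    truth$pct_age60[districts]
  } else {
    stats::runif(n_d, 4, 9)
  }
  pct_age60 <- anchored_series("pct_age60", 2011L, cbind(age60))

  fuel0 <- stats::runif(n_d, 15, 70)
  fuel <- cbind(fuel0, pmin(fuel0 + stats::runif(n_d, 2, 12), 100),
                pmin(fuel0 + stats::runif(n_d, 8, 25), 100))
  clean_fuel <- anchored_series("clean_fuel", c(2011L, 2015L, 2019L), fuel)

  lit0 <- stats::runif(n_d, 45, 90)
  lit <- cbind(lit0, pmin(lit0 + stats::runif(n_d, 1, 8), 100))
  women_lit <- anchored_series("women_lit", c(2015L, 2019L), lit)

  # State-level: median age at three anchors (2021 lies beyond the study
  # range and is served by flat extrapolation), completeness annually.
  age_anchors <- c(2011L, 2016L, 2021L)
  age_base <- stats::runif(length(states), 22, 30)
  med_age <- long("state",
                  rep(states, times = length(age_anchors)), "median_age",
                  rep(age_anchors, each = length(states)), NA_integer_,
                  c(age_base, age_base + stats::runif(length(states), 0.5, 1.5),
                    age_base + stats::runif(length(states), 1.5, 3)))

  comp <- if (!is.null(truth)) {
    truth$completeness[states]
  } else {
    stats::runif(length(states), config$completeness_range[1],
                 config$completeness_range[2])
  }
  completeness <- long("state", rep(states, times = length(sy)),
                       "completeness", rep(sy, each = length(states)),
                       NA_integer_, rep(comp, times = length(sy)))

  rbind(gdp, temp, pct_age60, clean_fuel, women_lit, med_age, completeness)
}

#' Simulate district-year death counts
#'
#' Draws death counts from the log-linear rate model the estimator assumes:
#' \deqn{\lambda_{dt} = P_{dt} \exp\{b_d + f_{v(d)}(t) +
#'   \beta_1 (PM_{dt} - c) + \gamma' W_{dt}\}}
#' with \eqn{b_d} the district baseline log-rate, \eqn{f_v} the division's
#' smooth trend, \eqn{c} the centring exposure, and \eqn{W} the (centred)
#' quarterly mean temperatures. Counts are drawn from a gamma-Poisson
#' mixture with variance \code{phi * mean} (a negative binomial with
#' \code{size = mean/(phi-1)}), which matches the first two quasi-Poisson
#' moments; at \code{phi = 1} draws are exactly Poisson. When completeness
#' is applied, reported deaths are true deaths scaled by the state
#' completeness fraction and rounded.
#'
#' @param config a \code{\link{sim_config}}.
#' @param district_exposures data.frame with \code{district_id}, \code{year},
#'   \code{pm25_pw} (the harmonised population-weighted district mean) and
#'   \code{population}, covering every study district-year.
#' @param covariates long covariate table from
#'   \code{\link{simulate_covariates}} (used for the temperature effect).
#' @param truth output of \code{\link{generate_sim_truth}}.
#' @param hierarchy output of \code{\link{generate_hierarchy}}.
#' @return data.frame: \code{district_id}, \code{year}, \code{deaths_true},
#'   \code{deaths_reported}.
#' @export
simulate_mortality <- function(config, district_exposures, covariates,
                               truth, hierarchy) {
  ed <- expected_deaths(config, district_exposures, covariates, truth,
                        hierarchy)
  de <- ed$rows
  lambda <- ed$lambda
  set.seed(config$seed + 3L)
  phi <- config$dispersion_phi
  deaths_true <- if (phi <= 1) {
    stats::rpois(length(lambda), lambda)
  } else {
    stats::rnbinom(length(lambda), mu = lambda, size = lambda / (phi - 1))
  }
  state <- hierarchy$state_id[match(de$district_id, hierarchy$district_id)]
  deaths_reported <- if (config$apply_completeness) {
    round(deaths_true * truth$completeness[state] / 100)
  } else {
    deaths_true
  }
  data.frame(district_id = de$district_id, year = de$year,
             deaths_true = deaths_true, deaths_reported = deaths_reported,
             stringsAsFactors = FALSE)
}

#' Expected deaths under the generator's rate model
#'
#' Deterministic counterpart of \code{\link{simulate_mortality}}: the mean
#' death count \eqn{\lambda_{dt}} for every study district-year, given the
#' exposure series, covariates, and ground truth. Useful for
#' parameter-recovery diagnostics and for computing the generator-based
#' excess deaths under a counterfactual exposure (pass a clamped
#' \code{pm25_pw} column).
#'
#' @inheritParams simulate_mortality
#' @return list with \code{rows} (the study-year exposure rows, ordered as
#'   used) and \code{lambda} (expected deaths per row).
#' @export
expected_deaths <- function(config, district_exposures, covariates,
                            truth, hierarchy) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  sy <- study_years(config)
  de <- district_exposures[district_exposures$year %in% sy, , drop = FALSE]
  need <- c("district_id", "year", "pm25_pw", "population")
  if (!all(need %in% names(de))) {
    stop("district_exposures must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  expected <- config$n_districts * length(sy)
  if (nrow(de) != expected) {
    stop(sprintf(
      "district_exposures must cover all %d study district-years (got %d)",
      expected, nrow(de)), call. = FALSE)
  }

  # Quarterly mean temperatures, centred across the panel, carry the
  # covariate effect; other covariates have no true effect.
  tm <- covariates[covariates$variable == "temp_monthly", , drop = FALSE]
  qt <- quarterly_temperature_stats(
    data.frame(district_id = tm$unit_id, year = tm$year, month = tm$month,
               temp = tm$value, stringsAsFactors = FALSE))
  qcols <- paste0("temp_q", 1:4)
  qt_c <- scale(as.matrix(qt[qcols]), center = TRUE, scale = FALSE)
  w_effect <- drop(qt_c %*% truth$gamma_temp[qcols])
  names(w_effect) <- paste(qt$district_id, qt$year)

  if (any(!is.finite(de$pm25_pw)) || any(!is.finite(w_effect))) {
    stop("non-finite exposure or covariate values", call. = FALSE)
  }

  log_rate <- truth$baseline_log_rate[de$district_id] +
    truth$trend_matrix[cbind(hierarchy$division_id[
      match(de$district_id, hierarchy$district_id)],
      as.character(de$year))] +
    config$true_beta * (de$pm25_pw - truth$exposure_center) +
    w_effect[paste(de$district_id, de$year)]
  lambda <- de$population * exp(log_rate)
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("non-finite or negative rates in mortality generator", call. = FALSE)
  }
  list(rows = de, lambda = unname(lambda))
}

#' Generate a complete set of synthetic inputs
#'
#' Runs the full generator: hierarchy, ground truth, exposure grid,
#' covariates, and mortality (using the population-weighted district
#' exposure, so the generating exposure is exactly the one the analysis
#' sees). The result is a pure function of the configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{hierarchy}, \code{truth}, \code{grid},
#'   \code{covariates}, \code{deaths}, and \code{config}.
#' @export
simulate_panel_inputs <- function(config = sim_config()) {
  hierarchy <- generate_hierarchy(config)
  truth <- generate_sim_truth(config, hierarchy)
  grid <- simulate_exposure_grid(config, hierarchy, truth)
  covariates <- simulate_covariates(config, hierarchy, truth)
  pm <- popweighted_district_means(grid)
  pop <- stats::aggregate(population ~ district_id + year, data = grid,
                          FUN = sum)
  de <- merge(pm, pop, by = c("district_id", "year"))
  deaths <- simulate_mortality(config, de, covariates, truth, hierarchy)
  list(hierarchy = hierarchy, truth = truth, grid = grid,
       covariates = covariates, deaths = deaths, config = config)
}

#' Write synthetic inputs to plain-text files
#'
#' Writes the grid, covariate and deaths tables as CSV and the ground truth
#' as JSON into \code{dir}.
#'
#' @param inputs output of \code{\link{simulate_panel_inputs}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_sim_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(grid = file.path(dir, "grid.csv"),
             covariates = file.path(dir, "covariates.csv"),
             deaths = file.path(dir, "deaths.csv"),
             hierarchy = file.path(dir, "hierarchy.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(inputs$grid, paths["grid"], row.names = FALSE)
  utils::write.csv(inputs$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(inputs$deaths, paths["deaths"], row.names = FALSE)
  utils::write.csv(inputs$hierarchy, paths["hierarchy"], row.names = FALSE)
  truth <- unclass(inputs$truth)
  truth$trend_matrix <- NULL   # reproducible from coefs; keep the JSON small
  truth$trend_shape <- NULL
  truth$trend_coefs <- unclass(truth$trend_coefs)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
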