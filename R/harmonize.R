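#' Population-weighted district mean exposure
#'
#' Aggregates grid-cell exposure to one value per district-year, weighting
#' each cell by its population:
#' \deqn{pm25\_pw = \sum_c pop_c \, pm25_c / \sum_c pop_c.}
#'
#' @param grid data.frame of cell-years with columns \code{district_id},
#'   \code{year}, \code{pm25_ugm3}, \code{population}.
#' @param allow_unweighted if \code{TRUE}, a district-year whose total
#'   population is zero falls back to the unweighted cell mean instead of
#'   erroring. Off by default: silent fallback would hide degenerate inputs.
#' @return data.frame \code{district_id}, \code{year}, \code{pm25_pw},
#'   sorted by district and year.
#' @export
popweighted_district_means <- function(grid, allow_unweighted = FALSE) {
  need <- c("district_id", "year", "pm25_ugm3", "population")
  missing_cols <- setdiff(need, names(grid))
  if (length(missing_cols)) {
    stop("grid is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(grid$pm25_ugm3 < 0) || any(grid$population < 0)) {
    stop("exposure and population must be nonnegative", call. = FALSE)
  }
  key <- paste(grid$district_id, grid$year, sep = "\r")
  wsum <- rowsum(grid$population, key)
  wx <- rowsum(grid$population * grid$pm25_ugm3, key)
  zero <- wsum[, 1] == 0
  if (any(zero) && !allow_unweighted) {
    bad <- sub("\r", " year ", rownames(wsum)[zero])
    stop("district-years with zero total population (no weights): ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (sum(zero) > 5) " ..." else "",
         "; pass allow_unweighted = TRUE for an unweighted fallback",
         call. = FALSE)
  }
  pm <- wx[, 1] / wsum[, 1]
  if (any(zero)) {
    plain <- rowsum(grid$pm25_ugm3, key)[, 1] / rowsum(rep(1, nrow(grid)), key)[, 1]
    pm[zero] <- plain[zero]
  }
  parts <- strsplit(rownames(wsum), "\r", fixed = TRUE)
  out <- data.frame(
    district_id = vapply(parts, `[`, "", 1L),
    year = as.integer(vapply(parts, `[`, "", 2L)),
    pm25_pw = unname(pm),
    stringsAsFactors = FALSE
  )
  out[order(out$district_id, out$year), , drop = FALSE]
}

#' Linear interpolation between anchor years
#'
#' Covariates observed only at census/survey anchor years are completed to
#' an annual series: linear interpolation strictly between anchors, flat
#' (nearest-anchor) extrapolation outside the anchor range, and constant
#' series when only one anchor exists. Flat extrapolation avoids negative or
#' explosive extrapolated percentages at the panel edges.
#'
#' @param series data.frame with columns \code{unit_id}, \code{year},
#'   \code{value}; \code{NA} values mark non-anchor years.
#' @param target_years integer years the output must cover.
#' @param variable name used in error messages.
#' @return data.frame \code{unit_id}, \code{year}, \code{value} with one row
#'   per unit and target year, no missing values.
#' @export
interpolate_anchor_years <- function(series, target_years,
                                     variable = "covariate") {
  stopifnot(all(c("unit_id", "year", "value") %in% names(series)))
  units <- unique(series$unit_id)
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    s <- series[series$unit_id == u & !is.na(series$value), , drop = FALSE]
    if (nrow(s) == 0L) {
      stop(sprintf("no anchor values for %s in unit %s", variable, u),
           call. = FALSE)
    }
    value <- if (nrow(s) == 1L) {
      rep(s$value, length(target_years))
    } else {
      stats::approx(s$year, s$value, xout = target_years, rule = 2)$y
    }
    out[[i]] <- data.frame(unit_id = u, year = as.integer(target_years),
                           value = value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Broadcast a state-level series to districts
#'
#' Every district inherits its state's series verbatim (the working
#' assumption for covariates observed only at state level, such as median
#' age and registration completeness).
#'
#' @param state_series data.frame with \code{unit_id} (state ids),
#'   \code{year}, \code{value}.
#' @param hierarchy district-division-state lookup
#'   (\code{\link{generate_hierarchy}} format).
#' @return data.frame \code{unit_id} (district ids), \code{year},
#'   \code{value}.
#' @export
broadcast_state_to_district <- function(state_series, hierarchy) {
  missing_states <- setdiff(hierarchy$state_id, state_series$unit_id)
  if (length(missing_states)) {
    stop("no state-level series for state(s): ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  years <- unique(state_series$year)
  out <- merge(
    data.frame(district_id = rep(hierarchy$district_id, each = length(years)),
               state_id = rep(hierarchy$state_id, each = length(years)),
               year = rep(as.integer(years), times = nrow(hierarchy)),
               stringsAsFactors = FALSE),
    state_series,
    by.x = c("state_id", "year"), by.y = c("unit_id", "year"),
    all.x = TRUE
  )
  data.frame(unit_id = out$district_id, year = out$year, value = out$value,
             stringsAsFactors = FALSE)
}

#' Quarterly temperature means and SDs
#'
#' Collapses 12 monthly district temperatures per year into the 8 covariate
#' columns the model adjusts for: for each seasonal quarter, the mean and
#' the sample standard deviation (n-1 denominator) of its 3 monthly values.
#' Quarters follow the season blocks December-February (q1), March-May (q2),
#' June-August (q3), September-November (q4). By default December is taken
#' from the same calendar year; set \code{december_from = "previous_year"}
#' to span calendar years (the first year then has no December and is
#' reported as incomplete).
#'
#' @param monthly data.frame with \code{district_id}, \code{year},
#'   \code{month} (1-12), \code{temp}.
#' @param december_from \code{"same_year"} (default) or
#'   \code{"previous_year"}.
#' @return data.frame with \code{district_id}, \code{year}, \code{temp_q1}
#'   ... \code{temp_q4}, \code{temp_sd_q1} ... \code{temp_sd_q4}.
#' @export
quarterly_temperature_stats <- function(monthly,
                                        december_from = c("same_year",
                                                          "previous_year")) {
  december_from <- match.arg(december_from)
  stopifnot(all(c("district_id", "year", "month", "temp") %in% names(monthly)))
  m <- monthly
  if (december_from == "previous_year") {
    dec <- m$month == 12L
    m$year[dec] <- m$year[dec] + 1L
    # the earliest year loses its December to an unavailable prior year and
    # is dropped as incomplete; the final December has no following year
    m <- m[m$year > min(monthly$year) & m$year <= max(monthly$year), ,
           drop = FALSE]
  }
  quarter <- integer(nrow(m))
  quarter[m$month %in% c(12L, 1L, 2L)] <- 1L
  quarter[m$month %in% 3:5] <- 2L
  quarter[m$month %in% 6:8] <- 3L
  quarter[m$month %in% 9:11] <- 4L
  if (any(quarter == 0L)) stop("month values must be in 1-12", call. = FALSE)

  cnt <- stats::aggregate(temp ~ district_id + year, data = m, FUN = length)
  bad <- cnt$temp != 12L
  if (any(bad)) {
    stop("district-years without exactly 12 monthly values: ",
         paste(utils::head(paste(cnt$district_id[bad], cnt$year[bad]), 5),
               collapse = "; "),
         if (sum(bad) > 5) " ..." else "", call. = FALSE)
  }

  key <- paste(m$district_id, m$year, sep = "\r")
  out <- NULL
  for (q in 1:4) {
    mq <- m[quarter == q, , drop = FALSE]
    kq <- paste(mq$district_id, mq$year, sep = "\r")
    mu <- tapply(mq$temp, kq, mean)
    sdq <- tapply(mq$temp, kq, stats::sd)
    df <- data.frame(key = names(mu), mu = as.numeric(mu),
                     sd = as.numeric(sdq), stringsAsFactors = FALSE)
    names(df)[2:3] <- c(paste0("temp_q", q), paste0("temp_sd_q", q))
    out <- if (is.null(out)) df else merge(out, df, by = "key")
  }
  parts <- strsplit(out$key, "\r", fixed = TRUE)
  res <- data.frame(district_id = vapply(parts, `[`, "", 1L),
                    year = as.integer(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  res <- cbind(res, out[, c(paste0("temp_q", 1:4), paste0("temp_sd_q", 1:4))])
  res[order(res$district_id, res$year), , drop = FALSE]
}

#' Attach lagged exposure columns
#'
#' Adds previous-year exposure (\code{pm25_lag1}) and the two-year mean
#' (\code{pm25_lag01}) to a district-year exposure table. The exposure
#' series must include the year before each target year; the generator's
#' pre-study year exists exactly for this purpose.
#'
#' @param pm data.frame \code{district_id}, \code{year}, \code{pm25_pw}
#'   covering target years and their predecessors.
#' @param target_years years that must receive lags (default: all years in
#'   \code{pm} except the earliest, which has no predecessor).
#' @return data.frame restricted to \code{target_years} with added columns
#'   \code{pm25_lag1} and \code{pm25_lag01}.
#' @export
attach_lags <- function(pm, target_years = NULL) {
  stopifnot(all(c("district_id", "year", "pm25_pw") %in% names(pm)))
  if (is.null(target_years)) target_years <- setdiff(pm$year, min(pm$year))
  cur <- pm[pm$year %in% target_years, , drop = FALSE]
  prev_key <- paste(pm$district_id, pm$year, sep = "\r")
  lag1 <- pm$pm25_pw[match(paste(cur$district_id, cur$year - 1L, sep = "\r"),
                           prev_key)]
  if (anyNA(lag1)) {
    bad <- paste(cur$district_id[is.na(lag1)], cur$year[is.na(lag1)])
    stop("missing prior-year exposure for: ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  cur$pm25_lag1 <- lag1
  cur$pm25_lag01 <- (cur$pm25_pw + lag1) / 2
  cur
}

#' Names of the harmonised covariate columns
#'
#' The 13 adjustment covariates of the panel schema, in order: quarterly
#' temperature means and SDs (degrees C), GDP per capita (2017 USD),
#' percentage aged 60+, clean-cooking-fuel percentage, women's literacy
#' percentage, and median age (years). Percentages are on the 0-100 scale.
#'
#' @return character vector of column names.
#' @export
panel_covariate_names <- function() {
  c(paste0("temp_q", 1:4), paste0("temp_sd_q", 1:4),
    "gdp_pc", "pct_age60", "clean_fuel", "women_lit", "median_age")
}

#' Build the balanced district-year analysis panel
#'
#' Converts gridded exposure, the long covariate table, and the deaths table
#' into the balanced panel the estimator consumes: one row per district and
#' study year with population-weighted exposure (plus lags), the 13
#' harmonised covariates, population, deaths, and state completeness.
#' Anchored covariates are linearly interpolated between anchors with flat
#' extrapolation outside; state-level series are broadcast to districts.
#' Percentages stay on the 0-100 scale throughout.
#'
#' @param grid cell-year exposure table (see
#'   \code{\link{simulate_exposure_grid}} for the schema).
#' @param covariates long covariate table (see
#'   \code{\link{simulate_covariates}}).
#' @param deaths data.frame \code{district_id}, \code{year}, and
#'   \code{deaths_reported} (a \code{deaths_true} column, if present, is
#'   carried through).
#' @param hierarchy district-division-state lookup.
#' @param years_out study years for the panel; default: every deaths year.
#' @param december_from December convention for quarterly temperatures, see
#'   \code{\link{quarterly_temperature_stats}}.
#' @return A validated balanced panel data.frame (schema columns:
#'   \code{district_id}, \code{division_id}, \code{state_id}, \code{year},
#'   \code{deaths}, \code{population}, \code{pm25_pw}, \code{pm25_lag1},
#'   \code{pm25_lag01}, the covariates of \code{panel_covariate_names()},
#'   \code{completeness}).
#' @export
build_panel <- function(grid, covariates, deaths, hierarchy,
                        years_out = NULL, december_from = "same_year") {
  years_out <- as.integer(years_out %||% sort(unique(deaths$year)))

  pm <- popweighted_district_means(grid)
  pm <- attach_lags(pm, target_years = years_out)

  pop <- stats::aggregate(population ~ district_id + year, data = grid,
                          FUN = sum)

  panel <- merge(pm, pop, by = c("district_id", "year"))
  panel <- merge(panel, hierarchy, by = "district_id")

  cov_of <- function(v) {
    s <- covariates[covariates$variable == v, , drop = FALSE]
    if (nrow(s) == 0L) stop("covariate table has no rows for variable ", v,
                            call. = FALSE)
    s
  }
  add_district_cov <- function(panel, variable, colname = variable) {
    s <- cov_of(variable)
    filled <- interpolate_anchor_years(
      data.frame(unit_id = s$unit_id, year = s$year, value = s$value),
      years_out, variable = variable)
    idx <- match(paste(panel$district_id, panel$year),
                 paste(filled$unit_id, filled$year))
    panel[[colname]] <- filled$value[idx]
    panel
  }
  add_state_cov <- function(panel, variable, colname = variable) {
    s <- cov_of(variable)
    filled <- interpolate_anchor_years(
      data.frame(unit_id = s$unit_id, year = s$year, value = s$value),
      years_out, variable = variable)
    dist <- broadcast_state_to_district(filled, hierarchy)
    idx <- match(paste(panel$district_id, panel$year),
                 paste(dist$unit_id, dist$year))
    panel[[colname]] <- dist$value[idx]
    panel
  }

  tm <- cov_of("temp_monthly")
  qt <- quarterly_temperature_stats(
    data.frame(district_id = tm$unit_id, year = tm$year, month = tm$month,
               temp = tm$value, stringsAsFactors = FALSE),
    december_from = december_from)
  panel <- merge(panel, qt, by = c("district_id", "year"))

  panel <- add_district_cov(panel, "gdp_pc")
  panel <- add_district_cov(panel, "pct_age60")
  panel <- add_district_cov(panel, "clean_fuel")
  panel <- add_district_cov(panel, "women_lit")
  panel <- add_state_cov(panel, "median_age")
  panel <- add_state_cov(panel, "completeness")

  dcols <- intersect(c("deaths_reported", "deaths_true"), names(deaths))
  panel <- merge(panel, deaths[, c("district_id", "year", dcols)],
                 by = c("district_id", "year"), all.x = TRUE)
  panel$deaths <- panel$deaths_reported
  panel$deaths_reported <- NULL

  ord <- c("district_id", "division_id", "state_id", "year", "deaths",
           "population", "pm25_pw", "pm25_lag1", "pm25_lag01",
           panel_covariate_names(), "completeness",
           intersect("deaths_true", names(panel)))
  panel <- panel[order(panel$district_id, panel$year), ord]
  rownames(panel) <- NULL
  validate_panel(panel)
  panel
}

#' Validate a harmonised analysis panel
#'
#' Checks the panel schema and the invariants the estimator relies on:
#' one row per district-year (balanced), strictly positive population (the
#' log offset must be finite), nonnegative deaths, completeness in
#' (0, 100], and no missing values in any schema column. Violations fail
#' loudly with the offending column names.
#'
#' @param panel data.frame to validate.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  schema <- c("district_id", "division_id", "state_id", "year", "deaths",
              "population", "pm25_pw", "pm25_lag1", "pm25_lag01",
              panel_covariate_names(), "completeness")
  missing_cols <- setdiff(schema, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  na_cols <- schema[vapply(panel[schema], anyNA, logical(1))]
  if (length(na_cols)) {
    stop("panel has missing values in: ", paste(na_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$population <= 0)) {
    stop("panel population must be > 0 (offset must be finite)",
         call. = FALSE)
  }
  if (any(panel$deaths < 0)) stop("panel deaths must be >= 0", call. = FALSE)
  if (any(panel$completeness <= 0 | panel$completeness > 100)) {
    stop("completeness must lie in (0, 100]", call. = FALSE)
  }
  if (anyDuplicated(paste(panel$district_id, panel$year))) {
    stop("panel must have exactly one row per district-year", call. = FALSE)
  }
  n_d <- length(unique(panel$district_id))
  n_y <- length(unique(panel$year))
  if (nrow(panel) != n_d * n_y) {
    stop(sprintf("panel is unbalanced: %d rows != %d districts x %d years",
                 nrow(panel), n_d, n_y), call. = FALSE)
  }
  invisible(panel)
}
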