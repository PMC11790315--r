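#' Counterfactual air-quality threshold
#'
#' @param label \code{"NAAQS"} (Indian standard, 40 ug/m3), \code{"WHO"}
#'   (guideline, 5 ug/m3), or \code{"custom"} with an explicit \code{value}.
#' @param value threshold in ug/m3; defaults by label, must be >= 0.
#' @return An object of class \code{cf_threshold}.
#' @export
counterfactual_threshold <- function(label = c("NAAQS", "WHO", "custom"),
                                     value = NULL) {
  label <- match.arg(label)
  value <- value %||% switch(label, NAAQS = 40, WHO = 5,
                             stop("custom threshold needs a value",
                                  call. = FALSE))
  if (!is.finite(value) || value < 0) {
    stop("threshold value must be a nonnegative number", call. = FALSE)
  }
  structure(list(label = label, value = value), class = "cf_threshold")
}

#' Attributable deaths and fraction for given exposures
#'
#' Applies the attributable-mortality formula with the exposure excess over
#' the counterfactual threshold, \eqn{\Delta X = \max(0, x - x_0)}:
#' \deqn{AF = (e^{\beta \Delta X} - 1) / e^{\beta \Delta X}
#'          = 1 - e^{-\beta \Delta X}, \qquad M = AF \cdot N,}
#' where \eqn{\beta} is the per-ug/m3 log-rate coefficient and N the
#' observed deaths. \eqn{\Delta X} is clamped at zero: a counterfactual
#' that only lowers exposure to the standard must not produce negative
#' attributable deaths.
#'
#' @param beta per-ug/m3 coefficient (finite).
#' @param exposure observed exposure(s), ug/m3.
#' @param threshold a \code{\link{counterfactual_threshold}}.
#' @param deaths observed death count(s), >= 0.
#' @return data.frame \code{delta_x}, \code{af}, \code{attributable}
#'   (one row per input element).
#' @export
attributable_deaths <- function(beta, exposure, threshold, deaths) {
  stopifnot(inherits(threshold, "cf_threshold"))
  if (!is.finite(beta)) stop("beta must be finite", call. = FALSE)
  if (any(deaths < 0)) stop("deaths must be >= 0", call. = FALSE)
  n <- max(length(exposure), length(deaths))
  exposure <- rep_len(exposure, n)
  deaths <- rep_len(deaths, n)
  delta_x <- pmax(0, exposure - threshold$value)
  af <- 1 - exp(-beta * delta_x)
  data.frame(delta_x = delta_x, af = af, attributable = af * deaths)
}

#' Per-district-year burden for a panel
#'
#' @param fit a converged linear-exposure \code{did_fit}, or a bare numeric
#'   \code{beta} per ug/m3.
#' @param panel harmonised panel.
#' @param threshold a \code{\link{counterfactual_threshold}}.
#' @param use_calibrated if \code{TRUE} the burden uses completeness-
#'   calibrated deaths instead of reported deaths. Default \code{FALSE}:
#'   the headline burden refers to the main (reported-deaths) analysis.
#' @param exposure_col panel exposure column.
#' @return data.frame \code{district_id}, \code{year}, \code{deaths},
#'   \code{delta_x}, \code{af}, \code{attributable}.
#' @export
panel_burden <- function(fit, panel, threshold, use_calibrated = FALSE,
                         exposure_col = "pm25_pw") {
  beta <- if (inherits(fit, "did_fit")) {
    if (fit$exposure_form != "linear") {
      stop("burden requires a linear-exposure fit", call. = FALSE)
    }
    beta1(fit)["estimate"]
  } else {
    fit
  }
  p <- if (use_calibrated) calibrate_completeness(panel) else panel
  ad <- attributable_deaths(beta, p[[exposure_col]], threshold, p$deaths)
  cbind(data.frame(district_id = p$district_id, year = p$year,
                   deaths = p$deaths, stringsAsFactors = FALSE), ad)
}

#' Aggregate per-row burden to totals
#'
#' Totals attributable deaths over all district-years; the aggregate
#' attributable fraction divides by ALL deaths in the panel (including
#' below-threshold district-years), so it reads as a percentage of total
#' mortality. Mean deaths per year is the total divided by the number of
#' study years.
#'
#' @param rows output of \code{\link{panel_burden}} (>= 1 row).
#' @return list: \code{total} attributable deaths, \code{total_deaths},
#'   \code{af} (fraction of all deaths), \code{n_years},
#'   \code{mean_per_year}, and a per-year data.frame \code{per_year}.
#' @export
aggregate_burden <- function(rows) {
  if (NROW(rows) == 0L) stop("no burden rows to aggregate", call. = FALSE)
  total <- sum(rows$attributable)
  total_deaths <- sum(rows$deaths)
  years <- sort(unique(rows$year))
  per_year <- data.frame(
    year = years,
    deaths = as.numeric(tapply(rows$deaths, rows$year, sum)[as.character(years)]),
    attributable = as.numeric(tapply(rows$attributable, rows$year,
                                     sum)[as.character(years)])
  )
  per_year$af <- per_year$attributable / per_year$deaths
  list(total = total, total_deaths = total_deaths,
       af = total / total_deaths, n_years = length(years),
       mean_per_year = total / length(years), per_year = per_year)
}

#' Burden with confidence bounds propagated from the exposure coefficient
#'
#' Recomputes totals and fractions with the coefficient at its confidence
#' bounds. The attributable fraction is monotone increasing in beta, so
#' endpoint substitution is exact for this functional. Uncertainty in the
#' death counts and exposures themselves is not propagated.
#'
#' @param fit a converged linear-exposure \code{did_fit}.
#' @param panel harmonised panel.
#' @param threshold a \code{\link{counterfactual_threshold}}.
#' @inheritParams panel_burden
#' @return An object of class \code{burden_result}: the threshold, the
#'   per-row data.frame at the point estimate, and an \code{aggregate} list
#'   whose \code{total}, \code{mean_per_year} and \code{af} carry
#'   \code{estimate}/\code{lo}/\code{hi}.
#' @export
burden_ci <- function(fit, panel, threshold, use_calibrated = FALSE,
                      exposure_col = "pm25_pw") {
  stopifnot(inherits(fit, "did_fit"))
  if (fit$exposure_form != "linear") {
    stop("burden_ci requires a linear-exposure fit", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  b <- beta1(fit)
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  betas <- c(estimate = unname(b["estimate"]),
             lo = unname(b["estimate"] - z * b["se"]),
             hi = unname(b["estimate"] + z * b["se"]))
  aggs <- lapply(betas, function(beta) {
    aggregate_burden(panel_burden(beta, panel, threshold,
                                  use_calibrated = use_calibrated,
                                  exposure_col = exposure_col))
  })
  point_rows <- panel_burden(betas["estimate"], panel, threshold,
                             use_calibrated = use_calibrated,
                             exposure_col = exposure_col)
  pick <- function(field) {
    c(estimate = aggs$estimate[[field]], lo = aggs$lo[[field]],
      hi = aggs$hi[[field]])
  }
  structure(list(
    threshold = threshold,
    rows = point_rows,
    aggregate = list(total = pick("total"),
                     mean_per_year = pick("mean_per_year"),
                     af = pick("af"),
                     total_deaths = aggs$estimate$total_deaths,
                     n_years = aggs$estimate$n_years,
                     per_year = aggs$estimate$per_year),
    ci_level = fit$ci_level
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<burden_result> threshold %s (%.1f ug/m3), %d years\n",
              x$threshold$label, x$threshold$value, a$n_years))
  cat(sprintf("  total attributable deaths: %.0f (%.0f-%.0f)\n",
              a$total["estimate"], a$total["lo"], a$total["hi"]))
  cat(sprintf("  mean per year: %.0f (%.0f-%.0f)\n",
              a$mean_per_year["estimate"], a$mean_per_year["lo"],
              a$mean_per_year["hi"]))
  cat(sprintf("  attributable fraction: %.1f%% (%.1f-%.1f)\n",
              100 * a$af["estimate"], 100 * a$af["lo"], 100 * a$af["hi"]))
  invisible(x)
}
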