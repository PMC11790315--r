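#' Calibrate deaths for registration completeness
#'
#' Scales reported deaths up to estimated true deaths by dividing by the
#' state-level completeness fraction:
#' \code{deaths_calibrated = deaths / (completeness / 100)}. (The source
#' description of this step reads "multiplying the actual number of reported
#' deaths with completeness of death reporting expressed as a percentage",
#' which — taken literally with a fraction at or below one — would shrink
#' already-incomplete counts; division is the operation that moves reported
#' counts toward the registry-estimated totals, so division is what is
#' implemented.) Calibrated counts are real-valued and are fed to the
#' quasi-likelihood fit unrounded.
#'
#' @param panel harmonised panel with \code{deaths} and \code{completeness}
#'   (percent in (0, 100]).
#' @return The panel with \code{deaths} replaced by the calibrated counts.
#' @export
calibrate_completeness <- function(panel) {
  if (any(panel$completeness <= 0)) {
    stop("completeness must be > 0 to calibrate", call. = FALSE)
  }
  if (any(panel$completeness > 100)) {
    stop("completeness above 100% is not meaningful", call. = FALSE)
  }
  panel$deaths <- panel$deaths / (panel$completeness / 100)
  panel
}

#' Exclude extreme exposure district-years
#'
#' Drops rows whose exposure is strictly below the pooled 1st percentile or
#' strictly above the pooled 99th percentile of district-year exposures
#' (percentiles by linear interpolation between order statistics; rows
#' exactly at a bound are retained). Percentiles are pooled nationally;
#' set \code{by_division = TRUE} for within-division percentiles.
#'
#' @param panel harmonised panel.
#' @param lower,upper percentile bounds as fractions (defaults 0.01, 0.99).
#' @param exposure_col exposure column the percentiles are taken over.
#' @param by_division compute percentiles within each division instead of
#'   pooled.
#' @return The reduced panel.
#' @export
filter_extreme_exposure <- function(panel, lower = 0.01, upper = 0.99,
                                    exposure_col = "pm25_pw",
                                    by_division = FALSE) {
  if (nrow(panel) < 100L) {
    stop("need >= 100 rows for meaningful 1st/99th percentiles",
         call. = FALSE)
  }
  x <- panel[[exposure_col]]
  keep <- if (by_division) {
    bounds <- tapply(x, panel$division_id, stats::quantile,
                     probs = c(lower, upper), type = 7)
    lo <- vapply(bounds, `[`, 0, 1L)[panel$division_id]
    hi <- vapply(bounds, `[`, 0, 2L)[panel$division_id]
    x >= lo & x <= hi
  } else {
    q <- stats::quantile(x, c(lower, upper), type = 7, names = FALSE)
    x >= q[1] & x <= q[2]
  }
  out <- panel[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("extreme-exposure filter removed every row",
                            call. = FALSE)
  out
}

#' Run the full sensitivity suite
#'
#' Fits, with an identical model specification throughout: the main model;
#' the completeness-calibrated model; the model on the panel with extreme
#' exposures excluded; and the two lagged-exposure models (exposure column
#' swapped to \code{pm25_lag1} and \code{pm25_lag01}). Lag analyses never
#' use the pre-study year as an outcome year: the panel contains outcome
#' years only, and the lag columns were filled from the prior year's
#' exposure at harmonisation.
#'
#' @param panel harmonised panel with lag columns attached.
#' @param spec a \code{\link{model_spec}} used for every fit.
#' @return An object of class \code{sensitivity_suite}: named list of
#'   \code{did_fit}s (\code{main}, \code{completeness_calibrated},
#'   \code{extremes_excluded}, \code{lag1}, \code{lag01}) plus \code{n_rows},
#'   the panel size actually fitted per analysis.
#' @export
run_sensitivity_suite <- function(panel, spec = model_spec()) {
  analyses <- list(
    main = function() fit_did(panel, spec),
    completeness_calibrated = function()
      fit_did(calibrate_completeness(panel), spec),
    extremes_excluded = function()
      fit_did(filter_extreme_exposure(panel, exposure_col = spec$exposure_col),
              spec),
    lag1 = function() {
      s <- spec
      s$exposure_col <- "pm25_lag1"
      fit_did(panel, s)
    },
    lag01 = function() {
      s <- spec
      s$exposure_col <- "pm25_lag01"
      fit_did(panel, s)
    }
  )
  fits <- lapply(names(analyses), function(label) {
    tryCatch(analyses[[label]](), error = function(e) {
      stop(sprintf("sensitivity analysis '%s' failed: %s", label,
                   conditionMessage(e)), call. = FALSE)
    })
  })
  names(fits) <- names(analyses)
  n_rows <- vapply(fits, function(f) f$n_obs, integer(1))
  structure(list(fits = fits, n_rows = n_rows),
            class = "sensitivity_suite")
}

#' @export
print.sensitivity_suite <- function(x, ...) {
  cat("<sensitivity_suite>\n")
  print(sensitivity_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Comparison table of a sensitivity suite
#'
#' @param suite a \code{\link{run_sensitivity_suite}} result.
#' @return data.frame with one row per analysis: label, rows fitted, percent
#'   change per 10 ug/m3 with CI, and dispersion.
#' @export
sensitivity_table <- function(suite) {
  stopifnot(inherits(suite, "sensitivity_suite"))
  rows <- lapply(names(suite$fits), function(label) {
    fit <- suite$fits[[label]]
    pc <- percent_change_per_10(fit)
    data.frame(analysis = label, n = fit$n_obs,
               pc_per_10 = unname(pc$estimate), lo = unname(pc$lo),
               hi = unname(pc$hi), phi = fit$phi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
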