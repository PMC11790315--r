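#' Estimator configuration
#'
#' @param exposure_form \code{"linear"} (a single per-ug/m3 coefficient) or
#'   \code{"spline_df4"} (a 4-df natural spline of exposure, for the
#'   exposure-response curve).
#' @param trend_df degrees of freedom of each division's natural-spline time
#'   trend (default 3).
#' @param covariates character vector of panel covariate columns to adjust
#'   for; default: the full harmonised set
#'   (\code{didpm25:::panel_covariate_names()}).
#' @param exposure_col panel column holding the exposure (swap to
#'   \code{"pm25_lag1"} / \code{"pm25_lag01"} for lag analyses).
#' @param dispersion_method only \code{"pearson"} is offered: the dispersion
#'   is the Pearson chi-square divided by residual degrees of freedom.
#' @param ci_level confidence level for intervals (normal critical values,
#'   consistent with quasi-likelihood asymptotics).
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(exposure_form = c("linear", "spline_df4"),
                       trend_df = 3L,
                       covariates = panel_covariate_names(),
                       exposure_col = "pm25_pw",
                       dispersion_method = "pearson",
                       ci_level = 0.95) {
  exposure_form <- match.arg(exposure_form)
  dispersion_method <- match.arg(dispersion_method, "pearson")
  if (trend_df < 1L) stop("trend_df must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }
  structure(list(exposure_form = exposure_form,
                 trend_df = as.integer(trend_df),
                 covariates = covariates,
                 exposure_col = exposure_col,
                 dispersion_method = dispersion_method,
                 ci_level = ci_level),
            class = "model_spec")
}

#' Natural cubic spline basis with fixed degrees of freedom
#'
#' Returns a \code{df}-column natural cubic spline basis (linear beyond the
#' boundary knots), with boundary knots at the range of \code{x} and
#' interior knots at equally spaced quantiles — the fixed-df regression
#' spline convention. Evaluate the basis at new points with
#' \code{predict(basis, newx)}.
#'
#' @param x numeric vector with at least \code{df + 1} distinct values.
#' @param df number of basis columns (>= 1).
#' @return The basis matrix (with knot attributes usable by \code{predict}).
#' @export
natural_spline_basis <- function(x, df) {
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  if (length(unique(x)) < df + 1L) {
    stop(sprintf("need at least %d distinct values for a %d-df basis",
                 df + 1L, df), call. = FALSE)
  }
  splines::ns(x, df = df)
}

#' Build the design matrix of the DiD model
#'
#' Assembles, in order: an intercept; the exposure term (one raw column for
#' the linear form, a 4-df natural-spline block for \code{spline_df4});
#' reference-coded division indicators (first division dropped); one
#' \code{trend_df}-column natural-spline-of-year block per division, zeroed
#' outside the division and centred within it (centring reduces collinearity
#' with the indicators and leaves the exposure coefficient invariant); and
#' the covariate block, centred and scaled. Exposure columns are never
#' rescaled, so the linear coefficient stays per ug/m3. Calendar year is
#' mapped to [0, 1] across the panel before the spline is built, for
#' numerical stability. The offset is log population and the response is the
#' death count.
#'
#' @param panel harmonised analysis panel (need not be balanced; sensitivity
#'   subsets are accepted).
#' @param spec a \code{\link{model_spec}}.
#' @return An object of class \code{did_design}: list with \code{X},
#'   \code{y}, \code{offset}, \code{exposure_cols}, \code{exposure_values},
#'   \code{exposure_basis} (spline form only), and bookkeeping metadata.
#' @export
build_design_matrix <- function(panel, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$exposure_col, spec$covariates,
                            "division_id", "year", "deaths", "population"),
                          names(panel))
  if (length(missing_cols)) {
    stop("panel lacks columns required by the model spec: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(panel$year))
  if (length(years) < spec$trend_df + 1L) {
    stop(sprintf("need >= %d distinct years for a %d-df trend",
                 spec$trend_df + 1L, spec$trend_df), call. = FALSE)
  }
  per_div_years <- tapply(panel$year, panel$division_id,
                          function(y) length(unique(y)))
  thin <- names(per_div_years)[per_div_years < spec$trend_df + 1L]
  if (length(thin)) {
    stop("divisions with fewer than trend_df + 1 years: ",
         paste(thin, collapse = ", "), call. = FALSE)
  }

  x <- panel[[spec$exposure_col]]
  exposure_basis <- NULL
  if (spec$exposure_form == "linear") {
    exposure <- matrix(x, ncol = 1,
                       dimnames = list(NULL, spec$exposure_col))
  } else {
    exposure_basis <- natural_spline_basis(x, df = 4L)
    exposure <- unclass(exposure_basis)
    colnames(exposure) <- paste0(spec$exposure_col, "_ns", 1:4)
  }

  divisions <- sort(unique(panel$division_id))
  div <- factor(panel$division_id, levels = divisions)
  ind <- NULL
  if (length(divisions) > 1L) {
    ind <- stats::model.matrix(~div)[, -1L, drop = FALSE]
    colnames(ind) <- paste0("div_", divisions[-1L])
  }

  year01 <- (panel$year - min(years)) / diff(range(years))
  tbasis <- natural_spline_basis(year01, df = spec$trend_df)
  trend <- matrix(0, nrow(panel), length(divisions) * spec$trend_df)
  cn <- character(ncol(trend))
  for (i in seq_along(divisions)) {
    rows <- div == divisions[i]
    cols <- (i - 1L) * spec$trend_df + seq_len(spec$trend_df)
    block <- unclass(tbasis)[rows, , drop = FALSE]
    trend[rows, cols] <- scale(block, center = TRUE, scale = FALSE)
    cn[cols] <- paste0("trend_", divisions[i], "_", seq_len(spec$trend_df))
  }
  colnames(trend) <- cn

  covs <- NULL
  if (length(spec$covariates)) {
    covs <- scale(as.matrix(panel[spec$covariates]))
    const <- attr(covs, "scaled:scale") == 0 | !is.finite(attr(covs, "scaled:scale"))
    if (any(const)) {
      stop("constant covariate column(s) cannot be scaled: ",
           paste(spec$covariates[const], collapse = ", "), call. = FALSE)
    }
  }

  X <- cbind(`(Intercept)` = 1, exposure, ind, trend, covs)
  if (any(!is.finite(X))) stop("design matrix has non-finite entries",
                               call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  structure(list(
    X = X,
    y = panel$deaths,
    offset = log(panel$population),
    exposure_cols = colnames(exposure),
    exposure_values = x,
    exposure_basis = exposure_basis,
    spec = spec,
    divisions = divisions,
    years = years
  ), class = "did_design")
}

#' Fit a quasi-Poisson regression by IRLS
#'
#' Maximises the Poisson log-likelihood with an offset by iteratively
#' reweighted least squares (convergence when the largest relative
#' coefficient change drops below \code{tol}; hard failure otherwise), then
#' scales inference by the Pearson dispersion
#' \eqn{\hat\phi = X^2_P / (n - p)}: the covariance is
#' \eqn{\hat\phi (X'WX)^{-1}} and intervals use normal critical values.
#' Real-valued nonnegative responses are accepted — calibrated death counts
#' are legitimately non-integer under quasi-likelihood.
#'
#' @param design a \code{\link{build_design_matrix}} result, or a bare
#'   numeric matrix (then \code{y} and \code{offset} must be given).
#' @param y,offset response and offset vectors (ignored when \code{design}
#'   is a \code{did_design}).
#' @param ci_level confidence level; defaults to the design's spec.
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return An object of class \code{did_fit}: coefficients, standard errors,
#'   dispersion-scaled covariance, Pearson dispersion \code{phi},
#'   \code{n_obs}, \code{n_params}, convergence metadata, fitted means, and
#'   the exposure bookkeeping needed by \code{\link{percent_change_per_10}}
#'   and \code{\link{erf_curve}}.
#' @export
fit_quasipoisson <- function(design, y = NULL, offset = NULL,
                             ci_level = NULL, max_iter = 100L, tol = 1e-8) {
  if (inherits(design, "did_design")) {
    X <- design$X
    y <- design$y
    offset <- design$offset
    ci_level <- ci_level %||% design$spec$ci_level
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("y is required with a bare design matrix",
                         call. = FALSE)
    offset <- offset %||% rep(0, length(y))
    ci_level <- ci_level %||% 0.95
  }
  n <- length(y)
  p <- ncol(X)
  if (any(y < 0)) stop("response must be nonnegative", call. = FALSE)
  if (n <= p) stop("need n_obs > n_params", call. = FALSE)

  mu <- pmax(y, 0) + mean(y) * 0.1 + 0.1
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    XtWz <- crossprod(X, w * z)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) {
      stop("IRLS normal equations are singular (separation or collinearity)",
           call. = FALSE)
    }
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), XtWz)))
    eta <- drop(X %*% beta_new) + offset
    if (any(!is.finite(eta)) || any(eta > 700)) {
      stop("IRLS diverged: unbounded linear predictor (separation?)",
           call. = FALSE)
    }
    mu <- exp(eta)
    # relative change, with a floor on the denominator so coefficients that
    # are genuinely ~0 are judged on an absolute 1e-10 scale instead of
    # stalling the iteration
    delta <- max(abs(beta_new - beta) / pmax(abs(beta), 1e-2))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "IRLS did not converge in %d iterations (last relative change %.3g)",
      max_iter, delta), call. = FALSE)
  }

  phi <- sum((y - mu)^2 / mu) / (n - p)
  w <- mu
  XtWX <- crossprod(X, X * w)
  vcov <- phi * chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)

  fit <- list(
    coefficients = beta,
    se = se,
    vcov = vcov,
    phi = phi,
    n_obs = n,
    n_params = p,
    converged = converged,
    iterations = iter,
    ci_level = ci_level,
    fitted = mu,
    exposure_form = if (inherits(design, "did_design"))
      design$spec$exposure_form else "linear",
    exposure_cols = if (inherits(design, "did_design"))
      design$exposure_cols else colnames(X)[min(2L, p)],
    exposure_values = if (inherits(design, "did_design"))
      design$exposure_values else NULL,
    exposure_basis = if (inherits(design, "did_design"))
      design$exposure_basis else NULL
  )
  class(fit) <- "did_fit"
  fit
}

#' Fit the DiD model to a harmonised panel
#'
#' Convenience wrapper: \code{\link{build_design_matrix}} followed by
#' \code{\link{fit_quasipoisson}}.
#'
#' @param panel harmonised analysis panel.
#' @param spec a \code{\link{model_spec}}.
#' @return A \code{did_fit}.
#' @export
fit_did <- function(panel, spec = model_spec()) {
  fit_quasipoisson(build_design_matrix(panel, spec))
}

#' Fit the crude model (no trends, no covariates)
#'
#' Intercept + exposure + offset only. Used as the before/after contrast to
#' the DiD fit: on confounded data the crude estimate absorbs whatever the
#' division trends would have removed.
#'
#' @inheritParams fit_did
#' @return A \code{did_fit}.
#' @export
fit_crude <- function(panel, spec = model_spec()) {
  crude_spec <- spec
  crude_spec$covariates <- character()
  x <- panel[[spec$exposure_col]]
  X <- cbind(`(Intercept)` = 1, matrix(x, ncol = 1,
                                       dimnames = list(NULL, spec$exposure_col)))
  fit <- fit_quasipoisson(X, y = panel$deaths, offset = log(panel$population),
                          ci_level = spec$ci_level)
  fit$exposure_cols <- spec$exposure_col
  fit$exposure_values <- x
  fit$exposure_form <- "linear"
  fit
}

# The linear exposure coefficient and its standard error.
beta1 <- function(fit) {
  stopifnot(inherits(fit, "did_fit"))
  if (fit$exposure_form != "linear") {
    stop("beta1 is only defined for the linear exposure form", call. = FALSE)
  }
  col <- fit$exposure_cols[1]
  c(estimate = unname(fit$coefficients[col]), se = unname(fit$se[col]))
}

#' Percent change in mortality per 10 ug/m3
#'
#' Transforms the linear exposure coefficient to the conventional reporting
#' scale: \code{100 * (exp(10 * beta1) - 1)} with CI endpoints transformed
#' the same way from \code{beta1 +/- z * SE}.
#'
#' @param fit a linear-exposure \code{did_fit}.
#' @return A list with \code{estimate}, \code{lo}, \code{hi} (percent),
#'   \code{beta1}, \code{se}, and \code{ci_level}.
#' @export
percent_change_per_10 <- function(fit) {
  if (fit$exposure_form != "linear") {
    stop("percent change per 10 ug/m3 requires the linear exposure form; ",
         "use erf_curve() for spline fits", call. = FALSE)
  }
  b <- beta1(fit)
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  pc <- function(beta) 100 * (exp(10 * beta) - 1)
  list(estimate = unname(pc(b["estimate"])),
       lo = unname(pc(b["estimate"] - z * b["se"])),
       hi = unname(pc(b["estimate"] + z * b["se"])),
       beta1 = unname(b["estimate"]), se = unname(b["se"]),
       ci_level = fit$ci_level)
}

#' Exposure-response curve from a spline-exposure fit
#'
#' The log relative rate at exposure x versus a reference exposure,
#' \code{logRR(x) = s(x) - s(ref)}, with delta-method pointwise confidence
#' bounds from the dispersion-scaled covariance of the spline coefficients.
#' The default grid spans the observed exposure range truncated at the 99th
#' percentile; the default reference is the minimum observed exposure. The
#' curve is exactly zero (with zero-width CI) at the reference.
#'
#' @param fit a \code{did_fit} with \code{exposure_form = "spline_df4"}.
#' @param reference reference exposure in ug/m3 (within the data range).
#' @param grid exposure grid; default 100 points up to the 99th percentile.
#' @return data.frame of class \code{erf_curve}: \code{exposure},
#'   \code{log_rr}, \code{se}, \code{lo}, \code{hi}.
#' @export
erf_curve <- function(fit, reference = NULL, grid = NULL) {
  if (fit$exposure_form != "spline_df4" || is.null(fit$exposure_basis)) {
    stop("erf_curve requires a spline_df4 exposure fit", call. = FALSE)
  }
  x <- fit$exposure_values
  reference <- reference %||% min(x)
  if (reference < min(x) || reference > max(x)) {
    stop(sprintf("reference %.2f lies outside the exposure range [%.2f, %.2f]",
                 reference, min(x), max(x)), call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- seq(min(x), stats::quantile(x, 0.99, names = FALSE),
                length.out = 100L)
  }
  basis_at <- function(v) {
    unname(stats::predict(fit$exposure_basis, v))
  }
  d <- basis_at(grid) - matrix(basis_at(reference), nrow = length(grid),
                               ncol = 4L, byrow = TRUE)
  cols <- fit$exposure_cols
  bexp <- fit$coefficients[cols]
  vexp <- fit$vcov[cols, cols]
  log_rr <- drop(d %*% bexp)
  se <- sqrt(pmax(rowSums((d %*% vexp) * d), 0))
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  out <- data.frame(exposure = grid, log_rr = log_rr, se = se,
                    lo = log_rr - z * se, hi = log_rr + z * se)
  class(out) <- c("erf_curve", "data.frame")
  out
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf(
    "<did_fit> %s exposure, %d obs, %d params, phi = %.3f, %d IRLS iterations\n",
    x$exposure_form, x$n_obs, x$n_params, x$phi, x$iterations))
  if (x$exposure_form == "linear") {
    pc <- percent_change_per_10(x)
    cat(sprintf("  percent change per 10 ug/m3: %.2f%% (%.0f%% CI %.2f to %.2f)\n",
                pc$estimate, 100 * x$ci_level, pc$lo, pc$hi))
  }
  invisible(x)
}

# FitResult as a plain list for JSON serialisation.
fit_as_list <- function(fit) {
  out <- list(coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              phi = fit$phi, n_obs = fit$n_obs, n_params = fit$n_params,
              converged = fit$converged, iterations = fit$iterations,
              ci_level = fit$ci_level, exposure_form = fit$exposure_form)
  if (fit$exposure_form == "linear") {
    out$percent_change_per_10 <- percent_change_per_10(fit)[c("estimate",
                                                              "lo", "hi")]
  }
  out
}
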