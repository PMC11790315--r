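test_that("design matrix has the documented column structure", {
  spec10 <- model_spec(covariates = panel_covariate_names()[1:10])
  d <- build_design_matrix(TINY_PANEL, spec10)
  # intercept + exposure + (V-1) indicators + V*trend_df spline + covariates
  expect_equal(ncol(d$X), 1 + 1 + 3 + 4 * 3 + 10)
  expect_equal(colnames(d$X)[1:2], c("(Intercept)", "pm25_pw"))
  expect_equal(d$offset, log(TINY_PANEL$population))
  expect_equal(d$y, TINY_PANEL$deaths)
  # trend columns are zero outside their own division
  v1_rows <- TINY_PANEL$division_id == "V001"
  v2_cols <- grep("^trend_V002", colnames(d$X))
  expect_true(all(d$X[v1_rows, v2_cols] == 0))

  dspl <- build_design_matrix(TINY_PANEL,
                              model_spec(exposure_form = "spline_df4"))
  expect_length(dspl$exposure_cols, 4L)

  # exposure column is never rescaled (coefficient must stay per ug/m3)
  expect_equal(unname(d$X[, "pm25_pw"]), TINY_PANEL$pm25_pw)
})

test_that("single-division model collapses to a plain spline-trend regression", {
  cfg1 <- tiny_config(n_states = 1, n_divisions = 1, n_districts = 8,
                      seed = 3)
  inp <- simulate_panel_inputs(cfg1)
  panel <- build_panel(inp$grid, inp$covariates, inp$deaths, inp$hierarchy)
  d <- build_design_matrix(panel)
  expect_false(any(grepl("^div_", colnames(d$X))))

  fit <- fit_quasipoisson(d)
  year01 <- (panel$year - min(panel$year)) / diff(range(panel$year))
  covs <- scale(as.matrix(panel[panel_covariate_names()]))
  oracle <- glm(panel$deaths ~ panel$pm25_pw + splines::ns(year01, df = 3) +
                  covs, family = poisson(),
                offset = log(panel$population))
  expect_lt(abs(coef(oracle)[["panel$pm25_pw"]] -
                  fit$coefficients[["pm25_pw"]]), 1e-8)
})

test_that("natural spline basis is linear at the boundaries and spans lines", {
  x <- seq(0, 1, length.out = 30)
  b1 <- natural_spline_basis(x, df = 1)
  expect_equal(abs(cor(as.vector(b1), x)), 1, tolerance = 1e-12)

  b3 <- natural_spline_basis(x, df = 3)
  # beyond the boundary knots each basis column is linear: second
  # differences vanish
  for (xout in list(seq(-1, -0.5, by = 0.05), seq(1.5, 2, by = 0.05))) {
    pb <- predict(b3, xout)
    for (j in 1:3) {
      d2 <- diff(pb[, j], differences = 2)
      expect_lt(max(abs(d2)), 1e-9)
    }
  }
  expect_error(natural_spline_basis(c(1, 1, 1, 2), df = 3), "distinct")
})

test_that("spline basis reproduces the tridiagonal natural-spline interpolant", {
  x <- seq(0, 1, length.out = 41)
  df <- 4
  b <- natural_spline_basis(x, df = df)
  knots <- sort(c(attr(b, "Boundary.knots"), attr(b, "knots")))
  f <- function(z) 1 + 2 * z - z^2 + 0.5 * z^3
  yk <- f(knots)
  # interpolate through the knots within the basis span (+ intercept):
  # df + 1 coefficients, df + 1 knots -> exactly determined
  A <- cbind(1, predict(b, knots))
  coefs <- solve(A, yk)
  grid <- seq(0, 1, length.out = 201)
  ours <- drop(cbind(1, predict(b, grid)) %*% coefs)
  oracle <- ncs_interpolate(knots, yk, grid)
  expect_equal(ours, oracle, tolerance = 1e-8)
})

test_that("IRLS quasi-Poisson matches an independent fitter and recovers truth", {
  # cross-check against stats::glm on the harmonised panel
  d <- build_design_matrix(TINY_PANEL)
  fit <- fit_quasipoisson(d)
  ref <- glm.fit(d$X, d$y, family = quasipoisson(), offset = d$offset,
                 control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  ref_phi <- sum((d$y - ref$fitted.values)^2 / ref$fitted.values) /
    (fit$n_obs - fit$n_params)
  expect_equal(fit$phi, ref_phi, tolerance = 1e-6)

  # parameter recovery on data simulated from a known Poisson model
  set.seed(77)
  n <- 3000
  X <- cbind(1, rnorm(n), runif(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta_true <- c(-1, 0.3, 0.8)
  off <- log(runif(n, 50, 150))
  y <- rpois(n, exp(drop(X %*% beta_true) + off))
  f <- fit_quasipoisson(X, y = y, offset = off)
  mc_se <- f$se
  expect_true(all(abs(f$coefficients - beta_true) < 3 * mc_se))
  # exact-Poisson data: Pearson dispersion near 1
  expect_lt(abs(f$phi - 1), 0.1)
})

test_that("a constant multiplied into the offset moves only the intercept", {
  d <- build_design_matrix(TINY_PANEL)
  f1 <- fit_quasipoisson(d$X, y = d$y, offset = d$offset)
  f2 <- fit_quasipoisson(d$X, y = d$y, offset = d$offset + log(10))
  expect_equal(f2$coefficients[["pm25_pw"]], f1$coefficients[["pm25_pw"]],
               tolerance = 1e-8)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] - log(10), tolerance = 1e-7)
})

test_that("confidence width scales with the root of the dispersion", {
  set.seed(31)
  n <- 4000
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  mu <- exp(3 + 0.2 * X[, 2])
  y_pois <- rpois(n, mu)
  phi <- 5
  y_nb <- rnbinom(n, mu = mu, size = mu / (phi - 1))
  f1 <- fit_quasipoisson(X, y = y_pois)
  f5 <- fit_quasipoisson(X, y = y_nb)
  ratio <- f5$se[["x"]] / f1$se[["x"]]
  expect_equal(ratio, sqrt(f5$phi / f1$phi), tolerance = 0.05)
  expect_equal(f5$phi, phi, tolerance = 0.25)
})

test_that("centring the per-division spline blocks leaves the estimate invariant", {
  d <- build_design_matrix(TINY_PANEL)
  # rebuild the trend block without within-division centring
  X2 <- d$X
  year01 <- (TINY_PANEL$year - min(TINY_PANEL$year)) /
    diff(range(TINY_PANEL$year))
  tb <- natural_spline_basis(year01, df = 3)
  for (v in unique(TINY_PANEL$division_id)) {
    rows <- TINY_PANEL$division_id == v
    cols <- grep(paste0("^trend_", v, "_"), colnames(X2))
    X2[rows, cols] <- unclass(tb)[rows, ]
  }
  f1 <- fit_quasipoisson(d)
  f2 <- fit_quasipoisson(X2, y = d$y, offset = d$offset)
  expect_equal(f2$coefficients[["pm25_pw"]], f1$coefficients[["pm25_pw"]],
               tolerance = 1e-7)
})

test_that("rank-deficient designs fail loudly with column names", {
  p <- TINY_PANEL
  p$gdp_pc <- p$median_age   # force exact collinearity
  expect_error(build_design_matrix(p), "collinear|scaled")
})

test_that("percent change per 10 transforms the coefficient exactly", {
  expect_equal(percent_change_per_10(stub_fit(log(1.086) / 10))$estimate,
               8.6, tolerance = 1e-10)
  expect_equal(percent_change_per_10(stub_fit(0))$estimate, 0)
  expect_equal(percent_change_per_10(stub_fit(log(2) / 10))$estimate, 100,
               tolerance = 1e-10)
  pc <- percent_change_per_10(stub_fit(log(1.086) / 10, se = 1e-3))
  expect_lt(pc$lo, pc$estimate)
  expect_gt(pc$hi, pc$estimate)

  sp <- stub_fit(0.001)
  sp$exposure_form <- "spline_df4"
  expect_error(percent_change_per_10(sp), "erf_curve")
})

test_that("exposure-response curve is anchored at the reference and bounded at p99", {
  fit <- fit_did(TINY_PANEL, model_spec(exposure_form = "spline_df4"))
  curve <- erf_curve(fit)
  ref_row <- which.min(abs(curve$exposure - min(TINY_PANEL$pm25_pw)))
  expect_equal(curve$log_rr[ref_row], 0, tolerance = 1e-12)
  expect_equal(curve$se[ref_row], 0, tolerance = 1e-12)
  expect_lte(max(curve$exposure),
             quantile(TINY_PANEL$pm25_pw, 0.99, names = FALSE))
  expect_true(all(is.finite(curve$lo) & is.finite(curve$hi)))
  expect_error(erf_curve(fit, reference = 1000), "outside")

  # on data with a truly linear exposure-response, the spline curve's
  # secant slope per 10 ug/m3 agrees with the linear fit
  lin <- percent_change_per_10(fit_did(TINY_PANEL))
  q <- quantile(TINY_PANEL$pm25_pw, c(0.2, 0.8), names = FALSE)
  i1 <- which.min(abs(curve$exposure - q[1]))
  i2 <- which.min(abs(curve$exposure - q[2]))
  secant_pc <- 100 * (exp(10 * (curve$log_rr[i2] - curve$log_rr[i1]) /
                            (curve$exposure[i2] - curve$exposure[i1])) - 1)
  expect_equal(secant_pc, lin$estimate, tolerance = 0.35 * lin$estimate)
})
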