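test_that("hierarchy has valid, deterministic structure", {
  h <- generate_hierarchy(tiny_config())
  expect_equal(nrow(h), 12L)
  expect_setequal(unique(h$division_id), sprintf("V%03d", 1:4))
  # each district in exactly one division, each division in exactly one state
  expect_false(anyDuplicated(h$district_id) > 0)
  div_states <- tapply(h$state_id, h$division_id,
                       function(s) length(unique(s)))
  expect_true(all(div_states == 1L))

  h1 <- generate_hierarchy(sim_config(n_states = 1, n_divisions = 1,
                                      n_districts = 1))
  expect_equal(nrow(h1), 1L)

  expect_identical(generate_hierarchy(tiny_config()), h)
  expect_error(sim_config(n_states = 2, n_divisions = 4, n_districts = 3),
               "n_districts")
})

test_that("exposure grid respects range, structure, and determinism", {
  expect_true(all(TINY$grid$pm25_ugm3 >= 11.2 & TINY$grid$pm25_ugm3 <= 119.0))
  expect_true(all(TINY$grid$population > 0))
  expect_false(anyDuplicated(paste(TINY$grid$cell_id, TINY$grid$year)) > 0)

  # degenerate variance: no noise, no trends -> every cell equals the
  # district mean, constant over years
  cfg0 <- tiny_config(cell_noise_sd = 0, exposure_sd_temporal = 0,
                      exposure_trend = 0)
  g0 <- simulate_exposure_grid(cfg0, generate_hierarchy(cfg0))
  spread <- tapply(g0$pm25_ugm3, g0$district_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))

  g_again <- simulate_exposure_grid(TINY_CFG, TINY$hierarchy, TINY$truth)
  expect_identical(g_again, TINY$grid)
})

test_that("district population-weighted exposures have realistic national spread", {
  cfg <- sim_config(seed = 99)
  inp <- simulate_panel_inputs(cfg)
  pm <- popweighted_district_means(inp$grid)
  q <- quantile(pm$pm25_pw, c(0.05, 0.5, 0.95), names = FALSE)
  # loose stochastic band around a 5th-95th spread of ~20-72 with median ~39
  expect_gt(q[1], 14)
  expect_lt(q[1], 29)
  expect_gt(q[2], 30)
  expect_lt(q[2], 50)
  expect_gt(q[3], 52)
  expect_lt(q[3], 95)
})

test_that("covariates have the anchor-year structure of their sources", {
  cov <- TINY$covariates
  per_district_anchors <- function(variable) {
    s <- cov[cov$variable == variable & !is.na(cov$value), ]
    tapply(s$year, s$unit_id, function(y) length(unique(y)))
  }
  expect_true(all(per_district_anchors("clean_fuel") == 3L))
  expect_true(all(per_district_anchors("women_lit") == 2L))
  expect_true(all(per_district_anchors("pct_age60") == 1L))

  comp <- cov[cov$variable == "completeness", "value"]
  expect_true(all(comp >= 30 & comp <= 100))

  # median age is a state-level quantity: identical across a state's
  # districts after harmonisation
  by_state_year <- tapply(TINY_PANEL$median_age,
                          paste(TINY_PANEL$state_id, TINY_PANEL$year),
                          function(x) length(unique(x)))
  expect_true(all(by_state_year == 1L))
})

test_that("generator mean matches the closed-form rate model", {
  # beta = 0, flat trends: expected mortality rate is exactly baseline_rate
  cfg <- tiny_config(true_beta = 0, trend_amplitude = 0,
                     apply_completeness = FALSE, dispersion_phi = 1,
                     seed = 5)
  inp <- simulate_panel_inputs(cfg)
  pm <- popweighted_district_means(inp$grid)
  pop <- aggregate(population ~ district_id + year, data = inp$grid, sum)
  de <- merge(pm, pop, by = c("district_id", "year"))
  ed <- expected_deaths(cfg, de, inp$covariates, inp$truth, inp$hierarchy)

  total_pop <- sum(ed$rows$population)
  rate <- sum(inp$deaths$deaths_true) / total_pop
  mc_se <- sqrt(sum(ed$lambda)) / total_pop
  expect_lt(abs(rate - sum(ed$lambda) / total_pop), 3 * mc_se)
  # and the analytic mean itself sits at baseline_rate up to the
  # finite-sample wobble of the realised district effects (12 districts
  # here, so a few percent)
  expect_equal(sum(ed$lambda) / total_pop, cfg$baseline_rate,
               tolerance = 0.03)

  # replicate draws at fixed covariates match lambda within 3 SE
  cfg2 <- tiny_config(n_states = 1, n_divisions = 2, n_districts = 4,
                      years = 2008:2012, apply_completeness = FALSE,
                      dispersion_phi = 2, seed = 8)
  inp2 <- simulate_panel_inputs(cfg2)
  pm2 <- popweighted_district_means(inp2$grid)
  pop2 <- aggregate(population ~ district_id + year, data = inp2$grid, sum)
  de2 <- merge(pm2, pop2, by = c("district_id", "year"))
  ed2 <- expected_deaths(cfg2, de2, inp2$covariates, inp2$truth,
                         inp2$hierarchy)
  n_rep <- 400L
  draws <- sapply(seq_len(n_rep), function(s) {
    c2 <- cfg2
    c2$seed <- 10000L + s
    simulate_mortality(c2, de2, inp2$covariates, inp2$truth,
                       inp2$hierarchy)$deaths_true
  })
  mean_draw <- rowMeans(draws)
  se_draw <- sqrt(cfg2$dispersion_phi * ed2$lambda / n_rep)
  expect_true(all(abs(mean_draw - ed2$lambda) < 4 * se_draw))

  # method-of-moments dispersion recovery across phi values
  for (phi in c(1, 2, 5)) {
    c3 <- cfg2
    c3$dispersion_phi <- phi
    draws3 <- sapply(seq_len(n_rep), function(s) {
      c4 <- c3
      c4$seed <- 20000L + s
      simulate_mortality(c4, de2, inp2$covariates, inp2$truth,
                         inp2$hierarchy)$deaths_true
    })
    phi_hat <- mean(apply(draws3, 1, var) / rowMeans(draws3))
    expect_lt(abs(phi_hat - phi) / phi, 0.10)
  }
})

test_that("doubling populations doubles expected deaths, rates unchanged", {
  pm <- popweighted_district_means(TINY$grid)
  pop <- aggregate(population ~ district_id + year, data = TINY$grid, sum)
  de <- merge(pm, pop, by = c("district_id", "year"))
  ed1 <- expected_deaths(TINY_CFG, de, TINY$covariates, TINY$truth,
                         TINY$hierarchy)
  de2 <- de
  de2$population <- 2 * de2$population
  ed2 <- expected_deaths(TINY_CFG, de2, TINY$covariates, TINY$truth,
                         TINY$hierarchy)
  expect_equal(ed2$lambda, 2 * ed1$lambda, tolerance = 1e-12)
})

test_that("the full dataset is a pure function of the configuration", {
  again <- simulate_panel_inputs(tiny_config())
  expect_identical(again$grid, TINY$grid)
  expect_identical(again$covariates, TINY$covariates)
  expect_identical(again$deaths, TINY$deaths)
  different <- simulate_panel_inputs(tiny_config(seed = 43L))
  expect_false(identical(different$deaths$deaths_true,
                         TINY$deaths$deaths_true))
})
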