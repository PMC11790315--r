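test_that("population weighting follows the weighted-mean definition", {
  g <- data.frame(cell_id = c("a", "b"), district_id = "D1", year = 2010L,
                  pm25_ugm3 = c(30, 50), population = c(100, 300))
  expect_equal(popweighted_district_means(g)$pm25_pw, 45.0)

  g$population <- c(200, 200)
  expect_equal(popweighted_district_means(g)$pm25_pw, 40.0)

  expect_equal(popweighted_district_means(g[1, ])$pm25_pw, 30.0)

  g$population <- c(0, 0)
  expect_error(popweighted_district_means(g), "zero total population")
  expect_equal(popweighted_district_means(g, allow_unweighted = TRUE)$pm25_pw,
               40.0)
})

test_that("aggregation is bounded by cell extremes and invariant to weight scale", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    g <- data.frame(cell_id = paste0("c", 1:n), district_id = "D1",
                    year = 2010L, pm25_ugm3 = runif(n, 5, 120),
                    population = runif(n, 1, 1e5))
    pw <- popweighted_district_means(g)$pm25_pw
    expect_gte(pw, min(g$pm25_ugm3))
    expect_lte(pw, max(g$pm25_ugm3))
    g2 <- g
    g2$population <- g2$population * 7.3
    expect_equal(popweighted_district_means(g2)$pm25_pw, pw,
                 tolerance = 1e-12)
  }
})

test_that("anchor-year interpolation is linear inside, flat outside", {
  s <- data.frame(unit_id = "D1", year = c(2010L, 2015L), value = c(10, 20))
  out <- interpolate_anchor_years(s, 2009:2016)
  expect_equal(out$value[out$year == 2012], 14.0)
  expect_equal(out$value[out$year == 2010], 10.0)  # passes through anchors
  expect_equal(out$value[out$year == 2015], 20.0)
  expect_equal(out$value[out$year == 2009], 10.0)  # flat extrapolation
  expect_equal(out$value[out$year == 2016], 20.0)

  single <- data.frame(unit_id = "D1", year = 2011L, value = 7.2)
  out1 <- interpolate_anchor_years(single, 2009:2019)
  expect_true(all(out1$value == 7.2))

  empty <- data.frame(unit_id = "D9", year = 2011L, value = NA_real_)
  expect_error(interpolate_anchor_years(empty, 2009:2019, variable = "gdp"),
               "gdp.*D9")
})

test_that("state series broadcast verbatim with no cross-contamination", {
  h <- data.frame(district_id = c("D1", "D2", "D3"),
                  division_id = c("V1", "V1", "V2"),
                  state_id = c("A", "A", "B"))
  s <- data.frame(unit_id = c("A", "B"), year = 2010L, value = c(27, 31))
  out <- broadcast_state_to_district(s, h)
  expect_equal(out$value[out$unit_id == "D1"], 27)
  expect_equal(out$value[out$unit_id == "D2"], 27)
  expect_equal(out$value[out$unit_id == "D3"], 31)

  expect_error(
    broadcast_state_to_district(s[s$unit_id == "A", ], h), "B")
})

test_that("quarterly temperature statistics use seasonal blocks and sample SD", {
  m <- expand.grid(district_id = "D1", year = 2010L, month = 1:12,
                   stringsAsFactors = FALSE)
  m$temp <- 0
  m$temp[m$month %in% c(12, 1, 2)] <- c(10, 20, 30)  # months 1, 2, 12
  qt <- quarterly_temperature_stats(m)
  expect_equal(qt$temp_q1, 20)
  expect_equal(qt$temp_sd_q1, 10)
  expect_equal(qt$temp_sd_q2, 0)   # constant months
  expect_equal(ncol(qt), 10L)

  m2 <- m
  m2$temp <- seq_len(12)
  qt2 <- quarterly_temperature_stats(m2)
  expect_true(all(is.finite(as.matrix(qt2[, -(1:2)]))))

  expect_error(quarterly_temperature_stats(m[m$month != 7, ]),
               "12 monthly")
})

test_that("December convention switch moves December across years", {
  m <- expand.grid(district_id = "D1", year = c(2010L, 2011L), month = 1:12,
                   stringsAsFactors = FALSE)
  m$temp <- ifelse(m$month == 12 & m$year == 2010, 99, 10)
  qt <- quarterly_temperature_stats(m, december_from = "previous_year")
  # 2010's December lands in 2011's winter quarter; 2010 drops out
  # (incomplete: no December available for it)
  expect_equal(qt$year, 2011L)
  expect_equal(qt$temp_q1, mean(c(10, 10, 99)))
})

test_that("lag columns shift exposure by one year and average two", {
  pm <- data.frame(district_id = "D1", year = c(2008L, 2009L, 2010L),
                   pm25_pw = c(40, 50, 60))
  out <- attach_lags(pm)
  expect_equal(out$year, c(2009L, 2010L))  # first year excluded
  expect_equal(out$pm25_lag1, c(40, 50))
  expect_equal(out$pm25_lag01, c(45, 55))

  flat <- data.frame(district_id = "D1", year = 2008:2012, pm25_pw = 33)
  outf <- attach_lags(flat)
  expect_true(all(outf$pm25_lag1 == 33 & outf$pm25_lag01 == 33))

  gap <- pm[-1, ]
  expect_error(attach_lags(gap, target_years = c(2009L, 2010L)),
               "missing prior-year")
})

test_that("harmonised panel is balanced, complete, and consistent with cells", {
  expect_silent(validate_panel(TINY_PANEL))
  n_d <- length(unique(TINY_PANEL$district_id))
  n_y <- length(unique(TINY_PANEL$year))
  expect_equal(nrow(TINY_PANEL), n_d * n_y)
  expect_equal(n_y, length(TINY_CFG$years) - 1L)  # pre-study year excluded

  # pm25_pw bounded by cell extremes per district-year
  key_p <- paste(TINY_PANEL$district_id, TINY_PANEL$year)
  key_g <- paste(TINY$grid$district_id, TINY$grid$year)
  lo <- tapply(TINY$grid$pm25_ugm3, key_g, min)[key_p]
  hi <- tapply(TINY$grid$pm25_ugm3, key_g, max)[key_p]
  expect_true(all(TINY_PANEL$pm25_pw >= lo - 1e-9 &
                    TINY_PANEL$pm25_pw <= hi + 1e-9))

  broken <- TINY_PANEL
  broken$population[1] <- 0
  expect_error(validate_panel(broken), "population")
  broken2 <- TINY_PANEL[-1, ]
  expect_error(validate_panel(broken2), "unbalanced")
})
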