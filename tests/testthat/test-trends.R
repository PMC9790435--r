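test_that("regime annual series aggregate burned area correctly", {
  s <- toy_series(matrix(10, 12, 5), cell_area = 200)
  y <- regime_annual_series(s, labels = 1, regime = 1)
  expect_equal(unname(y), rep(120, 5))

  # additivity over disjoint cells
  g <- one_region_grid(2, 1, cell_area = 200)
  s2 <- structure(list(
    grid = g, years = 1:5,
    burned_area = array(rep(c(10, 5), 12 * 5), c(2, 12, 5)),
    fire_count = array(1, c(2, 12, 5)),
    mean_fire_size = array(rep(c(10, 5), 12 * 5), c(2, 12, 5))
  ), class = "fire_series")
  both <- regime_annual_series(s2, labels = c(1, 1), regime = 1)
  expect_equal(unname(both), rep(180, 5))
  expect_error(regime_annual_series(s2, labels = c(1, 1), regime = 2), "empty cell set")
})

test_that("a planted geometric decline appears in the regime series with noise off", {
  arch <- list(regime_archetype(1, pyromes:::seasonal_climatology(10, 8, 5),
    ba_year_cv = 0, fsize_cv = 0, trend = -0.02
  ))
  arc <- simulate_fire_archive(one_region_grid(3, 4), arch,
    years = 10,
    nlsf_fraction = 0, seed = 1
  )
  y <- regime_annual_series(arc$series, arc$truth$cells$regime, 1)
  expect_equal(unname(y / y[1]), 1 - 0.02 * (0:9), tolerance = 1e-10)
})

test_that("OLS trend statistics and relative change match hand arithmetic", {
  y <- 100 - 2 * (0:16)
  tr <- suppressWarnings(ols_trend(y)) # summary.lm warns on a perfect fit
  expect_equal(tr$slope, -2, tolerance = 1e-12)
  expect_equal(tr$relative_change_pct, -32, tolerance = 1e-10)
  expect_true(tr$significant)

  flat <- ols_trend(rep(7, 10))
  expect_equal(flat$slope, 0)
  expect_false(flat$significant)
  expect_true(flat$degenerate)
  expect_error(ols_trend(1:4), "at least 5")
})

test_that("OLS slope significance attains its nominal type-I error on null series", {
  set.seed(11)
  hits <- vapply(seq_len(1000), function(i) {
    ols_trend(stats::rnorm(17))$significant
  }, logical(1))
  expect_lte(abs(mean(hits) - 0.05), 0.02)
})

test_that("antecedent precipitation features sum the correct strictly-preceding windows", {
  p <- rep(100, 24 + 12 * 5)
  attr(p, "lead_months") <- 24L
  f <- lagged_precip_features(p, years = 1:5, anchor_month = 7)
  expect_equal(f$p6, rep(600, 5))
  expect_equal(f$p24, rep(2400, 5))

  # one wet month only inside the 24-month window
  p2 <- rep(0, 24 + 12 * 2)
  p2[10] <- 500 # 21 months before the year-1 anchor: in the 24- but not 6-window
  attr(p2, "lead_months") <- 24L
  f2 <- lagged_precip_features(p2, years = 1, anchor_month = 7)
  expect_equal(f2$p6, 0)
  expect_equal(f2$p24, 500)

  # seasonal sinusoid: matches a brute-force window sum
  p3 <- 50 + 40 * sin(2 * pi * seq_len(24 + 36) / 12)
  attr(p3, "lead_months") <- 24L
  f3 <- lagged_precip_features(p3, years = 1:3, anchor_month = 9)
  for (i in 1:3) {
    idx <- 24 + (i - 1) * 12 + 9
    expect_equal(f3$p6[i], sum(p3[(idx - 6):(idx - 1)]), tolerance = 1e-12)
    expect_equal(f3$p24[i], sum(p3[(idx - 24):(idx - 1)]), tolerance = 1e-12)
  }

  expect_error(
    lagged_precip_features(rep(1, 30), years = 1, anchor_month = 1),
    "insufficient history"
  )
})

test_that("decoupled trend reduces to OLS when precipitation is constant, and matches a normal-equations oracle", {
  set.seed(12)
  y <- 5 + 0.3 * (0:11) + stats::rnorm(12, sd = 0.2)
  expect_warning(tr <- decoupled_trend(y, rep(600, 12), rep(2400, 12)), "constant")
  tr0 <- ols_trend(y)
  expect_equal(tr$slope, tr0$slope, tolerance = 1e-12)
  expect_equal(tr$t_value, tr0$t_value, tolerance = 1e-12)

  p6 <- stats::runif(12, 400, 800)
  p24 <- stats::runif(12, 1800, 2600)
  y2 <- 2 + 0.1 * (0:11) + 0.01 * p6 - 0.002 * p24 + stats::rnorm(12, sd = 0.1)
  tr2 <- decoupled_trend(y2, p6, p24)
  or <- lm_oracle(y2, cbind(0:11, p6, p24))
  expect_equal(tr2$slope, or$coef[2], tolerance = 1e-8)
  expect_equal(tr2$t_value, or$t[2], tolerance = 1e-8)
  expect_equal(tr2$p_value, or$p[2], tolerance = 1e-8)
  expect_equal(tr2$coef_p6, or$coef[3], tolerance = 1e-8)
})

test_that("precipitation-driven burned area does not trigger anthropogenic flags beyond alpha", {
  set.seed(13)
  n_cells <- 300
  years <- 15
  hits <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    p6 <- stats::runif(years, 300, 900)
    p24 <- stats::runif(years, 1500, 3000)
    y <- 0.5 * p6 + 0.1 * p24 + stats::rnorm(years, sd = 20)
    hits[i] <- decoupled_trend(y, p6, p24)$significant
  }
  expect_lte(abs(mean(hits) - 0.05), 0.02)
})

test_that("a trending-precipitation confounder is absorbed by the precipitation terms", {
  set.seed(14)
  years <- 15
  flag_dec <- flag_ols <- logical(200)
  for (i in 1:200) {
    p6 <- 600 + 15 * (0:(years - 1)) + stats::rnorm(years, sd = 30)
    p24 <- 4 * p6 + stats::rnorm(years, sd = 60)
    y <- 0.2 * p6 + 0.05 * p24 + stats::rnorm(years, sd = 5)
    flag_dec[i] <- decoupled_trend(y, p6, p24)$significant
    flag_ols[i] <- ols_trend(y)$significant
  }
  expect_lte(mean(flag_dec), 0.10) # near the nominal rate
  expect_gte(mean(flag_ols), 0.9) # the naive trend would be called significant
})

test_that("the regime-by-region trend table recovers planted relative declines", {
  arch <- list(
    regime_archetype(1, pyromes:::seasonal_climatology(8, 8, 3),
      ba_year_cv = 0.05, trend = 0
    ),
    regime_archetype(2, pyromes:::seasonal_climatology(30, 7, 7),
      ba_year_cv = 0.05, trend = -0.025
    )
  )
  g <- grid_spec(10, 20, region_fractions = c(focal = 0.5, continental = 0.5, other = 0))
  arc <- simulate_fire_archive(g, arch, years = 17, nlsf_fraction = 0, seed = 3)
  tab <- regime_trend_table(arc$series, arc$truth$cells$regime, g$region)
  r2 <- tab[tab$regime == 2, ]
  expect_true(all(r2$significant))
  # planted -2.5 %/yr over 17 years: about -40 % relative change
  expect_equal(mean(r2$relative_change_pct), -40, tolerance = 6)
  expect_true(all(abs(tab$relative_change_pct[tab$regime == 1]) < 15))
})
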