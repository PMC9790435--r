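test_that("generator validates its inputs", {
  g <- one_region_grid(3, 4)
  arch <- default_archetypes(2)
  expect_error(simulate_fire_archive(g, list(), years = 5), "empty archetype")
  expect_error(simulate_fire_archive(g, arch, years = 0), "non-positive years")
  expect_error(simulate_fire_archive(g, arch, years = 2), "at least 3")
  expect_error(simulate_fire_archive(g, arch, years = 5, nlsf_fraction = 1), "nlsf_fraction")
  expect_error(
    simulate_fire_archive(g, c(arch, arch[1]), years = 5),
    "distinct"
  )
})

test_that("an all-zero climatology archetype yields NLSF-equivalent cells", {
  g <- one_region_grid(4, 5)
  arch <- list(regime_archetype(1, rep(0, 12)))
  arc <- simulate_fire_archive(g, arch, years = 5, nlsf_fraction = 0, seed = 1)
  expect_true(all(arc$series$burned_area == 0))
  expect_true(all(assign_nlsf(arc$series)))
})

test_that("with noise off, per-cell monthly climatologies equal the archetype tables", {
  clim_a <- c(2, 3, 2, rep(0, 9)) # fire only in months 1-3
  clim_b <- c(rep(0, 6), 3, 5, 3, rep(0, 3)) # only months 7-9
  arch <- list(
    regime_archetype(1, clim_a, ba_year_cv = 0, fsize_cv = 0, mean_fire_size = 0.5),
    regime_archetype(2, clim_b, ba_year_cv = 0, fsize_cv = 0, mean_fire_size = 0.5)
  )
  g <- one_region_grid(5, 8)
  arc <- simulate_fire_archive(g, arch, years = 4, nlsf_fraction = 0, seed = 3)
  clim <- rowMeans(arc$series$burned_area, dims = 2L)
  truth <- arc$truth$cells$regime
  for (i in which(truth == 1)) expect_equal(unname(clim[i, ]), clim_a)
  for (i in which(truth == 2)) expect_equal(unname(clim[i, ]), clim_b)
})

test_that("realized interannual CV matches the archetype target", {
  # 200 cells, 2 archetypes, CV target 0.3, 14 years
  arch <- list(
    regime_archetype(1, pyromes:::seasonal_climatology(6, 9, 3), ba_year_cv = 0.3),
    regime_archetype(2, pyromes:::seasonal_climatology(20, 7, 7), ba_year_cv = 0.3)
  )
  g <- one_region_grid(10, 20)
  arc <- simulate_fire_archive(g, arch, years = 14, nlsf_fraction = 0, seed = 1)
  ba_year <- pyromes:::sum_months(arc$series$burned_area)
  realized <- apply(ba_year, 1L, cv)
  for (r in 1:2) {
    expect_lte(abs(mean(realized[arc$truth$cells$regime == r]) - 0.3), 0.1)
  }
})

test_that("identical configuration and seed regenerate bit-identical data", {
  g <- grid_spec(6, 9)
  a <- simulate_tropics(g, years = 4, seed = 123)
  b <- simulate_tropics(g, years = 4, seed = 123)
  expect_identical(a$series, b$series)
  expect_identical(a$env, b$env)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_tropics(g, years = 4, seed = 124)
  expect_false(identical(a$series$burned_area, c_$series$burned_area))
})

test_that("regions occupy contiguous column blocks and NLSF cells never burn", {
  g <- grid_spec(4, 10)
  blocks <- tapply(g$col, g$region, function(cc) all(diff(sort(unique(cc))) == 1))
  expect_true(all(blocks))

  arc <- simulate_fire_archive(g, default_archetypes(),
    years = 4,
    nlsf_fraction = 0.25, seed = 2
  )
  nlsf <- arc$truth$cells$regime == 0
  expect_equal(sum(nlsf), floor(0.25 * nrow(g)))
  expect_true(all(arc$series$burned_area[nlsf, , ] == 0))
  expect_true(all(arc$series$burned_area <= attr(g, "cell_area") + 1e-12))
})

test_that("planted regimes separate in characteristic space (silhouette > 0.5)", {
  # >= 3x climatology gaps, noise CVs <= 0.3
  arch <- lapply(1:3, function(i) {
    regime_archetype(i, pyromes:::seasonal_climatology(3 * 3^i, 8, 2 * i + 1),
      ba_year_cv = 0.3, mean_fire_size = 0.4 * i
    )
  })
  arc <- simulate_fire_archive(one_region_grid(10, 15), arch,
    years = 14,
    nlsf_fraction = 0, seed = 4
  )
  ch <- fire_characteristics(arc$series)
  nm <- normalise_characteristics(ch)
  m <- as.matrix(nm$table[, pyromes:::CHAR_COLS])
  sil <- cluster::silhouette(arc$truth$cells$regime, stats::dist(m))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("forest cells satisfy the NDVI thresholds by construction", {
  g <- grid_spec(10, 20)
  tr <- simulate_tropics(g, years = 6, seed = 11)
  stats <- ndvi_statistics(tr$env$ndvi)
  forest <- tr$truth$cells$veg_class == "forest"
  expect_true(any(forest))
  expect_true(all(stats$mean_ndvi[forest] > 0.80))
  expect_true(all(stats$annual_cv[forest] < 0.08))
})

test_that("a null anomaly field is recovered as ratio 1 and a planted 4x anomaly as 4", {
  g <- one_region_grid(25, 20) # 500 cells
  arc <- simulate_fire_archive(g, default_archetypes(),
    years = 4,
    nlsf_fraction = 0.1, seed = 6
  )
  env <- simulate_environment(g, arc$truth, years = 4, seed = 6)
  truth <- arc$truth$cells
  frac <- tree_loss_fraction(env$tree_cover, env$tree_loss)
  sub <- truth$regime == 3
  expect_equal(
    anomaly_ratio(tree_loss_fraction(env$tree_cover[sub], env$tree_loss[sub]), frac),
    1.0,
    tolerance = 0.1
  )

  # planted 4x anomaly on one regime x class stratum, ~1000 cells
  g2 <- one_region_grid(80, 80)
  arc2 <- simulate_fire_archive(g2, default_archetypes(),
    years = 4,
    nlsf_fraction = 0.05, seed = 7
  )
  env2 <- simulate_environment(g2, arc2$truth,
    years = 4, seed = 7,
    anomaly = data.frame(regime = 5, veg_class = "grassy", ratio = 4)
  )
  t2 <- arc2$truth$cells
  sub2 <- t2$regime == 5 & t2$veg_class == "grassy"
  expect_gt(sum(sub2), 900)
  rec <- anomaly_ratio(
    tree_loss_fraction(env2$tree_cover[sub2], env2$tree_loss[sub2]),
    tree_loss_fraction(env2$tree_cover, env2$tree_loss)
  )
  expect_equal(rec, 4.0, tolerance = 0.1) # +/- 0.4
})

test_that("an unattainable anomaly plant is rejected", {
  g <- one_region_grid(5, 8)
  arc <- simulate_fire_archive(g, default_archetypes()[3],
    years = 4,
    nlsf_fraction = 0, seed = 8
  )
  expect_error(
    simulate_environment(g, arc$truth,
      years = 4, seed = 8,
      anomaly = data.frame(regime = 3, veg_class = "grassy", ratio = 50)
    ),
    "background rate"
  )
})
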