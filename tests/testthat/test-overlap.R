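test_that("PCA reduction behaves on degenerate, isotropic and centred inputs", {
  # perfectly correlated pair: axis 1 explains everything
  x <- cbind(a = 1:50, b = 1:50 * 2)
  sp <- pca_reduce(x + 0)
  expect_equal(sp$explained[1], 1, tolerance = 1e-12)

  # isotropic Gaussian: each axis about 50%
  set.seed(4)
  iso <- matrix(stats::rnorm(2e4), ncol = 2)
  sp_iso <- pca_reduce(iso)
  expect_equal(sp_iso$explained[1], 0.5, tolerance = 0.03)
  expect_equal(sp_iso$explained[2], 0.5, tolerance = 0.03)

  # a cell at the variable means scores (0, 0)
  m <- matrix(stats::runif(60), 20, 3)
  m <- rbind(m, colMeans(m))
  sp_c <- pca_reduce(m)
  expect_equal(unname(sp_c$scores[21, ]), c(0, 0), tolerance = 1e-10)

  # constant variable dropped with a warning; loadings orthonormal
  mc <- cbind(m, 5)
  expect_warning(sp_d <- pca_reduce(mc), "constant")
  gram <- t(sp_d$loadings) %*% sp_d$loadings
  expect_equal(gram, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(sp_d$explained) <= 1e-12))
})

test_that("occupancy grids normalise binary and density weights as specified", {
  b <- list(x = c(0, 1), y = c(0, 1))
  one <- occupancy_grid(cbind(0.5, 0.5), b, R = 10)
  expect_equal(sum(one$w), 1)
  expect_equal(sum(one$w > 0), 1)

  two_same <- occupancy_grid(rbind(c(0.51, 0.51), c(0.52, 0.52)), b, R = 10)
  expect_equal(sum(two_same$w > 0), 1) # binary collapse
  expect_equal(max(two_same$w), 1)

  two_diff <- occupancy_grid(rbind(c(0.05, 0.05), c(0.95, 0.95)), b, R = 10)
  expect_equal(sort(two_diff$w[two_diff$w > 0]), c(0.5, 0.5))

  expect_error(occupancy_grid(cbind(0.5, 0.5), b, R = 5), "at least 10")
  expect_error(occupancy_grid(cbind(2, 0.5), b, R = 10), "bounds")
  expect_error(occupancy_grid(matrix(0, 0, 2), b, R = 10), "empty")
})

test_that("Schoener's D satisfies its exact identities and symmetry", {
  b <- list(x = c(0, 1), y = c(0, 1))
  set.seed(5)
  pts <- cbind(stats::runif(40), stats::runif(40))
  ga <- occupancy_grid(pts, b, R = 10)
  expect_equal(schoener_d(ga, ga), 1.0)

  gb <- occupancy_grid(cbind(stats::runif(40, 0, 0.45), stats::runif(40, 0, 0.45)), b, R = 10)
  gc <- occupancy_grid(cbind(stats::runif(40, 0.55, 1), stats::runif(40, 0.55, 1)), b, R = 10)
  expect_equal(schoener_d(gb, gc), 0.0)
  expect_equal(schoener_d(gb, gc), schoener_d(gc, gb))

  # hand case: weights (0.5, 0.5, 0, 0) vs (0, 0.5, 0.5, 0) -> 0.5
  pa <- rbind(c(0.05, 0.5), c(0.15, 0.5))
  pb <- rbind(c(0.15, 0.5), c(0.25, 0.5))
  expect_equal(schoener_d(
    occupancy_grid(pa, b, R = 10),
    occupancy_grid(pb, b, R = 10)
  ), 0.5)

  # bounded in [0, 1] over random grids
  for (i in 1:5) {
    g1 <- occupancy_grid(cbind(stats::runif(30), stats::runif(30)), b, R = 15)
    g2 <- occupancy_grid(cbind(stats::runif(30), stats::runif(30)), b, R = 15)
    d <- schoener_d(g1, g2)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }

  g_mode <- occupancy_grid(pts, b, R = 10, mode = "density")
  expect_error(schoener_d(ga, g_mode), "not comparable")
})

test_that("refining the resolution cannot increase binary D for disjoint point sets", {
  b <- list(x = c(0, 1), y = c(0, 1))
  set.seed(6)
  pa <- cbind(stats::runif(100, 0, 0.4), stats::runif(100))
  pb <- cbind(stats::runif(100, 0.6, 1), stats::runif(100))
  ds <- vapply(c(10, 25, 50), function(R) {
    schoener_d(occupancy_grid(pa, b, R = R), occupancy_grid(pb, b, R = R))
  }, numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
})

test_that("regional overlap is high for a shared niche, low for disjoint niches", {
  g <- grid_spec(40, 100, region_fractions = c(focal = 0.5, continental = 0.5, other = 0))
  arch <- default_archetypes()[c(2, 4)]
  arc <- simulate_fire_archive(g, arch, years = 14, nlsf_fraction = 0, seed = 1)
  ch <- fire_characteristics(arc$series)
  nm <- normalise_characteristics(ch)
  sp <- pca_reduce(nm$table[, pyromes:::CHAR_COLS])
  truth <- arc$truth$cells$regime
  reg <- as.character(g$region)

  # same planted archetype in both regions: shared niche
  for (r in c(2, 4)) {
    d <- regional_overlap(sp, truth, reg, r, "focal", "continental", R = 15)
    expect_gte(d, 0.8)
  }

  # disjoint niches: pretend the two regimes are one regime in different regions
  fake_label <- rep(9, nrow(ch))
  fake_region <- ifelse(truth == 2, "focal", "continental")
  d_disj <- regional_overlap(sp$scores, fake_label, fake_region, 9,
    "focal", "continental",
    R = 100
  )
  expect_lte(d_disj, 0.05)

  # a region compared with itself: D = 1
  d_self <- regional_overlap(sp, truth, reg, 2, "focal", "focal", R = 25)
  expect_equal(d_self, 1.0)

  # absent regime: missing, not zero
  expect_true(is.na(regional_overlap(sp, truth, reg, 5, "focal", "continental")))
})

test_that("regime proportions sum to one over classified burned cells per region", {
  labels <- c(1, 1, 2, -1, 0, 2, 2)
  regions <- c("focal", "focal", "focal", "focal", "other", "other", "other")
  pr <- regime_proportions(labels, regions)
  focal_p <- pr$proportion[pr$region == "focal" & pr$regime > 0]
  expect_equal(sum(focal_p, na.rm = TRUE), 1)
  expect_equal(pr$proportion[pr$region == "focal" & pr$regime == 1], 2 / 3)
})
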