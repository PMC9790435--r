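# Synthetic tropics generator: a small lattice of cells split into three
# contiguous regions (a focal island, a continental block, and the remaining
# tropics), with planted fire-regime archetypes, NLSF cells, precipitation-
# coupled burned area with optional linear anthropogenic trends, NDVI cycles
# by vegetation class, and planted tree-loss anomaly ratios. Every dataset is
# exactly regenerable from its configuration and seed.

#' Define a synthetic grid
#'
#' Builds a rectangular lattice of cells with row-major 0-origin-free ids and
#' a region label per cell. Regions are assigned in contiguous column blocks
#' (not interleaved), so regional summaries carry spatial autocorrelation
#' rather than an i.i.d. layout.
#'
#' @param n_rows,n_cols Lattice dimensions (at least 1).
#' @param cell_area Cell area in km^2 (default 21, roughly a 2.5 arc-minute
#'   tropical cell).
#' @param region_fractions Named proportions of columns given to the
#'   `focal`, `continental` and `other` regions; must sum to 1.
#' @return A data frame of class `grid_spec` with columns `cell_id`, `row`,
#'   `col`, `region`, and a `cell_area` attribute.
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 21,
                      region_fractions = c(focal = 0.2, continental = 0.4, other = 0.4)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_area > 0)
  if (!all(REGION_LEVELS %in% names(region_fractions))) {
    stop("region_fractions must name focal, continental and other")
  }
  region_fractions <- region_fractions[REGION_LEVELS]
  if (abs(sum(region_fractions) - 1) > 1e-8) stop("region_fractions must sum to 1")
  cuts <- round(cumsum(region_fractions) * n_cols)
  cuts[3] <- n_cols
  col_region <- rep(REGION_LEVELS, times = diff(c(0, cuts)))
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  g <- g[order(g$row, g$col), , drop = FALSE]
  g <- data.frame(
    cell_id = seq_len(n_rows * n_cols),
    row = g$row, col = g$col,
    region = factor(col_region[g$col], levels = REGION_LEVELS)
  )
  attr(g, "cell_area") <- cell_area
  class(g) <- c("grid_spec", "data.frame")
  g
}

#' Fire-regime archetype
#'
#' The generative parameters of one planted fire regime: a 12-value monthly
#' burned-area climatology (km^2 per cell), interannual noise targets,
#' a characteristic mean fire size, linear coupling coefficients to the
#' antecedent 6- and 24-month precipitation sums, an anthropogenic trend
#' (fraction of the baseline per year), the regions in which the regime
#' occurs, and vegetation-class weights for cells of the regime.
#'
#' @param label Positive integer regime label; labels must be distinct within
#'   one archetype set.
#' @param climatology Numeric vector of 12 non-negative monthly burned-area
#'   means (km^2).
#' @param ba_year_cv Target interannual coefficient of variation of annual
#'   burned area (bounded mean-1 multiplier).
#' @param fsize_cv Target year-to-year coefficient of variation of fire size.
#' @param cv_shared_frac Fraction of the interannual variance shared by all
#'   cells of the regime (regionally coherent fire years driven by common
#'   climate), the remainder being cell-level noise. Near 1 means burned
#'   area in all cells of a regime rises and falls together.
#' @param mean_fire_size Mean individual fire size (km^2).
#' @param beta6,beta24 Linear coefficients (km^2 burned per mm) on the
#'   centred antecedent 6-month (drought) and 24-month (fuel build-up)
#'   precipitation sums.
#' @param trend Linear anthropogenic trend as a fraction of the baseline
#'   annual burned area per year (e.g. -0.025 for a 2.5 %/yr decline).
#' @param regions Regions in which the archetype occurs.
#' @param veg_weights Named sampling weights over `forest`, `grassy`, `other`
#'   for the planted vegetation class of the regime's cells.
#' @param weight Relative abundance weight when assigning cells to regimes.
#' @return A list of class `regime_archetype`.
#' @export
regime_archetype <- function(label, climatology, ba_year_cv = 0.3, fsize_cv = 0.2,
                             mean_fire_size = 0.6, beta6 = 0, beta24 = 0,
                             trend = 0, cv_shared_frac = 0.97,
                             regions = REGION_LEVELS,
                             veg_weights = c(forest = 0.2, grassy = 0.7, other = 0.1),
                             weight = 1) {
  stopifnot(length(climatology) == 12L, all(climatology >= 0),
            ba_year_cv >= 0, fsize_cv >= 0, mean_fire_size > 0,
            cv_shared_frac >= 0, cv_shared_frac <= 1,
            label == as.integer(label), label >= 1)
  regions <- match.arg(regions, REGION_LEVELS, several.ok = TRUE)
  stopifnot(all(c("forest", "grassy", "other") %in% names(veg_weights)))
  structure(list(
    label = as.integer(label), climatology = as.numeric(climatology),
    ba_year_cv = ba_year_cv, fsize_cv = fsize_cv,
    mean_fire_size = mean_fire_size, beta6 = beta6, beta24 = beta24,
    trend = trend, cv_shared_frac = cv_shared_frac, regions = regions,
    veg_weights = veg_weights[c("forest", "grassy", "other")], weight = weight
  ), class = "regime_archetype")
}

# Mean-1 bounded random multipliers with a given CV: 2 * Beta(a, a) has
# support [0, 2], mean 1 and CV 1/sqrt(2a + 1). Bounded (rather than
# lognormal) interannual noise keeps realized CV estimates light-tailed, as
# multi-year satellite burned-area records are.
rmult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  if (cv >= 1) stop("multiplier cv must be below 1")
  a <- (1 / cv^2 - 1) / 2
  2 * stats::rbeta(n, a, a)
}

# Unimodal seasonal climatology: `total` km^2/yr spread over `width` months
# around `peak` with cosine tapering.
seasonal_climatology <- function(total, peak, width) {
  m <- 1:12
  d <- pmin(abs(m - peak), 12 - abs(m - peak))
  w <- ifelse(d <= width / 2, cos(pi * d / (width + 1)), 0)
  w <- pmax(w, 0)
  total * w / sum(w)
}

#' Default regime archetypes
#'
#' Five archetypes spanning the low-variable / medium-variable / high-stable
#' contrast: total burned area increases roughly threefold between
#' consecutive regimes, the burning season lengthens, interannual variability
#' decreases (the highest-fire regime is the most stable), and vegetation
#' shifts from forest-associated to grassy. Regimes 3-5 carry declining
#' anthropogenic trends of 2-3 % of baseline per year; regimes 1-2 carry
#' none.
#'
#' @param k Number of archetypes (2 to 5).
#' @return A list of [regime_archetype] objects.
#' @export
default_archetypes <- function(k = 5) {
  stopifnot(k >= 2, k <= 5)
  totals <- c(2.5, 6, 14, 30, 60)
  widths <- c(1, 3, 6, 9, 11)
  peaks <- c(9, 9, 8, 8, 7)
  cvs <- c(0.30, 0.24, 0.19, 0.14, 0.10)
  fcvs <- c(0.25, 0.20, 0.16, 0.12, 0.08)
  sizes <- c(0.3, 0.55, 0.8, 1.05, 1.3)
  trends <- c(0, 0, -0.022, -0.025, -0.028)
  veg <- list(
    c(forest = 0.6, grassy = 0.3, other = 0.1),
    c(forest = 0.4, grassy = 0.5, other = 0.1),
    c(forest = 0.1, grassy = 0.8, other = 0.1),
    c(forest = 0.05, grassy = 0.85, other = 0.1),
    c(forest = 0.02, grassy = 0.93, other = 0.05)
  )
  lapply(seq_len(k), function(i) {
    regime_archetype(
      label = i,
      climatology = seasonal_climatology(totals[i], peaks[i], widths[i]),
      ba_year_cv = cvs[i], fsize_cv = fcvs[i], mean_fire_size = sizes[i],
      beta6 = -0.0004 * totals[i], beta24 = 0.0002 * totals[i],
      trend = trends[i], veg_weights = veg[[i]]
    )
  })
}

#' Simulate monthly precipitation
#'
#' Seasonal sinusoid (wet season opposite the burning season) around a
#' cell-specific annual mean, with lognormal interannual factors and monthly
#' noise. Includes `lead_months` of history before the first fire year so
#' 24-month antecedent sums are defined from the first analysis year onward.
#'
#' @param grid A [grid_spec].
#' @param years Number of fire years.
#' @param lead_months Months of pre-record history (default 24).
#' @param seed RNG seed.
#' @param annual_mean Domain-typical annual precipitation (mm).
#' @param annual_trend Linear trend in the interannual factor (fraction/yr),
#'   for confounding experiments.
#' @return A matrix [cell x month] with attributes `lead_months` and `years`.
#' @export
simulate_precipitation <- function(grid, years, lead_months = 24, seed = 1,
                                   annual_mean = 1200, annual_trend = 0) {
  n <- nrow(grid)
  n_months <- lead_months + 12L * years
  with_seed(seed, {
    cell_mean <- annual_mean * exp(stats::rnorm(n, 0, 0.25))
    # calendar month of each column, counting back from the first fire year
    cal <- ((seq_len(n_months) - 1L - lead_months) %% 12L) + 1L
    season <- 1 + 0.8 * cos(2 * pi * (cal - 1) / 12) # wet season peaks in Jan
    yr_index <- floor((seq_len(n_months) - 1L - lead_months) / 12)
    yr_levels <- sort(unique(yr_index))
    yfac <- exp(stats::rnorm(n * length(yr_levels), 0, 0.12))
    yfac <- matrix(yfac, n, length(yr_levels))
    yfac <- yfac * (1 + annual_trend * rep(yr_levels - min(yr_levels), each = n))
    p <- matrix(0, n, n_months)
    for (j in seq_len(n_months)) {
      yi <- match(yr_index[j], yr_levels)
      base <- cell_mean / 12 * season[j] * yfac[, yi]
      p[, j] <- pmax(0, base * exp(stats::rnorm(n, -0.005, 0.1)))
    }
    attr(p, "lead_months") <- lead_months
    attr(p, "years") <- years
    p
  })
}

#' Simulate a gridded fire archive with planted regimes
#'
#' Assigns each cell a planted regime (or NLSF status), then draws monthly
#' burned area from the regime's climatology with bounded mean-1 interannual
#' multipliers hitting the target CV, an optional linear anthropogenic trend,
#' and linear coupling to centred antecedent 6-/24-month precipitation sums.
#' Monthly burned area is decomposed into fire events of equal size within a
#' cell-month, so burned area equals fire count times mean fire size exactly;
#' events below the landscape-scale detection floor (`event_floor`, 0.21 km^2)
#' are dropped before aggregation, and months whose total burned area falls
#' below the floor record no fire. Burned area never exceeds the cell area.
#'
#' @param grid A [grid_spec].
#' @param archetypes List of [regime_archetype]s with distinct labels.
#' @param years Number of years (at least 3).
#' @param nlsf_fraction Fraction of cells forced to zero burned area (NLSF).
#' @param seed RNG seed; identical inputs and seed give identical output.
#' @param precip Optional precipitation matrix from
#'   [simulate_precipitation()]; simulated internally when NULL and any
#'   archetype couples to precipitation.
#' @param event_floor Minimum detectable fire size (km^2).
#' @param nlsf_veg_weights Vegetation-class weights for NLSF cells.
#' @return A list with `series` (a `fire_series`: arrays
#'   [cell x 12 x year] of `burned_area`, `fire_count`, `mean_fire_size`),
#'   `truth` (a `tropics_truth` with planted per-cell labels, trends,
#'   vegetation classes, anchor months and the seed), and `precip`.
#' @export
simulate_fire_archive <- function(grid, archetypes, years = 14, nlsf_fraction = 0.15,
                                  seed = 1, precip = NULL, event_floor = 0.21,
                                  nlsf_veg_weights = c(forest = 0.5, grassy = 0.3, other = 0.2)) {
  if (length(archetypes) == 0L) stop("empty archetype list")
  if (!is.numeric(years) || years <= 0) stop("non-positive years")
  if (years < 3) stop("years must be at least 3")
  if (nlsf_fraction < 0 || nlsf_fraction >= 1) stop("nlsf_fraction must be in [0, 1)")
  labels <- vapply(archetypes, function(a) a$label, integer(1))
  if (anyDuplicated(labels)) stop("archetype labels must be distinct")
  n <- nrow(grid)
  cell_area <- attr(grid, "cell_area")
  Y <- as.integer(years)

  if (is.null(precip)) {
    precip <- simulate_precipitation(grid, Y, seed = child_seed(seed, 1L))
  }
  lead <- attr(precip, "lead_months")
  if (is.null(lead) || ncol(precip) < lead + 12L * Y) {
    stop("precip must cover lead_months plus 12 * years columns")
  }
  pc <- t(apply(precip, 1L, cumsum)) # cumulative for fast window sums

  with_seed(seed, {
    # --- planted labels: per region, sample among eligible archetypes
    regime <- integer(n)
    for (r in REGION_LEVELS) {
      idx <- which(grid$region == r)
      if (!length(idx)) next
      elig <- which(vapply(archetypes, function(a) r %in% a$regions, logical(1)))
      if (!length(elig)) stop("no archetype eligible for region ", r)
      w <- vapply(archetypes[elig], function(a) a$weight, numeric(1))
      # exact proportional allocation (largest remainder), randomly placed:
      # regime abundances are part of the planted design, not sampling noise
      quota <- length(idx) * w / sum(w)
      n_each <- floor(quota)
      rem <- length(idx) - sum(n_each)
      if (rem > 0) {
        top_up <- order(quota - n_each, decreasing = TRUE)[seq_len(rem)]
        n_each[top_up] <- n_each[top_up] + 1L
      }
      regime[sample(idx)] <- rep(labels[elig], times = n_each)
    }
    n_nlsf <- floor(nlsf_fraction * n)
    if (n_nlsf > 0) regime[sample.int(n, n_nlsf)] <- 0L

    # --- vegetation class
    veg <- character(n)
    veg_levels <- c("forest", "grassy", "other")
    for (a in archetypes) {
      idx <- which(regime == a$label)
      if (length(idx)) {
        veg[idx] <- veg_levels[sample.int(3L, length(idx),
          replace = TRUE, prob = a$veg_weights
        )]
      }
    }
    idx0 <- which(regime == 0L)
    if (length(idx0)) {
      veg[idx0] <- veg_levels[sample.int(3L, length(idx0),
        replace = TRUE, prob = nlsf_veg_weights[veg_levels]
      )]
    }

    ba <- array(0, c(n, 12L, Y))
    nf <- array(0, c(n, 12L, Y))
    fs <- array(0, c(n, 12L, Y))
    trend_cell <- numeric(n)
    anchor_cell <- integer(n)

    for (a in archetypes) {
      cells <- which(regime == a$label)
      if (!length(cells)) next
      A0 <- sum(a$climatology)
      trend_cell[cells] <- a$trend
      anchor <- if (A0 > 0) which.max(a$climatology) else 1L
      anchor_cell[cells] <- anchor
      if (A0 == 0) next # all-zero climatology: NLSF-equivalent series
      share <- a$climatology / A0
      nc <- length(cells)

      # regionally coherent fire years: a shared year factor for the regime
      # times a smaller cell-level factor, variance split by cv_shared_frac
      f <- a$cv_shared_frac
      S_ba <- rmult(Y, sqrt(f) * a$ba_year_cv)
      L <- matrix(rmult(nc * Y, sqrt(1 - f) * a$ba_year_cv), nc, Y)
      L <- sweep(L, 2L, S_ba, `*`)
      Tfac <- pmax(0, 1 + a$trend * (seq_len(Y) - 1))

      # antecedent precipitation sums at the climatological peak month
      P6 <- P24 <- matrix(0, nc, Y)
      for (y in seq_len(Y)) {
        j <- lead + (y - 1L) * 12L + anchor # column of the anchor month
        P6[, y] <- pc[cells, j - 1L] - pc[cells, j - 7L]
        P24[, y] <- pc[cells, j - 1L] - pc[cells, j - 25L]
      }
      C <- a$beta6 * (P6 - rowMeans(P6)) + a$beta24 * (P24 - rowMeans(P24))
      A <- pmax(A0 * sweep(L, 2L, Tfac, `*`) + C, 0) # annual burned area

      S_fs <- rmult(Y, sqrt(f) * a$fsize_cv)
      for (y in seq_len(Y)) {
        bam <- A[, y] %o% share # [cells x 12]
        bam <- pmin(bam, cell_area)
        bam[bam < event_floor] <- 0 # no detectable event this month
        sz <- a$mean_fire_size * S_fs[y] *
          matrix(rmult(nc * 12L, sqrt(1 - f) * a$fsize_cv), nc, 12L)
        cnt <- ifelse(bam > 0,
          pmax(1, pmin(round(bam / sz), floor(bam / event_floor))), 0
        )
        ba[cells, , y] <- bam
        nf[cells, , y] <- cnt
        fs[cells, , y] <- ifelse(cnt > 0, bam / cnt, 0)
      }
    }

    series <- structure(list(
      grid = grid, years = seq_len(Y),
      burned_area = ba, fire_count = nf, mean_fire_size = fs,
      event_floor = event_floor
    ), class = "fire_series")
    truth <- structure(list(
      cells = data.frame(
        cell_id = grid$cell_id, region = grid$region, regime = regime,
        trend = trend_cell, veg_class = veg,
        anchor_month = anchor_cell
      ),
      archetypes = archetypes, seed = seed, years = Y
    ), class = "tropics_truth")
    list(series = series, truth = truth, precip = precip)
  })
}

#' Expand a fire series into event records
#'
#' Returns the individual fire events underlying a synthetic [fire_series]:
#' within a cell-month the generator burns `fire_count` events of equal size,
#' so the monthly aggregates satisfy burned area = count x mean size exactly.
#'
#' @param series A `fire_series`.
#' @return Data frame with columns `cell_id`, `year`, `month`, `size`.
#' @export
fire_events <- function(series) {
  stopifnot(inherits(series, "fire_series"))
  idx <- which(series$fire_count > 0, arr.ind = TRUE)
  cnt <- series$fire_count[idx]
  data.frame(
    cell_id = rep(series$grid$cell_id[idx[, 1L]], cnt),
    year = rep(series$years[idx[, 3L]], cnt),
    month = rep(idx[, 2L], cnt),
    size = rep(series$mean_fire_size[idx], cnt)
  )
}

#' Simulate the environmental bundle for a synthetic tropics
#'
#' Generates, for the planted truth of [simulate_fire_archive()]: monthly
#' NDVI series (high-stable for forest cells, seasonal open-variable for
#' grassy cells, sparse for other), four climate summaries per cell,
#' population density, baseline tree-cover fraction, and tree-loss fraction
#' with planted anomaly ratios by regime x vegetation class.
#'
#' Planted anomaly ratios are ratios *to the all-domain baseline*: cells in
#' a stratum listed in `anomaly` lose trees at `ratio` times the base rate,
#' and all remaining cells form a background stratum whose rate is solved so
#' that the cover-weighted domain mean rate equals the base rate exactly.
#' This makes the planted ratios recoverable as subset / baseline ratios.
#'
#' @param grid A [grid_spec].
#' @param truth A `tropics_truth` (must carry `regime` and `veg_class`).
#' @param years Number of NDVI years.
#' @param seed RNG seed.
#' @param anomaly Optional data frame (`regime`, `veg_class`, `ratio`) of
#'   planted tree-loss anomaly strata; NULL plants ratio 1 everywhere.
#' @param precip Optional precipitation matrix to embed (else simulated).
#' @param base_loss_rate All-domain expected tree-loss fraction.
#' @return A list of class `tropics_env`: `ndvi` [cell x 12 x year],
#'   `climate` (data frame of the four summaries), `precip`, `population`,
#'   `tree_cover`, `tree_loss`, `veg_class_true`, and `anomaly_achieved`.
#' @export
simulate_environment <- function(grid, truth, years = 14, seed = 1, anomaly = NULL,
                                 precip = NULL, base_loss_rate = 0.05) {
  stopifnot(inherits(truth, "tropics_truth"))
  cells <- truth$cells
  need <- c("cell_id", "regime", "veg_class")
  if (!all(need %in% names(cells))) {
    stop("truth is missing fields: ", paste(setdiff(need, names(cells)), collapse = ", "))
  }
  n <- nrow(grid)
  stopifnot(nrow(cells) == n)
  Y <- as.integer(years)
  veg <- cells$veg_class
  regime <- cells$regime

  if (is.null(precip)) {
    precip <- simulate_precipitation(grid, Y, seed = child_seed(seed, 11L))
  }

  with_seed(seed, {
    # --- NDVI: forest high-stable, grassy seasonal, other sparse
    ndvi <- array(0, c(n, 12L, Y))
    mean_i <- numeric(n)
    amp_i <- numeric(n)
    yr_sd <- numeric(n)
    f <- veg == "forest"; g <- veg == "grassy"; o <- veg == "other"
    mean_i[f] <- stats::runif(sum(f), 0.80, 0.92)
    amp_i[f] <- 0.02
    yr_sd[f] <- 0.012
    mean_i[g] <- stats::runif(sum(g), 0.30, 0.55)
    amp_i[g] <- mean_i[g] * stats::runif(sum(g), 0.35, 0.55)
    yr_sd[g] <- 0.05
    mean_i[o] <- stats::runif(sum(o), 0.01, 0.05)
    amp_i[o] <- mean_i[o] * 0.2
    yr_sd[o] <- 0.05
    for (y in seq_len(Y)) {
      yfac <- 1 + stats::rnorm(n, 0, yr_sd)
      for (m in 1:12) {
        v <- mean_i * yfac + amp_i * cos(2 * pi * (m - 2) / 12) +
          stats::rnorm(n, 0, 0.006)
        ndvi[, m, y] <- pmin(pmax(v, 0), 1)
      }
    }

    # --- climate summaries, structured along the regime gradient
    rg <- pmax(regime, 0)
    lead <- attr(precip, "lead_months")
    ap_cols <- lead + seq_len(12L * Y)
    annual_precip <- rowSums(precip[, ap_cols, drop = FALSE]) / Y
    climate <- data.frame(
      annual_mean_temp = 22 + 0.6 * rg + stats::rnorm(n, 0, 0.5),
      temp_seasonality = pmax(0.005, 0.02 + 0.008 * rg + stats::rnorm(n, 0, 0.004)),
      annual_precip = annual_precip,
      precip_seasonality = pmax(0.05, 0.5 + 0.08 * rg + stats::rnorm(n, 0, 0.05))
    )

    # --- population density (persons / km^2)
    pop_factor <- c(forest = 1.2, grassy = 1.0, other = 0.3)[veg]
    population <- stats::rlnorm(n, log(20), 0.8) * pop_factor

    # --- baseline tree cover by vegetation class
    rbeta_mu <- function(k, mu, conc = 30) stats::rbeta(k, mu * conc, (1 - mu) * conc)
    tree_cover <- numeric(n)
    tree_cover[f] <- rbeta_mu(sum(f), 0.72)
    tree_cover[g] <- rbeta_mu(sum(g), 0.20)
    tree_cover[o] <- rbeta_mu(sum(o), 0.05)

    # --- tree loss with planted anomaly ratios (compensating background)
    rate <- rep(NA_real_, n)
    if (!is.null(anomaly)) {
      stopifnot(all(c("regime", "veg_class", "ratio") %in% names(anomaly)),
                all(anomaly$ratio >= 0))
      for (i in seq_len(nrow(anomaly))) {
        sel <- regime == anomaly$regime[i] & veg == anomaly$veg_class[i]
        rate[sel] <- base_loss_rate * anomaly$ratio[i]
      }
    }
    bg <- is.na(rate)
    if (any(bg)) {
      w_total <- sum(tree_cover)
      w_spec <- sum(tree_cover[!bg] * rate[!bg] / base_loss_rate)
      r_bg <- base_loss_rate * (w_total - w_spec) / sum(tree_cover[bg])
      if (r_bg <= 0) {
        stop("planted anomaly ratios too large: compensating background rate is not positive")
      }
      rate[bg] <- r_bg
    }
    noise <- stats::rgamma(n, shape = 60, rate = 60)
    tree_loss <- pmin(tree_cover, tree_cover * rate * noise)

    achieved <- stats::aggregate(
      list(rate = rate),
      by = list(regime = regime, veg_class = veg), FUN = mean
    )
    achieved$ratio <- achieved$rate / base_loss_rate
    achieved$rate <- NULL

    structure(list(
      ndvi = ndvi, climate = climate, precip = precip,
      population = population, tree_cover = tree_cover, tree_loss = tree_loss,
      veg_class_true = veg, base_loss_rate = base_loss_rate,
      anomaly_achieved = achieved
    ), class = "tropics_env")
  })
}

#' Synthetic tropics with a fire regime absent from the focal region
#'
#' Builds a scenario for testing similarity coverage: the default archetypes
#' occur everywhere, plus one "alien" archetype — far outside the focal
#' characteristic ranges (much higher burned area, year-round season, large
#' fires) — restricted to the `other` region, with its sampling weight
#' solved so that the alien regime contributes `alien_share` of the
#' expected total burned area. Projecting focal-fitted regimes over this
#' domain should classify alien cells as dissimilar, giving similarity
#' coverage of about `1 - alien_share`.
#'
#' @param grid A [grid_spec].
#' @param alien_share Target share of expected burned area from the alien
#'   archetype (default 0.10).
#' @param years,nlsf_fraction,seed,... Passed to [simulate_tropics()].
#' @return A `synthetic_tropics`; the alien regime carries label 6.
#' @export
simulate_coverage_scenario <- function(grid, alien_share = 0.10, years = 14,
                                       nlsf_fraction = 0.15, seed = 1, ...) {
  stopifnot(alien_share > 0, alien_share < 1)
  arch <- default_archetypes()
  alien <- regime_archetype(
    label = 6L,
    climatology = seasonal_climatology(180, 7, 12),
    ba_year_cv = 0.08, fsize_cv = 0.08, mean_fire_size = 3,
    regions = "other",
    veg_weights = c(forest = 0.02, grassy = 0.93, other = 0.05)
  )
  # expected per-cell burned area per archetype, including the mean trend
  # factor over the span
  Y <- years
  exp_total <- function(a) sum(a$climatology) * (1 + a$trend * (Y - 1) / 2)
  tbar <- mean(vapply(arch, exp_total, numeric(1)))
  ta <- exp_total(alien)
  n_tot <- nrow(grid)
  n_other <- sum(grid$region == "other")
  s <- alien_share
  q <- s * n_tot * tbar / (n_other * (ta * (1 - s) + s * tbar))
  if (q >= 1) stop("alien_share unattainable with this region layout")
  alien$weight <- 5 * q / (1 - q) # five unit-weight archetypes share the rest
  simulate_tropics(grid,
    archetypes = c(arch, list(alien)), years = years,
    nlsf_fraction = nlsf_fraction, seed = seed, ...
  )
}

#' Simulate a full synthetic tropics
#'
#' Convenience wrapper binding [simulate_fire_archive()] and
#' [simulate_environment()] with one master seed. The returned truth record
#' carries the planted regime labels, per-cell anthropogenic trends,
#' vegetation classes, achieved anomaly ratios, and the seed, so any dataset
#' is exactly regenerable.
#'
#' @param grid A [grid_spec].
#' @param archetypes List of [regime_archetype]s.
#' @param years Number of years.
#' @param nlsf_fraction Fraction of NLSF cells.
#' @param anomaly Planted tree-loss anomaly strata (see
#'   [simulate_environment()]).
#' @param seed Master RNG seed.
#' @param ... Passed to [simulate_fire_archive()].
#' @return A list of class `synthetic_tropics` with `series`, `env`, `truth`.
#' @export
simulate_tropics <- function(grid, archetypes = default_archetypes(), years = 14,
                             nlsf_fraction = 0.15, anomaly = NULL, seed = 1, ...) {
  arc <- simulate_fire_archive(grid, archetypes,
    years = years,
    nlsf_fraction = nlsf_fraction, seed = child_seed(seed, 2L), ...
  )
  env <- simulate_environment(grid, arc$truth,
    years = years,
    seed = child_seed(seed, 3L), anomaly = anomaly, precip = arc$precip
  )
  truth <- arc$truth
  truth$anomaly <- env$anomaly_achieved
  truth$master_seed <- seed
  structure(list(series = arc$series, env = env, truth = truth),
    class = "synthetic_tropics"
  )
}
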