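# Vegetation classification from NDVI statistics, tree-loss fractions and
# anomaly ratios, population ratios, and the regime x region x vegetation
# summary table.

#' Rolling-median smoothing of an NDVI series
#'
#' Centred moving median (default 5 observations) that ignores missing
#' values within the window; shrinks the window at the series edges. Window
#' 1 is the identity.
#'
#' @param x Numeric series (NA allowed).
#' @param window Odd window length, at least 1.
#' @return Smoothed series of the same length.
#' @export
smooth_ndvi <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (all(is.na(x))) stop("all-missing series")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w)) stats::median(w) else NA_real_
  }, numeric(1))
}

#' Classify vegetation from normalised NDVI statistics
#'
#' Forest: normalised mean NDVI above 0.80 with annual CV below 0.08
#' (high-stable canopies). Grassy: normalised mean NDVI in [0.06, 0.80) with
#' monthly CV above 0.08 (open, seasonally variable canopies; the 0.06 floor
#' excludes barren surfaces). Everything else is `other`. "Normalised" means
#' divided by the domain-wide maximum mean NDVI, so thresholds act on [0, 1]
#' values; see [ndvi_statistics()].
#'
#' @param mean_ndvi,annual_cv,monthly_cv Normalised per-cell statistics
#'   (vectorised).
#' @param thresholds Named list overriding `forest_mean` (0.80),
#'   `forest_annual_cv` (0.08), `grassy_floor` (0.06), `grassy_monthly_cv`
#'   (0.08).
#' @return Factor with levels forest, grassy, other; the three rules
#'   partition every cell into exactly one class.
#' @export
classify_vegetation <- function(mean_ndvi, annual_cv, monthly_cv,
                                thresholds = list()) {
  th <- utils::modifyList(list(
    forest_mean = 0.80, forest_annual_cv = 0.08,
    grassy_floor = 0.06, grassy_monthly_cv = 0.08
  ), thresholds)
  forest <- mean_ndvi > th$forest_mean & annual_cv < th$forest_annual_cv
  grassy <- !forest & mean_ndvi < th$forest_mean & mean_ndvi >= th$grassy_floor &
    monthly_cv > th$grassy_monthly_cv
  cls <- ifelse(forest, "forest", ifelse(grassy, "grassy", "other"))
  factor(cls, levels = c("forest", "grassy", "other"))
}

#' Per-cell NDVI statistics for vegetation classification
#'
#' From a [cell x 12 x year] NDVI array: the mean, the interannual CV of
#' yearly means, and the seasonal CV of the monthly climatology, each with
#' the mean normalised by the domain-wide maximum mean NDVI (the CVs are
#' scale-free already).
#'
#' @param ndvi Array [cell x 12 x year].
#' @return Data frame `mean_ndvi` (normalised), `annual_cv`, `monthly_cv`.
#' @export
ndvi_statistics <- function(ndvi) {
  stopifnot(length(dim(ndvi)) == 3L, dim(ndvi)[2] == 12L)
  clim <- rowMeans(ndvi, dims = 2L) # [cell x 12]
  yearly <- apply(ndvi, c(1L, 3L), mean) # [cell x year]
  mean_raw <- rowMeans(clim)
  data.frame(
    mean_ndvi = mean_raw / max(mean_raw),
    annual_cv = row_cv(yearly),
    monthly_cv = row_cv(clim)
  )
}

#' Tree-loss fraction of a cell set
#'
#' Total tree loss divided by total baseline tree cover over the set.
#' Undefined (NA) when the set has no baseline cover.
#'
#' @param cover Baseline tree-cover fractions.
#' @param loss Tree-loss fractions over the interval.
#' @return A single proportion, or NA when baseline cover is zero.
#' @export
tree_loss_fraction <- function(cover, loss) {
  if (length(cover) != length(loss)) stop("cover and loss lengths differ")
  if (any(loss > cover + 1e-12)) stop("loss exceeds baseline cover")
  total <- sum(cover)
  if (total == 0) return(NA_real_)
  sum(loss) / total
}

#' Anomaly ratio of a subset statistic against a baseline
#'
#' Subset divided by baseline; values above 1 mark anomalously high levels
#' relative to the whole domain (e.g. tree loss or population density
#' against the all-tropics average).
#'
#' @param subset_stat,baseline_stat Non-negative statistics; the baseline
#'   must be positive.
#' @return A single ratio.
#' @export
anomaly_ratio <- function(subset_stat, baseline_stat) {
  if (!is.finite(baseline_stat) || baseline_stat <= 0) {
    stop("baseline statistic must be positive")
  }
  subset_stat / baseline_stat
}

#' Degradation summary by regime, region and vegetation class
#'
#' Assembles the summary table: one row per combination of regime (0 = NLSF
#' up to K, plus `all`), region (focal, continental, other, plus `all`) and
#' vegetation class (forest, grassy, plus `all`; cells classified `other`
#' enter only the `all` rows). Each row reports the cell count, mean
#' baseline tree cover, tree-loss fraction, tree-loss anomaly ratio against
#' the all-domain all-class baseline, mean population density, and the
#' population ratio against the same baseline. Empty strata are kept as
#' rows with NA statistics, never dropped. The all-domain row has both
#' ratios exactly 1 by construction.
#'
#' @param labels Regime label per cell (-1 dissimilar cells are excluded).
#' @param regions Region label per cell.
#' @param veg Vegetation class per cell (factor from
#'   [classify_vegetation()]).
#' @param cover,loss Baseline tree cover and tree loss per cell.
#' @param population Population density per cell.
#' @return Data frame of class `degradation_summary`.
#' @export
summarize_degradation <- function(labels, regions, veg, cover, loss, population) {
  n <- length(labels)
  stopifnot(
    length(regions) == n, length(veg) == n, length(cover) == n,
    length(loss) == n, length(population) == n
  )
  keep <- labels >= 0
  labels <- labels[keep]; regions <- as.character(regions)[keep]
  veg <- as.character(veg)[keep]; cover <- cover[keep]; loss <- loss[keep]
  population <- population[keep]

  base_loss <- tree_loss_fraction(cover, loss)
  base_pop <- mean(population)
  regimes <- c(sort(unique(labels)), NA) # NA codes the 'all' stratum
  region_set <- c(sort(unique(regions)), NA)
  veg_set <- c("forest", "grassy", NA)

  rows <- list()
  for (g in regimes) for (r in region_set) for (v in veg_set) {
    sel <- rep(TRUE, length(labels))
    if (!is.na(g)) sel <- sel & labels == g
    if (!is.na(r)) sel <- sel & regions == r
    if (!is.na(v)) sel <- sel & veg == v
    n_cells <- sum(sel)
    if (n_cells > 0) {
      lf <- tree_loss_fraction(cover[sel], loss[sel])
      mp <- mean(population[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        regime = if (is.na(g)) "all" else as.character(g),
        region = if (is.na(r)) "all" else r,
        veg_class = if (is.na(v)) "all" else v,
        n_cells = n_cells,
        tree_cover_frac = mean(cover[sel]),
        tree_loss_frac = lf,
        loss_anomaly = if (is.na(lf)) NA_real_ else anomaly_ratio(lf, base_loss),
        mean_population = mp,
        population_ratio = anomaly_ratio(mp, base_pop)
      )
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        regime = if (is.na(g)) "all" else as.character(g),
        region = if (is.na(r)) "all" else r,
        veg_class = if (is.na(v)) "all" else v,
        n_cells = 0L, tree_cover_frac = NA_real_, tree_loss_frac = NA_real_,
        loss_anomaly = NA_real_, mean_population = NA_real_,
        population_ratio = NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$loss_anomaly) & out$loss_anomaly > 1
  class(out) <- c("degradation_summary", "data.frame")
  out
}
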