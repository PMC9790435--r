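# Configuration, plain-text serialization, and the end-to-end pipeline:
# characterise -> cluster -> project -> overlap -> trends -> degradation.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: grid dimensions,
#' record span, number of regimes, the fixed thresholds (MESS similarity 0
#' and exclusivity 24; NDVI 0.80 / 0.08 / 0.06; significance level 0.05;
#' landscape-scale event floor 0.21 km^2), overlap grid resolution and mode,
#' and the master seed. The configuration round-trips unchanged through
#' [write_config()] / [read_config()].
#'
#' @param n_rows,n_cols Synthetic grid dimensions.
#' @param cell_area Cell area (km^2).
#' @param years Record span in years.
#' @param k Number of fire regimes (at least 2).
#' @param mess_similar,mess_exclusive MESS thresholds.
#' @param ndvi_forest_mean,ndvi_forest_annual_cv,ndvi_grassy_floor,ndvi_grassy_monthly_cv
#'   Vegetation-classification thresholds on normalised NDVI statistics.
#' @param alpha Trend significance level.
#' @param event_floor Minimum detectable fire size (km^2).
#' @param overlap_R,overlap_mode Occupancy-grid resolution and mode.
#' @param nlsf_fraction Planted NLSF fraction for synthetic mode.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 30, n_cols = 60, cell_area = 21, years = 14,
                            k = 5, mess_similar = 0, mess_exclusive = 24,
                            ndvi_forest_mean = 0.80, ndvi_forest_annual_cv = 0.08,
                            ndvi_grassy_floor = 0.06, ndvi_grassy_monthly_cv = 0.08,
                            alpha = 0.05, event_floor = 0.21,
                            overlap_R = 100, overlap_mode = "binary",
                            nlsf_fraction = 0.15, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (years < 3) stop("years must be at least 3")
  cfg <- list(
    n_rows = n_rows, n_cols = n_cols, cell_area = cell_area, years = years,
    k = k, mess_similar = mess_similar, mess_exclusive = mess_exclusive,
    ndvi_forest_mean = ndvi_forest_mean,
    ndvi_forest_annual_cv = ndvi_forest_annual_cv,
    ndvi_grassy_floor = ndvi_grassy_floor,
    ndvi_grassy_monthly_cv = ndvi_grassy_monthly_cv,
    alpha = alpha, event_floor = event_floor,
    overlap_R = overlap_R, overlap_mode = overlap_mode,
    nlsf_fraction = nlsf_fraction, seed = seed
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Write and read a fire series as CSV
#'
#' Long-format plain-text serialization: one row per cell-month with burned
#' area, fire count and mean fire size, preceded by the grid table in a
#' companion file. `read_fire_series()` reconstructs the `fire_series`
#' and errors if the stored grid shape disagrees with `grid`.
#'
#' @param series A `fire_series`.
#' @param path CSV path for the series; the grid is written next to it as
#'   `<path>_grid.csv`.
#' @export
write_fire_series <- function(series, path) {
  stopifnot(inherits(series, "fire_series"))
  idx <- expand.grid(
    cell = seq_len(nrow(series$grid)),
    month = 1:12, year = series$years
  )
  df <- data.frame(
    cell_id = series$grid$cell_id[idx$cell],
    year = idx$year, month = idx$month,
    burned_area = as.vector(series$burned_area),
    fire_count = as.vector(series$fire_count),
    mean_fire_size = as.vector(series$mean_fire_size)
  )
  utils::write.csv(df, path, row.names = FALSE)
  g <- as.data.frame(series$grid)
  g$cell_area <- attr(series$grid, "cell_area")
  utils::write.csv(g, grid_companion_path(path), row.names = FALSE)
  invisible(path)
}

grid_companion_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_grid.csv")
}

#' @rdname write_fire_series
#' @param path CSV path produced by [write_fire_series()].
#' @export
read_fire_series <- function(path) {
  df <- utils::read.csv(path)
  g <- utils::read.csv(grid_companion_path(path))
  grid <- data.frame(
    cell_id = g$cell_id, row = g$row, col = g$col,
    region = factor(g$region, levels = REGION_LEVELS)
  )
  attr(grid, "cell_area") <- g$cell_area[1]
  class(grid) <- c("grid_spec", "data.frame")
  n <- nrow(grid)
  years <- sort(unique(df$year))
  expected <- n * 12L * length(years)
  if (nrow(df) != expected) {
    stop(
      "grid mismatch: series has ", nrow(df), " rows but grid implies ",
      expected, " (", n, " cells x 12 months x ", length(years), " years)"
    )
  }
  df <- df[order(match(df$year, years), df$month, match(df$cell_id, grid$cell_id)), ]
  shape <- c(n, 12L, length(years))
  structure(list(
    grid = grid, years = years,
    burned_area = array(df$burned_area, shape),
    fire_count = array(df$fire_count, shape),
    mean_fire_size = array(df$mean_fire_size, shape)
  ), class = "fire_series")
}

#' Run the full pipeline on a synthetic tropics
#'
#' Executes, in order: synthetic generation, per-cell fire characteristics,
#' regime clustering on the focal region, MESS projection over the whole
#' domain, similarity coverage, environmental overlap by regime and region
#' pair, regime-wide trends, pixel-wise decoupled trends on the focal
#' region, vegetation classification and the degradation summary. With
#' `out_dir` set, every stage's table is written as CSV alongside a JSON run
#' log recording the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param tropics Optional pre-generated `synthetic_tropics` (must match the
#'   configuration); generated from the config seed when NULL.
#' @return A list of class `pyromes_run` with the stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, tropics = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "validate"
  result <- tryCatch({
    if (config$years < 10) {
      stop("pixel-wise decoupled trends need at least 10 years (8 analysis years after the 24-month precipitation lead)")
    }
    stage <- "simulate"
    if (is.null(tropics)) {
      grid <- grid_spec(config$n_rows, config$n_cols, config$cell_area)
      tropics <- simulate_tropics(grid,
        years = config$years,
        nlsf_fraction = config$nlsf_fraction, seed = config$seed,
        event_floor = config$event_floor
      )
    }
    series <- tropics$series
    grid <- series$grid

    stage <- "characterize"
    chars <- fire_characteristics(series)

    stage <- "cluster"
    focal <- grid$region == "focal"
    fit <- fire_regimes(chars[focal, ], k = config$k)

    stage <- "project"
    proj <- predict(fit, chars,
      similar = config$mess_similar,
      exclusive = config$mess_exclusive
    )
    total_ba <- rowSums(series$burned_area, dims = 1L)
    coverage <- similarity_coverage(proj$labels, total_ba)

    stage <- "overlap"
    norm_all <- normalise_characteristics(chars, params = fit$norm)$table
    burned <- !chars$is_nlsf
    space <- pca_reduce(norm_all[burned, CHAR_COLS])
    scores <- space$scores
    lab_b <- proj$labels[burned]
    reg_b <- as.character(grid$region)[burned]
    pairs <- list(
      c("focal", "continental"), c("focal", "other"), c("continental", "other")
    )
    ov <- list()
    for (g in seq_len(config$k)) {
      for (p in pairs) {
        ov[[length(ov) + 1L]] <- data.frame(
          regime = g, region_a = p[1], region_b = p[2],
          schoener_d = regional_overlap(scores, lab_b, reg_b, g, p[1], p[2],
            R = config$overlap_R, mode = config$overlap_mode
          )
        )
      }
    }
    overlap <- do.call(rbind, ov)
    proportions <- regime_proportions(proj$labels, grid$region)

    stage <- "trends"
    trend_table <- regime_trend_table(series, proj$labels, grid$region,
      alpha = config$alpha
    )
    # pixel-wise decoupled trends on focal burned cells, years 3..Y
    an_years <- 3:length(series$years)
    cells <- which(focal & proj$labels > 0)
    feats <- lagged_precip_features(tropics$env$precip, an_years, anchor_month = 8L)
    annual <- sum_months(series$burned_area)
    pixel <- do.call(rbind, lapply(cells, function(i) {
      tr <- decoupled_trend(annual[i, an_years], feats$p6[i, ], feats$p24[i, ],
        alpha = config$alpha
      )
      cbind(cell_id = grid$cell_id[i], tr)
    }))

    stage <- "degrade"
    nstats <- ndvi_statistics(tropics$env$ndvi)
    veg <- classify_vegetation(nstats$mean_ndvi, nstats$annual_cv, nstats$monthly_cv,
      thresholds = list(
        forest_mean = config$ndvi_forest_mean,
        forest_annual_cv = config$ndvi_forest_annual_cv,
        grassy_floor = config$ndvi_grassy_floor,
        grassy_monthly_cv = config$ndvi_grassy_monthly_cv
      )
    )
    degradation <- summarize_degradation(
      proj$labels, grid$region, veg,
      tropics$env$tree_cover, tropics$env$tree_loss, tropics$env$population
    )

    list(
      config = config, tropics = tropics, characteristics = chars,
      regimes = fit, projection = proj, coverage = coverage,
      env_space = space, overlap = overlap, proportions = proportions,
      trend_table = trend_table, pixel_trends = pixel,
      vegetation = veg, degradation = degradation
    )
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
      call. = FALSE
    )
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$characteristics,
      file.path(out_dir, "characteristics.csv"),
      row.names = FALSE
    )
    lab <- data.frame(
      cell_id = result$tropics$series$grid$cell_id,
      region = result$tropics$series$grid$region,
      label = result$projection$labels,
      exclusive = result$projection$exclusive,
      veg_class = result$vegetation
    )
    utils::write.csv(lab, file.path(out_dir, "regime_map.csv"), row.names = FALSE)
    utils::write.csv(result$overlap, file.path(out_dir, "overlap.csv"), row.names = FALSE)
    utils::write.csv(result$trend_table, file.path(out_dir, "trends.csv"), row.names = FALSE)
    utils::write.csv(result$pixel_trends, file.path(out_dir, "pixel_trends.csv"),
      row.names = FALSE
    )
    utils::write.csv(result$degradation, file.path(out_dir, "degradation.csv"),
      row.names = FALSE
    )
    log <- list(
      config = unclass(result$config),
      seed = result$config$seed,
      config_hash = config_hash(result$config),
      coverage = result$coverage,
      timestamp_order = "stages run: simulate, characterize, cluster, project, overlap, trends, degrade"
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  class(result) <- "pyromes_run"
  result
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
    character(1)
  ), sep = "=", collapse = ";")
  # small rolling hash; stable across sessions, no extra dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.pyromes_run <- function(x, ...) {
  cat("pyromes pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  cells:", nrow(x$characteristics), " k:", x$config$k, "\n")
  cat(sprintf(
    "  similarity coverage: %.3f of burned area (%.3f of burned cells)\n",
    x$coverage$area_fraction, x$coverage$cell_fraction
  ))
  cat("  regimes (projected):\n")
  print(table(factor(x$projection$labels, levels = c(-1, 0, seq_len(x$config$k)))))
  invisible(x)
}
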