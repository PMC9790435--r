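# Per-cell fire characteristics: the twelve monthly/yearly mean and CV
# descriptors of burned area, fire number and fire size, plus fire-season
# length and the no-landscape-scale-fire (NLSF) flag.

#' Monthly climatology of a monthly series
#'
#' Averages each calendar month over years: value m is the mean of the
#' month-m observations across all years. Input must cover complete years.
#'
#' @param x Either a 12 x n_years numeric matrix (months in rows) or a
#'   numeric vector of length `12 * n_years` in month-within-year order.
#' @return Numeric vector of length 12.
#' @export
monthly_climatology <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 12L) stop("matrix input must have 12 rows (months)")
    m <- x
  } else {
    if (length(x) == 0L || length(x) %% 12L != 0L) {
      stop("series length must be a positive multiple of 12 (complete years)")
    }
    m <- matrix(x, nrow = 12L)
  }
  rowMeans(m)
}

# Row-wise sample CV with the mean-zero -> 0 convention; single column -> 0.
row_cv <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n < 2L) return(rep(0, nrow(m)))
  s <- sqrt(pmax(0, (rowSums(m^2) - n * mu^2) / (n - 1)))
  ifelse(mu == 0, 0, s / mu)
}

# Sum a [cell x 12 x year] array over months -> [cell x year] matrix.
sum_months <- function(a) {
  rowSums(aperm(a, c(1L, 3L, 2L)), dims = 2L)
}

#' Fire characteristics of gridded burned-area records
#'
#' Computes, for every cell of a [fire_series] (or for a single cell given as
#' 12 x n_years matrices), the twelve descriptors used to define fire regimes:
#' monthly and yearly means and coefficients of variation of burned area,
#' fire number, and fire size. Monthly statistics are taken over the 12-value
#' monthly climatology, so the monthly CV measures average annual seasonality;
#' yearly statistics are taken over per-year annual aggregates (annual burned
#' area and fire count are sums; annual fire size is annual burned area over
#' annual count, 0 in fire-free years), so the yearly CV measures interannual
#' variability. Also returns the average fire-season length (mean number of
#' months per year with any burned area) and the NLSF flag (no burned area at
#' landscape scale over the whole span).
#'
#' Months without fires contribute a fire size of 0 to the size climatology by
#' default, keeping the 12-vector complete for clustering;
#' `fsize_fire_months_only = TRUE` instead averages size over fire months only.
#'
#' @param x A [fire_series], or a list with 12 x n_years matrices
#'   `burned_area`, `fire_count`, `mean_fire_size` for one cell.
#' @param fsize_fire_months_only Logical; see above.
#' @return A data frame with one row per cell: `cell_id`, the 12
#'   characteristic columns, `season_length`, and `is_nlsf`.
#' @export
fire_characteristics <- function(x, fsize_fire_months_only = FALSE) {
  if (inherits(x, "fire_series")) {
    ba <- x$burned_area
    nf <- x$fire_count
    fs <- x$mean_fire_size
    cell_id <- x$grid$cell_id
  } else if (is.list(x) &&
    all(c("burned_area", "fire_count", "mean_fire_size") %in% names(x))) {
    as_cell_array <- function(m) {
      m <- as.matrix(m)
      if (nrow(m) != 12L) stop("per-cell matrices must have 12 rows (months)")
      array(m, dim = c(1L, dim(m)))
    }
    ba <- as_cell_array(x$burned_area)
    nf <- as_cell_array(x$fire_count)
    fs <- as_cell_array(x$mean_fire_size)
    cell_id <- NULL
  } else {
    stop("x must be a fire_series or a per-cell list of burned_area/fire_count/mean_fire_size")
  }
  stopifnot(all(dim(ba) == dim(nf)), all(dim(ba) == dim(fs)))
  if (any(ba < 0) || any(nf < 0)) stop("negative burned area or fire count")

  ba_clim <- rowMeans(ba, dims = 2L) # [cell x 12]
  nf_clim <- rowMeans(nf, dims = 2L)
  fs_clim <- if (fsize_fire_months_only) {
    t(apply(fs, 1L, function(m) {
      m <- matrix(m, nrow = 12L)
      apply(m, 1L, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
    }))
  } else {
    rowMeans(fs, dims = 2L)
  }

  ba_year <- sum_months(ba) # [cell x year]
  nf_year <- sum_months(nf)
  fs_year <- ifelse(nf_year > 0, ba_year / nf_year, 0)

  res <- data.frame(
    ba_month_mean = rowMeans(ba_clim), ba_month_cv = row_cv(ba_clim),
    ba_year_mean = rowMeans(ba_year), ba_year_cv = row_cv(ba_year),
    nfire_month_mean = rowMeans(nf_clim), nfire_month_cv = row_cv(nf_clim),
    nfire_year_mean = rowMeans(nf_year), nfire_year_cv = row_cv(nf_year),
    fsize_month_mean = rowMeans(fs_clim), fsize_month_cv = row_cv(fs_clim),
    fsize_year_mean = rowMeans(fs_year), fsize_year_cv = row_cv(fs_year),
    season_length = rowMeans(sum_months(ba > 0)),
    is_nlsf = rowSums(ba, dims = 1L) == 0
  )
  if (!is.null(cell_id)) res <- cbind(cell_id = cell_id, res)
  rownames(res) <- NULL
  res
}

#' Min-max normalisation of a characteristics table
#'
#' Rescales each of the 12 characteristics to [0, 1] over the burned
#' (non-NLSF) cells of the reference domain, and returns the scaling
#' parameters so that projection targets can be transformed with the
#' *reference* parameters (values outside the reference range map outside
#' [0, 1]; they are deliberately not clipped, which is what lets the
#' similarity surface flag out-of-range cells).
#'
#' @param x Data frame containing the 12 characteristic columns (and
#'   optionally `is_nlsf`, used to restrict the reference domain).
#' @param params Optional parameters from a previous call (a `char_norm`
#'   object or its `params` data frame); when supplied, `x` is transformed
#'   with them instead of refitting.
#' @return A list of class `char_norm` with `table` (normalised copy of the
#'   characteristic columns plus any `cell_id`/`is_nlsf` columns) and
#'   `params` (data frame `variable`, `min`, `max`).
#' @export
normalise_characteristics <- function(x, params = NULL) {
  missing_cols <- setdiff(CHAR_COLS, names(x))
  if (length(missing_cols)) {
    stop("missing characteristic columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(params)) {
    domain <- if ("is_nlsf" %in% names(x)) !x$is_nlsf else rep(TRUE, nrow(x))
    if (!any(domain)) stop("no burned (non-NLSF) cells to define the scaling domain")
    params <- data.frame(
      variable = CHAR_COLS,
      min = vapply(CHAR_COLS, function(v) min(x[[v]][domain]), numeric(1)),
      max = vapply(CHAR_COLS, function(v) max(x[[v]][domain]), numeric(1))
    )
    rownames(params) <- NULL
  } else {
    if (inherits(params, "char_norm")) params <- params$params
    stopifnot(all(c("variable", "min", "max") %in% names(params)))
  }
  out <- x
  for (v in CHAR_COLS) {
    p <- params[params$variable == v, ]
    rng <- p$max - p$min
    if (rng == 0) {
      warning("characteristic '", v, "' is constant over the domain; set to 0")
      out[[v]] <- rep(0, nrow(x))
    } else {
      out[[v]] <- (x[[v]] - p$min) / rng
    }
  }
  keep <- intersect(c("cell_id", CHAR_COLS, "season_length", "is_nlsf"), names(out))
  structure(list(table = out[keep], params = params), class = "char_norm")
}
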