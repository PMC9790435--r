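# Burned-area trend analysis: regime-wide OLS trends on annual totals, and
# pixel-wise trends decoupled from antecedent precipitation by multiple
# regression on the preceding 6-month (drought) and 24-month (fuel
# build-up) precipitation sums.

#' Annual burned-area series of a regime within a region
#'
#' One value per year: the total burned area over the cells carrying the
#' regime label (optionally restricted to one region).
#'
#' @param series A `fire_series`.
#' @param labels Regime label per cell.
#' @param regime Regime to aggregate.
#' @param regions Optional region label per cell.
#' @param region Optional region to restrict to.
#' @return Named numeric vector, one element per year.
#' @export
regime_annual_series <- function(series, labels, regime, regions = NULL, region = NULL) {
  stopifnot(inherits(series, "fire_series"))
  sel <- labels == regime
  if (!is.null(region)) {
    if (is.null(regions)) stop("region given without per-cell regions")
    sel <- sel & regions == region
  }
  if (!any(sel)) stop("empty cell set: regime ", regime, " absent",
                      if (!is.null(region)) paste0(" in region ", region))
  annual <- sum_months(series$burned_area[sel, , , drop = FALSE])
  out <- colSums(annual)
  names(out) <- series$years
  out
}

#' Ordinary least squares trend of an annual series
#'
#' Regresses the series on the year index and reports the slope, its
#' two-sided t statistic and p value, and the relative change over the span:
#' `100 * slope * (n_years - 1) / fitted value at the first year` (percent).
#' A zero-variance series is degenerate: slope 0, not significant.
#'
#' @param y Annual values (at least 5 years).
#' @param alpha Significance level (default 0.05).
#' @return A one-row data frame of class `fire_trend`: `slope`, `t_value`,
#'   `p_value`, `relative_change_pct`, `n_years`, `significant`,
#'   `degenerate`.
#' @export
ols_trend <- function(y, alpha = 0.05) {
  n <- length(y)
  if (n < 5) stop("need at least 5 years")
  t_idx <- seq_len(n) - 1
  if (stats::sd(y) == 0) {
    return(structure(data.frame(
      slope = 0, t_value = NA_real_, p_value = NA_real_,
      relative_change_pct = 0, n_years = n, significant = FALSE,
      degenerate = TRUE
    ), class = c("fire_trend", "data.frame")))
  }
  fit <- stats::lm(y ~ t_idx)
  co <- summary(fit)$coefficients
  slope <- co["t_idx", "Estimate"]
  fitted0 <- stats::fitted(fit)[1]
  rel <- if (fitted0 > 0) 100 * slope * (n - 1) / fitted0 else NA_real_
  p <- co["t_idx", "Pr(>|t|)"]
  structure(data.frame(
    slope = slope, t_value = co["t_idx", "t value"], p_value = p,
    relative_change_pct = rel, n_years = n,
    significant = is.finite(p) && p < alpha, degenerate = FALSE
  ), class = c("fire_trend", "data.frame"))
}

#' Antecedent precipitation features
#'
#' For each analysis year, the sums of monthly precipitation over the 6 and
#' 24 months strictly preceding the fire-year anchor month (by default the
#' climatological peak burning month, so the antecedent windows precede the
#' burning season). Requires at least 24 months of history before the first
#' analysis year — with a record starting in 2003, decoupled trends start
#' in 2005.
#'
#' @param precip Either a vector of monthly precipitation for one cell or a
#'   [cell x month] matrix, with a `lead_months` attribute giving the months
#'   of history before fire year 1 (assumed 0 when absent).
#' @param years Analysis years as indices into the fire record (1-based).
#' @param anchor_month Calendar month (1-12) anchoring the fire year.
#' @return For vector input a data frame `year`, `p6`, `p24`; for matrix
#'   input a list of matrices `p6`, `p24` of size [cell x length(years)].
#' @export
lagged_precip_features <- function(precip, years, anchor_month) {
  stopifnot(anchor_month %in% 1:12)
  vec <- is.null(dim(precip))
  p <- if (vec) matrix(precip, nrow = 1L) else as.matrix(precip)
  lead <- attr(precip, "lead_months")
  if (is.null(lead)) lead <- 0L
  idx <- lead + (years - 1L) * 12L + anchor_month
  if (any(idx - 24L < 1L)) {
    stop("insufficient history: need 24 months of precipitation before the first analysis year")
  }
  if (any(idx - 1L > ncol(p))) stop("precipitation record shorter than the analysis span")
  cs <- if (nrow(p) == 1L) matrix(cumsum(p), 1L) else t(apply(p, 1L, cumsum))
  p6 <- cs[, idx - 1L, drop = FALSE] - cs[, idx - 7L, drop = FALSE]
  p24 <- cs[, idx - 1L, drop = FALSE] - cs[, idx - 25L, drop = FALSE]
  if (vec) {
    data.frame(year = years, p6 = p6[1L, ], p24 = p24[1L, ])
  } else {
    list(p6 = p6, p24 = p24)
  }
}

#' Precipitation-decoupled (anthropogenic) burned-area trend
#'
#' Multiple linear regression of annual burned area on the year index and
#' the antecedent 6- and 24-month precipitation sums. The year coefficient
#' is the trend left after removing what precipitation explains; its t value
#' is the pixel map statistic, and its significance at `alpha` flags an
#' anthropogenic trend. Constant (collinear) precipitation features are
#' dropped with a warning, reducing the model to [ols_trend()]. No
#' multiple-testing correction is applied across pixels.
#'
#' @param y Annual burned area over the analysis years (at least 8).
#' @param p6,p24 Antecedent sums aligned with `y` (from
#'   [lagged_precip_features()]).
#' @param alpha Significance level.
#' @return A one-row data frame of class `fire_trend` (year-coefficient
#'   statistics) with extra columns `coef_p6`, `coef_p24`.
#' @export
decoupled_trend <- function(y, p6, p24, alpha = 0.05) {
  n <- length(y)
  if (n < 8) stop("need at least 8 years")
  if (length(p6) != n || length(p24) != n) stop("misaligned years")
  t_idx <- seq_len(n) - 1
  keep6 <- stats::sd(p6) > 0
  keep24 <- stats::sd(p24) > 0
  if (!keep6 || !keep24) {
    warning("constant precipitation feature(s) dropped")
  }
  X <- cbind(t_idx = t_idx)
  if (keep6) X <- cbind(X, p6 = p6)
  if (keep24) X <- cbind(X, p24 = p24)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L && "p24" %in% colnames(X)) {
    warning("collinear precipitation features; dropping the 24-month sum")
    X <- X[, colnames(X) != "p24", drop = FALSE]
  }
  if (stats::sd(y) == 0) {
    return(structure(data.frame(
      slope = 0, t_value = NA_real_, p_value = NA_real_,
      relative_change_pct = 0, n_years = n, significant = FALSE,
      degenerate = TRUE, coef_p6 = NA_real_, coef_p24 = NA_real_
    ), class = c("fire_trend", "data.frame")))
  }
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  co <- summary(fit)$coefficients
  slope <- co["t_idx", "Estimate"]
  p <- co["t_idx", "Pr(>|t|)"]
  fitted0 <- stats::fitted(fit)[1]
  rel <- if (fitted0 > 0) 100 * slope * (n - 1) / fitted0 else NA_real_
  structure(data.frame(
    slope = slope, t_value = co["t_idx", "t value"], p_value = p,
    relative_change_pct = rel, n_years = n,
    significant = is.finite(p) && p < alpha, degenerate = FALSE,
    coef_p6 = if (keep6 && "p6" %in% rownames(co)) co["p6", "Estimate"] else NA_real_,
    coef_p24 = if (keep24 && "p24" %in% rownames(co)) co["p24", "Estimate"] else NA_real_
  ), class = c("fire_trend", "data.frame"))
}

#' Regime-by-region trend table
#'
#' [ols_trend()] applied to every regime x region combination present,
#' including an all-regions row per region.
#'
#' @param series A `fire_series`.
#' @param labels Regime label per cell.
#' @param regions Region label per cell.
#' @param alpha Significance level.
#' @return Data frame with columns `regime`, `region`, `slope`, `t_value`,
#'   `p_value`, `relative_change_pct`, `n_years`, `significant`.
#' @export
regime_trend_table <- function(series, labels, regions, alpha = 0.05) {
  regimes <- sort(unique(labels[labels > 0]))
  out <- list()
  for (r in unique(as.character(regions))) {
    for (g in regimes) {
      if (!any(labels == g & regions == r)) next
      y <- regime_annual_series(series, labels, g, regions, r)
      tr <- ols_trend(y, alpha = alpha)
      out[[length(out) + 1L]] <- cbind(regime = g, region = r, tr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[setdiff(names(res), "degenerate")]
}
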