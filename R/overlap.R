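# PCA-reduced environmental spaces and niche overlap between regions via
# Schoener's D on occupancy grids over the first two principal axes.

#' Reduce an environmental table to two principal axes
#'
#' Standardises the variables (zero mean, unit variance), drops any constant
#' variable with a warning, and returns the top two principal axes with
#' their explained-variance shares. Fit the space on the pooled domain (all
#' regions together) so that regional score clouds are directly comparable.
#'
#' @param x Data frame or matrix of cells x variables (fire 12, vegetation
#'   6, or climate 4 in the standard pipeline; any numeric table works).
#' @return An object of class `env_space`: `loadings` (variables x 2,
#'   orthonormal), `explained` (proportions for all axes, non-increasing),
#'   `scores` (cells x 2), `center`, `scale`, `variables`.
#' @export
pca_reduce <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 cells")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(
      "dropping constant variable(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 non-constant variables")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    loadings = p$rotation[, 1:2, drop = FALSE],
    explained = expl,
    scores = p$x[, 1:2, drop = FALSE],
    center = p$center, scale = p$scale,
    variables = colnames(x)
  ), class = "env_space")
}

#' @export
print.env_space <- function(x, ...) {
  cat("Reduced environment:", length(x$variables), "variables,",
      nrow(x$scores), "cells\n")
  cat(sprintf(
    "  axis 1: %.2f%%  axis 2: %.2f%%  (two axes: %.2f%%)\n",
    100 * x$explained[1], 100 * x$explained[2],
    100 * sum(x$explained[1:2])
  ))
  invisible(x)
}

# Score new cells in a fitted reduced space.
project_scores <- function(space, x) {
  x <- as.matrix(x)[, space$variables, drop = FALSE]
  scale(x, center = space$center, scale = space$scale) %*% space$loadings
}

#' Occupancy grid over a reduced environmental space
#'
#' Discretises axis-1/axis-2 scores on an R x R lattice over fixed bounds.
#' In binary mode each occupied bin gets weight 1 before normalisation (the
#' occupancy pattern, not the density, defines the niche); in density mode
#' bins carry counts. Weights are normalised to sum to 1. Two grids are
#' comparable only when built with identical bounds, resolution and mode.
#'
#' @param scores Two-column matrix of cell scores.
#' @param bounds List with numeric `x` and `y` ranges covering all scores of
#'   both grids being compared.
#' @param R Grid resolution per axis (at least 10; default 100).
#' @param mode `"binary"` or `"density"`.
#' @return An object of class `occupancy_grid` with the R x R weight matrix
#'   `w` and the grid metadata.
#' @export
occupancy_grid <- function(scores, bounds, R = 100, mode = c("binary", "density")) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("empty cell set")
  if (R < 10) stop("R must be at least 10")
  bx <- bounds$x
  by <- bounds$y
  if (any(scores[, 1] < bx[1] | scores[, 1] > bx[2] |
          scores[, 2] < by[1] | scores[, 2] > by[2])) {
    stop("bounds do not cover all scores")
  }
  ix <- pmin(R, pmax(1L, findInterval(scores[, 1], seq(bx[1], bx[2], length.out = R + 1),
    rightmost.closed = TRUE
  )))
  iy <- pmin(R, pmax(1L, findInterval(scores[, 2], seq(by[1], by[2], length.out = R + 1),
    rightmost.closed = TRUE
  )))
  w <- matrix(0, R, R)
  counts <- table(factor(ix, levels = 1:R), factor(iy, levels = 1:R))
  w[] <- as.numeric(counts)
  if (mode == "binary") w <- (w > 0) * 1
  w <- w / sum(w)
  structure(list(w = w, bounds = bounds, R = R, mode = mode),
    class = "occupancy_grid"
  )
}

#' Schoener's D overlap between two occupancy grids
#'
#' `D = 1 - 0.5 * sum(|w_a - w_b|)` over bins: 1 for identical occupancy,
#' 0 for disjoint occupancy; symmetric and bounded in [0, 1].
#'
#' @param a,b `occupancy_grid`s with identical bounds, resolution and mode.
#' @return A single number in [0, 1].
#' @export
schoener_d <- function(a, b) {
  stopifnot(inherits(a, "occupancy_grid"), inherits(b, "occupancy_grid"))
  if (a$R != b$R || a$mode != b$mode ||
      !isTRUE(all.equal(a$bounds, b$bounds))) {
    stop("grids are not comparable: bounds, resolution and mode must match")
  }
  1 - 0.5 * sum(abs(a$w - b$w))
}

#' Environmental overlap of one regime between two regions
#'
#' Builds occupancy grids over a shared reduced environmental space for the
#' cells of one regime in each of two regions and returns their Schoener's
#' D. The grid bounds span the *pooled* score cloud (all cells of the
#' space), so the same discretisation underlies every regime and region
#' comparison and a single regime's cells concentrate into well-sampled
#' bins. If the regime is absent from either region the overlap is
#' undefined and NA is returned (never 0, which would mean fully disjoint
#' niches).
#'
#' @param scores Two-column score matrix for all cells (from [pca_reduce()]
#'   on the pooled domain), or an `env_space`.
#' @param labels Regime label per cell.
#' @param regions Region label per cell.
#' @param regime Regime to compare.
#' @param region_a,region_b The two regions.
#' @param R Grid resolution.
#' @param mode `"binary"` (default) or `"density"`.
#' @param bounds Optional bounds (list with `x`, `y`); defaults to the
#'   padded range of the pooled scores.
#' @return Schoener's D, or NA if the regime is absent from a region.
#' @export
regional_overlap <- function(scores, labels, regions, regime, region_a, region_b,
                             R = 100, mode = "binary", bounds = NULL) {
  if (inherits(scores, "env_space")) scores <- scores$scores
  if (is.null(bounds)) bounds <- score_bounds(scores)
  sa <- scores[labels == regime & regions == region_a, , drop = FALSE]
  sb <- scores[labels == regime & regions == region_b, , drop = FALSE]
  if (nrow(sa) == 0L || nrow(sb) == 0L) return(NA_real_)
  schoener_d(
    occupancy_grid(sa, bounds, R = R, mode = mode),
    occupancy_grid(sb, bounds, R = R, mode = mode)
  )
}

# Padded bounds of a pooled score cloud.
score_bounds <- function(scores) {
  pad <- function(r) r + c(-1, 1) * max(1e-9, diff(r) * 1e-6)
  list(x = pad(range(scores[, 1])), y = pad(range(scores[, 2])))
}

#' Proportion of regional cells attributed to each regime
#'
#' The companion statistic to regional overlap: within each region, the
#' share of classified burned cells carrying each regime label.
#'
#' @param labels Regime label per cell (0 NLSF and -1 dissimilar are
#'   reported as their own rows).
#' @param regions Region label per cell.
#' @return Data frame `region`, `regime`, `n`, `proportion` (within region,
#'   over burned classified cells).
#' @export
regime_proportions <- function(labels, regions) {
  tab <- table(region = regions, regime = labels)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("region", "regime", "n")
  out$regime <- as.integer(out$regime)
  burned <- out$regime > 0
  denom <- stats::ave(out$n * burned, out$region, FUN = sum)
  out$proportion <- ifelse(burned & denom > 0, out$n / denom, NA_real_)
  out
}
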