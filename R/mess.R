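# Multivariate environmental similarity surface (MESS): per-variable
# piecewise similarity of a probe point to a reference sample, combined as
# the minimum over variables. Positive values mean the probe lies inside the
# reference range on every variable; 100 is attained at the per-variable
# reference median.

MESS_DEGENERATE <- -1e6 # sentinel for off-value probes of a constant variable

#' Single-variable MESS score
#'
#' With f the percentage of reference values strictly below the probe
#' (ties count as not-below by default, matching the standard MESS
#' convention):
#' f = 0 gives `100 * (point - min) / (max - min)` (negative below range);
#' 0 < f <= 50 gives `2 f`; 50 < f < 100 gives `2 (100 - f)`; f = 100 gives
#' `100 * (max - point) / (max - min)` (negative above range). The score is
#' piecewise linear and continuous in the probe, at most 100.
#'
#' A degenerate variable (reference max equals min) scores 100 when the
#' probe equals the constant and a large negative sentinel otherwise.
#'
#' @param reference Non-empty numeric vector of reference values.
#' @param point Numeric vector of probe values (vectorised).
#' @param ties `"not_below"` (default: reference values equal to the probe
#'   do not count as below) or `"below"`.
#' @return Numeric vector of similarities, one per probe.
#' @export
mess_variable <- function(reference, point, ties = c("not_below", "below")) {
  ties <- match.arg(ties)
  if (length(reference) == 0L) stop("empty reference")
  rmin <- min(reference)
  rmax <- max(reference)
  # a reference range at floating-point scale is degenerate: characteristics
  # that are deterministically constant within a regime (e.g. the seasonality
  # CV of a one-month fire season) differ across cells only by rounding dust,
  # and the piecewise formula would turn that dust into a knife edge
  scale <- max(abs(rmax), abs(rmin), 1)
  if (rmax - rmin <= 1e-9 * scale) {
    return(ifelse(abs(point - (rmin + rmax) / 2) <= 1e-8 * scale,
      100, MESS_DEGENERATE
    ))
  }
  sorted <- sort(reference)
  nref <- length(sorted)
  n_below <- if (ties == "not_below") {
    findInterval(point, sorted, left.open = TRUE)
  } else {
    findInterval(point, sorted)
  }
  f <- 100 * n_below / nref
  score <- numeric(length(point))
  i0 <- f == 0
  i1 <- f > 0 & f <= 50
  i2 <- f > 50 & f < 100
  i3 <- f == 100
  score[i0] <- 100 * (point[i0] - rmin) / (rmax - rmin)
  score[i1] <- 2 * f[i1]
  score[i2] <- 2 * (100 - f[i2])
  score[i3] <- 100 * (rmax - point[i3]) / (rmax - rmin)
  score
}

#' MESS surface of one reference set
#'
#' The similarity of each target cell to the reference cells, defined as the
#' minimum over variables of [mess_variable()]. Reference and targets must
#' be on the same (reference-parameter) normalisation.
#'
#' @param reference Matrix or data frame of reference cells x variables
#'   (at least 2 rows).
#' @param targets Matrix or data frame of target cells over the same
#'   variables.
#' @param ties Tie convention, see [mess_variable()].
#' @return Numeric vector of similarities, one per target cell.
#' @export
mess_surface <- function(reference, targets, ties = "not_below") {
  reference <- as.matrix(reference)
  targets <- as.matrix(targets)
  if (nrow(reference) < 2L) stop("reference set must have at least 2 cells")
  if (ncol(reference) != ncol(targets)) {
    stop("reference and targets must share the same variables")
  }
  out <- rep(Inf, nrow(targets))
  for (j in seq_len(ncol(reference))) {
    out <- pmin(out, mess_variable(reference[, j], targets[, j], ties = ties))
  }
  out
}

# One surface per regime, as a [target x regime] matrix.
mess_surfaces <- function(reference_list, targets, ties = "not_below") {
  vapply(reference_list, function(ref) mess_surface(ref, targets, ties = ties),
    numeric(nrow(as.matrix(targets)))
  )
}

#' Classify tropical cells from regime similarity surfaces
#'
#' NLSF cells get label 0. Burned cells whose similarity is at or below
#' `similar` for every regime are dissimilar (label -1; fire conditions not
#' represented in the reference region). All other burned cells are labelled
#' by the regime of maximum similarity — the assignment rule where several
#' surfaces overlap. The exclusivity mask is TRUE where exactly one regime
#' exceeds the `exclusive` threshold, isolating cells attributable to a
#' single distinct regime.
#'
#' @param mess Matrix [cell x regime] of similarities.
#' @param nlsf Logical NLSF mask over the same cells.
#' @param similar Similarity threshold (default 0).
#' @param exclusive Exclusivity threshold (default 24).
#' @return List with integer `labels` and logical `exclusive`.
#' @export
classify_tropics <- function(mess, nlsf, similar = 0, exclusive = 24) {
  mess <- as.matrix(mess)
  if (nrow(mess) != length(nlsf)) {
    stop(
      "grid mismatch: similarity surface has ", nrow(mess),
      " cells but NLSF mask has ", length(nlsf)
    )
  }
  labels <- max.col(mess, ties.method = "first")
  labels[apply(mess, 1L, max) <= similar] <- -1L
  labels[nlsf] <- 0L
  excl <- rowSums(mess > exclusive) == 1L & !nlsf
  list(labels = as.integer(labels), exclusive = excl)
}

#' Burned-area coverage of the similarity classification
#'
#' The fraction of total burned area — and, separately, of burned cells —
#' falling in cells classified as similar to some reference regime
#' (labels 1..K) rather than dissimilar (-1). This is the statistic behind
#' "similar to X % of tropical burned area".
#'
#' @param labels Integer labels from [classify_tropics()] (or a
#'   `regime_projection`).
#' @param burned_area Total burned area per cell over the span (km^2).
#' @return List with `area_fraction` and `cell_fraction`.
#' @export
similarity_coverage <- function(labels, burned_area) {
  if (inherits(labels, "regime_projection")) labels <- labels$labels
  if (length(labels) != length(burned_area)) stop("labels and burned_area lengths differ")
  total <- sum(burned_area)
  if (total == 0) stop("zero total burned area")
  burned <- labels != 0L
  list(
    area_fraction = sum(burned_area[labels > 0L]) / total,
    cell_fraction = mean(labels[burned] > 0L)
  )
}
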