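# Fire-regime definition: agglomerative complete-linkage clustering of the
# normalised 12-characteristic vectors, with NLSF cells held out, wrapped as
# a fitted-model object whose predict() method projects the regimes onto new
# cells via the multivariate environmental similarity surface.

#' No-landscape-scale-fire mask
#'
#' TRUE exactly where total burned area over the record span is zero. Fires
#' below the detection floor (0.21 km^2 by default in the generator) are
#' dropped upstream at event level, so cells burning only below that floor
#' are NLSF here. NLSF cells are excluded from the clustering input.
#'
#' @param x A `fire_series` or a characteristics data frame (from
#'   [fire_characteristics()]).
#' @return Logical vector, one element per cell.
#' @export
assign_nlsf <- function(x) {
  if (inherits(x, "fire_series")) {
    return(rowSums(x$burned_area, dims = 1L) == 0)
  }
  if (is.data.frame(x) && "is_nlsf" %in% names(x)) return(x$is_nlsf)
  if (is.data.frame(x) && "ba_year_mean" %in% names(x)) return(x$ba_year_mean == 0)
  stop("x must be a fire_series or a characteristics data frame")
}

#' Fit fire regimes by complete-linkage clustering
#'
#' Defines K fire regimes from gridded burned-area records: computes the 12
#' per-cell fire characteristics (unless given a precomputed table), holds
#' out NLSF cells, min-max normalises the characteristics over the burned
#' cells, and clusters them agglomeratively with Euclidean distance and
#' complete linkage (merges join the pair of clusters with the smallest
#' maximum inter-point distance), cut to exactly `k` clusters. Regime labels
#' are renumbered so that they ascend with cluster-mean total burned area:
#' label `k` is always the highest-fire regime, label 0 is NLSF.
#'
#' @param x A `fire_series` or a characteristics data frame with the 12
#'   columns (plus optionally `cell_id`, `is_nlsf`).
#' @param k Number of regimes (at least 2, at most the number of burned
#'   cells).
#' @param method Linkage: `"complete"` (the default regime definition) or
#'   `"ward"` (Ward's D2, provided for robustness comparison).
#' @return An object of class `fire_regimes`: `labels` (per cell, 0 = NLSF,
#'   1..k = regime), `characteristics`, `norm` (the `char_norm` with
#'   reference scaling parameters), `hclust`, `heights`, `k`, `nlsf`.
#' @seealso [predict.fire_regimes()] for tropical projection,
#'   [cut_height_diagnostics()] for the choice of `k`.
#' @export
fire_regimes <- function(x, k = 5, method = c("complete", "ward")) {
  method <- match.arg(method)
  chars <- if (inherits(x, "fire_series")) fire_characteristics(x) else x
  if (!all(CHAR_COLS %in% names(chars))) {
    stop("input lacks the 12 characteristic columns")
  }
  if (!"cell_id" %in% names(chars)) chars$cell_id <- seq_len(nrow(chars))
  if (!"is_nlsf" %in% names(chars)) chars$is_nlsf <- assign_nlsf(chars)
  nlsf <- chars$is_nlsf
  n_burn <- sum(!nlsf)
  if (k < 2) stop("k must be at least 2")
  if (k > n_burn) stop("k exceeds the number of burned cells (", n_burn, ")")

  norm <- normalise_characteristics(chars)
  m <- as.matrix(norm$table[!nlsf, CHAR_COLS])
  # stable row order: distances are order-independent, and relabelling by
  # burned-area rank below removes any residual ordering effect
  hc <- stats::hclust(stats::dist(m),
    method = if (method == "complete") "complete" else "ward.D2"
  )
  if (max(hc$height) == 0) {
    warning("all characteristic vectors identical: single effective cluster (zero merge heights)")
  }
  raw <- stats::cutree(hc, k = k)
  # ascending cluster-mean total burned area -> label k = highest-fire regime
  ba <- chars$ba_year_mean[!nlsf]
  ord <- order(vapply(seq_len(k), function(g) mean(ba[raw == g]), numeric(1)))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- integer(nrow(chars))
  labels[!nlsf] <- relabel[raw]

  structure(list(
    labels = labels, characteristics = chars, norm = norm,
    hclust = hc, heights = hc$height, k = k, nlsf = nlsf,
    method = method, call = match.call()
  ), class = "fire_regimes")
}

#' @export
print.fire_regimes <- function(x, ...) {
  cat("Fire regimes (", x$method, "-linkage clustering, k = ", x$k, ")\n", sep = "")
  cat("  cells: ", length(x$labels), " (", sum(x$nlsf), " NLSF held out)\n", sep = "")
  tab <- table(factor(x$labels, levels = 0:x$k))
  cat("  cells per label (0 = NLSF):\n")
  print(tab)
  invisible(x)
}

#' @export
summary.fire_regimes <- function(object, ...) {
  chars <- object$characteristics
  by_regime <- stats::aggregate(
    chars[, c("ba_year_mean", "ba_year_cv", "nfire_year_mean",
              "fsize_year_mean", "season_length")],
    by = list(regime = object$labels), FUN = mean
  )
  structure(list(
    k = object$k, n = length(object$labels), n_nlsf = sum(object$nlsf),
    regime_means = by_regime, heights = object$heights
  ), class = "summary.fire_regimes")
}

#' @export
print.summary.fire_regimes <- function(x, ...) {
  cat("Fire regimes: k =", x$k, "on", x$n - x$n_nlsf, "burned cells (",
      x$n_nlsf, "NLSF )\n")
  cat("Cluster means by regime (0 = NLSF):\n")
  print(x$regime_means, digits = 3)
  invisible(x)
}

#' Dendrogram with the regime cut
#'
#' Plots the complete-linkage dendrogram and marks the height at which the
#' tree is cut into the fitted number of regimes.
#'
#' @param x A `fire_regimes` object.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.fire_regimes <- function(x, ...) {
  plot(x$hclust, labels = FALSE, main = "Fire-regime dendrogram",
       xlab = "", sub = "", ...)
  h <- sort(x$heights) # cutting into k clusters falls between these merges
  n <- length(h) + 1L
  if (x$k < n) {
    lo <- h[n - x$k]
    hi <- h[n - x$k + 1L]
    graphics::abline(h = (lo + hi) / 2, lty = 2)
  }
  invisible(x)
}

#' Relative cut heights over candidate cluster numbers
#'
#' For each candidate K, reports the height of the merge that would fuse K
#' clusters into K - 1, relative to the maximum merge height. K values whose
#' cut sits above half the tree height (ratio > 0.5) mark strong natural
#' breaks in dataset variability and are flagged.
#'
#' @param x A `fire_regimes` object or an `hclust`.
#' @param k_range Candidate K values (default 2 to 10).
#' @param ratio_threshold Flagging threshold (default 0.5).
#' @return Data frame with `k`, `cut_height`, `ratio`, `flagged`.
#' @export
cut_height_diagnostics <- function(x, k_range = 2:10, ratio_threshold = 0.5) {
  hc <- if (inherits(x, "fire_regimes")) x$hclust else x
  if (!inherits(hc, "hclust")) stop("x must be a fire_regimes or hclust object")
  h <- hc$height # non-decreasing, length n - 1
  n <- length(h) + 1L
  k_range <- k_range[k_range >= 2 & k_range <= n - 1L]
  hmax <- max(h)
  cut_h <- h[n - k_range + 1L] # merge that reduces K clusters to K - 1
  ratio <- if (hmax > 0) cut_h / hmax else rep(0, length(cut_h))
  data.frame(
    k = k_range, cut_height = cut_h, ratio = ratio,
    flagged = ratio > ratio_threshold
  )
}

#' Project fitted fire regimes onto new cells
#'
#' Computes, for every target cell, the multivariate environmental similarity
#' of its 12 fire characteristics to each fitted regime's reference cells
#' (characteristics are transformed with the *reference* normalisation
#' parameters), then classifies cells as NLSF (label 0), dissimilar to every
#' regime (label -1, all similarities at or below `similar`), or by the
#' regime of maximum similarity. Cells where exactly one regime exceeds the
#' `exclusive` threshold form the mutually exclusive subset used for
#' distinct-regime comparisons.
#'
#' @param object A fitted `fire_regimes`.
#' @param newdata A `fire_series` or characteristics data frame for the
#'   target cells.
#' @param similar Similarity threshold for "similar" (default 0).
#' @param exclusive Threshold for exclusive similarity (default 24).
#' @param ... Unused.
#' @return An object of class `regime_projection`: `labels`, `exclusive`
#'   (logical), `mess` (cell x regime similarity matrix), thresholds.
#' @export
predict.fire_regimes <- function(object, newdata, similar = 0, exclusive = 24, ...) {
  chars <- if (inherits(newdata, "fire_series")) fire_characteristics(newdata) else newdata
  if (!all(CHAR_COLS %in% names(chars))) {
    stop("newdata lacks the 12 characteristic columns")
  }
  if (!"is_nlsf" %in% names(chars)) chars$is_nlsf <- assign_nlsf(chars)
  scaled <- normalise_characteristics(chars, params = object$norm)$table
  ref_tab <- object$norm$table
  ref_list <- lapply(seq_len(object$k), function(g) {
    as.matrix(ref_tab[object$labels == g, CHAR_COLS])
  })
  mess <- mess_surfaces(ref_list, as.matrix(scaled[, CHAR_COLS]))
  colnames(mess) <- paste0("regime_", seq_len(object$k))
  cls <- classify_tropics(mess, chars$is_nlsf,
    similar = similar, exclusive = exclusive
  )
  structure(list(
    labels = cls$labels, exclusive = cls$exclusive, mess = mess,
    similar = similar, exclusive_threshold = exclusive,
    characteristics = chars
  ), class = "regime_projection")
}

#' @export
print.regime_projection <- function(x, ...) {
  cat("Regime projection over", length(x$labels), "cells\n")
  tab <- table(factor(x$labels, levels = c(-1, 0, seq_len(ncol(x$mess)))))
  names(dimnames(tab)) <- NULL
  cat("  labels (-1 dissimilar, 0 NLSF):\n")
  print(tab)
  cat("  exclusive (single regime >", x$exclusive_threshold, "):",
      sum(x$exclusive), "cells\n")
  invisible(x)
}
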