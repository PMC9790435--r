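# Internal helpers shared across modules.

# The 12 clustering characteristics, in canonical column order.
CHAR_COLS <- c(
  "ba_month_mean", "ba_month_cv", "ba_year_mean", "ba_year_cv",
  "nfire_month_mean", "nfire_month_cv", "nfire_year_mean", "nfire_year_cv",
  "fsize_month_mean", "fsize_month_cv", "fsize_year_mean", "fsize_year_cv"
)

REGION_LEVELS <- c("focal", "continental", "other")

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean. Series with mean zero
#' (notably all-zero burned-area records of no-landscape-scale-fire cells)
#' return 0 rather than NaN, so downstream characteristic tables stay finite.
#'
#' @param x Numeric vector, non-empty.
#' @return A single non-negative number (0 when `mean(x) == 0` or `n == 1`).
#' @examples
#' cv(c(1, 3)) # sqrt(2)/2
#' cv(c(2, 2, 2)) # 0
#' @export
cv <- function(x) {
  if (length(x) == 0L) stop("cv(): empty input")
  if (anyNA(x)) stop("cv(): missing values not allowed")
  m <- mean(x)
  if (m == 0) return(0)
  if (length(x) == 1L) return(0)
  stats::sd(x) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness flows through this; no function leaves the global
# random state disturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% .Machine$integer.max)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions of the same cells, corrected for chance;
#' 1 means identical partitions up to relabelling, 0 is the chance level.
#' Used to score recovery of planted regime labels by the clustering.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number (at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
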