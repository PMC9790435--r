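# Independent oracles and scenario builders shared across tests. Oracles are
# deliberately naive (direct formula evaluation, O(n^3) loops) so they stay
# independent of the vectorised implementation paths they check.

# Direct piecewise MESS evaluation for a single variable and probe.
mess_oracle_var <- function(reference, point) {
  f <- 100 * sum(reference < point) / length(reference)
  rmin <- min(reference)
  rmax <- max(reference)
  if (f == 0) {
    100 * (point - rmin) / (rmax - rmin)
  } else if (f <= 50) {
    2 * f
  } else if (f < 100) {
    2 * (100 - f)
  } else {
    100 * (rmax - point) / (rmax - rmin)
  }
}

# Multivariate oracle: min over variables.
mess_oracle <- function(reference, probe) {
  min(vapply(seq_along(probe), function(j) {
    mess_oracle_var(reference[, j], probe[j])
  }, numeric(1)))
}

# Brute-force O(n^3) complete-linkage agglomeration: returns sorted merge
# heights (maximum pairwise distance between merged clusters).
complete_linkage_oracle <- function(m) {
  D <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Normal-equations least squares: coefficients, t and p values.
lm_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- xtx_inv %*% t(X1) %*% y
  resid <- y - X1 %*% beta
  df <- length(y) - ncol(X1)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * s2)
  tval <- beta / se
  list(
    coef = as.numeric(beta), t = as.numeric(tval),
    p = 2 * stats::pt(-abs(as.numeric(tval)), df)
  )
}

# A minimal single-cell fire series from 12 x Y matrices.
toy_series <- function(ba, nf = NULL, fs = NULL, cell_area = 21) {
  Y <- ncol(ba)
  if (is.null(nf)) nf <- (ba > 0) * 1
  if (is.null(fs)) fs <- ifelse(nf > 0, ba / nf, 0)
  grid <- grid_spec(1, 1, cell_area = cell_area,
    region_fractions = c(focal = 1, continental = 0, other = 0)
  )
  structure(list(
    grid = grid, years = seq_len(Y),
    burned_area = array(ba, c(1L, 12L, Y)),
    fire_count = array(nf, c(1L, 12L, Y)),
    mean_fire_size = array(fs, c(1L, 12L, Y))
  ), class = "fire_series")
}

# A characteristics data frame from a matrix of 12-dim vectors (one row per
# cell), bypassing series computation, for clustering geometry tests.
chars_from_matrix <- function(m) {
  colnames(m) <- pyromes:::CHAR_COLS
  df <- as.data.frame(m)
  df$cell_id <- seq_len(nrow(m))
  df$is_nlsf <- FALSE
  df
}

# Five mutually well-separated archetypes (crossed design: burned-area
# level x season width x fire size x interannual CV) used for diagnostics
# that need near-equidistant regimes.
simplex_archetypes <- function() {
  mk <- function(lab, total, width, size, cv) {
    regime_archetype(lab, pyromes:::seasonal_climatology(total, 8, width),
      ba_year_cv = cv, fsize_cv = 0.1, mean_fire_size = size
    )
  }
  list(
    mk(1, 3, 1, 0.3, 0.25), mk(2, 3, 9, 0.3, 0.1), mk(3, 45, 3, 0.3, 0.25),
    mk(4, 45, 9, 2.0, 0.1), mk(5, 10, 5, 2.8, 0.5)
  )
}

# One-region grid helper.
one_region_grid <- function(n_rows, n_cols, cell_area = 21) {
  grid_spec(n_rows, n_cols, cell_area = cell_area,
    region_fractions = c(focal = 1, continental = 0, other = 0)
  )
}
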