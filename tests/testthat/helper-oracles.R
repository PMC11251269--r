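# Independent oracles, kept deliberately naive: explicit design matrices,
# exhaustive enumeration, closed forms. They never share code with the
# package's implementation paths.

# ANCOVA oracle for the repeated-measures correlation: full design matrix
# with subject indicator columns plus x, solved by QR; SS_measure is the
# RSS drop when x is added to the subject-only model.
rmcorr_oracle <- function(x, y, subject_id) {
  f <- factor(subject_id)
  D <- model.matrix(~ f - 1)
  X_full <- cbind(D, x = x)
  X_red <- D
  rss <- function(X) {
    fit <- qr.coef(qr(X), y)
    sum((y - X %*% fit)^2)
  }
  rss_full <- rss(X_full)
  rss_red <- rss(X_red)
  slope <- qr.coef(qr(X_full), y)[["x"]]
  ss_measure <- rss_red - rss_full
  r <- sign(slope) * sqrt(max(0, ss_measure) / (ss_measure + rss_full))
  list(rrm = r, df = length(y) - nlevels(f) - 1L)
}

# Exhaustive robust-range oracle over a logical upper-triangular mask:
# test every interval [a, b]; longest wins, ties to larger parameter
# values (larger end, then larger start).
robust_range_oracle <- function(mask) {
  n <- ncol(mask)
  best <- NULL
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ok <- TRUE
    for (i in a:(b - 1)) for (j in (i + 1):b) if (!mask[i, j]) ok <- FALSE
    if (!ok) next
    if (is.null(best) ||
        (b - a) > (best[2] - best[1]) ||
        ((b - a) == (best[2] - best[1]) &&
         (b > best[2] || (b == best[2] && a > best[1])))) {
      best <- c(a, b)
    }
  }
  best
}

margin_oracle <- function(mask) {
  hits <- which(mask, arr.ind = TRUE)
  if (!nrow(hits)) return(NULL)
  c(min(hits[, 1]), max(hits[, 2]))
}

# Closed-form weighted least squares on design [g, 1].
wls_oracle <- function(g, y, w) {
  X <- cbind(g, 1)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# Build a radr_matrix-shaped object from a logical mask so the range
# derivations can be driven directly.
mask_matrix <- function(mask, grid) {
  n <- ncol(mask)
  idx <- which(upper.tri(mask), arr.ind = TRUE)
  tiles <- tibble::tibble(
    start = idx[, 1], end = idx[, 2],
    start_value = grid$values[idx[, 1]], end_value = grid$values[idx[, 2]],
    cv_mean = NA_real_, rrm = NA_real_, rrm_abs = NA_real_,
    robust = mask[idx]
  )
  structure(list(feature_name = "mask", grid = grid, tiles = tiles,
                 robust_mask = mask, criteria = robust_criteria()),
            class = "radr_matrix")
}

random_mask <- function(n, p = 0.4) {
  m <- matrix(FALSE, n, n)
  m[upper.tri(m)] <- runif(sum(upper.tri(m))) < p
  m
}

# Conditionally-robust range stub for aggregation tests (indices on grid).
range_stub <- function(grid, margin = NULL, robust_range = NULL) {
  iv <- function(z) if (is.null(z)) NULL else
    list(start = z[1], end = z[2],
         start_value = grid$values[z[1]], end_value = grid$values[z[2]])
  structure(list(feature_name = "stub",
                 category = if (is.null(margin)) "non_robust"
                            else "conditionally_robust",
                 robust_range = iv(robust_range), margin = iv(margin),
                 grid = grid),
            class = "radr_range")
}
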