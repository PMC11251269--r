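#' Pairwise robustness matrix for one feature
#'
#' Evaluates both robustness metrics for every start-end parameter
#' range of the grid: tile (i, j), i < j, holds the metrics computed
#' over all grid values k with i <= k <= j (the full inclusive
#' sub-range, per subject), and the robust mask applies the robust
#' criteria to each tile. An n-value grid has `choose(n, 2)`
#' off-diagonal tiles (435 / 496 / 378 for the default FBW / FBN /
#' voxel-size grids); the diagonal (a value paired with itself) is
#' never populated.
#'
#' @inheritParams feature_metrics
#' @param criteria a [robust_criteria()] object.
#' @return A `radr_matrix` object with fields `feature_name`, `grid`,
#'   `tiles` (tibble: `start`, `end` indices, `start_value`,
#'   `end_value`, `cv_mean`, `rrm`, `rrm_abs`, `robust`) and
#'   `robust_mask` (logical upper-triangular matrix).
#' @export
compute_robustness_matrix <- function(table, feature, grid,
                                      criteria = robust_criteria(),
                                      eps = 1e-8) {
  Y <- feature_value_matrix(table, feature, grid)
  x <- grid$values
  n <- length(x)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    m <- metrics_from_matrix(Y[, i:j, drop = FALSE], x[i:j], eps = eps)
    tibble(start = i, end = j,
           start_value = x[i], end_value = x[j],
           cv_mean = m$cv_mean, rrm = m$rrm, rrm_abs = m$rrm_abs,
           robust = is_robust(m, criteria))
  })
  tiles <- dplyr::bind_rows(rows)
  mask <- matrix(FALSE, n, n, dimnames = list(format(x), format(x)))
  mask[cbind(tiles$start, tiles$end)] <- tiles$robust
  structure(list(feature_name = feature, grid = grid, tiles = tiles,
                 robust_mask = mask, criteria = criteria),
            class = "radr_matrix")
}

#' @export
print.radr_matrix <- function(x, ...) {
  cat(sprintf("<radr_matrix> %s (%s/%s): %d tiles, %d robust\n",
              x$feature_name, x$grid$scheme, x$grid$algorithm,
              nrow(x$tiles), sum(x$tiles$robust)))
  invisible(x)
}

#' Robust range of a robustness matrix
#'
#' The robust range is the largest closed square region of the matrix
#' containing only robust tiles: the longest index interval `[a, b]`,
#' `b > a`, such that every off-diagonal tile (i, j) with
#' `a <= i < j <= b` is robust. The contiguity requirement excludes
#' isolated tiles with spuriously favourable metrics. Ties between
#' equal-length intervals are broken toward the interval with the
#' larger parameter values. Returns `NULL` when no interval of at least
#' two grid values is fully robust.
#'
#' @param matrix a `radr_matrix` from [compute_robustness_matrix()].
#' @return `NULL`, or a list with `start`, `end` (grid indices) and
#'   `start_value`, `end_value` (parameter units).
#' @export
derive_robust_range <- function(matrix) {
  interval_from_mask(matrix$robust_mask, matrix$grid)
}

# Largest fully-robust interval of a logical upper-triangular mask;
# ties -> larger parameter values (larger end, then larger start).
interval_from_mask <- function(mask, grid) {
  n <- ncol(mask)
  # all_ok[a, b]: every tile in [a, b] robust. Build by recurrence:
  # [a, b] ok iff [a, b-1] ok, [a+1, b] ok and (a, b) robust.
  all_ok <- matrix(FALSE, n, n)
  for (b in 2:n) {
    for (a in (b - 1):1) {
      all_ok[a, b] <- mask[a, b] &&
        (b - a == 1L || (all_ok[a, b - 1L] && all_ok[a + 1L, b]))
    }
  }
  idx <- which(all_ok, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  len <- idx[, 2L] - idx[, 1L]
  best <- idx[order(-len, -idx[, 2L], -idx[, 1L])[1L], ]
  list(start = unname(best[1L]), end = unname(best[2L]),
       start_value = grid$values[best[1L]], end_value = grid$values[best[2L]])
}

#' Robustness margin of a robustness matrix
#'
#' The margin is the non-contiguous counterpart of the robust range:
#' the interval spanned by the two outermost parameter values touched
#' by at least one robust tile (diagonal excluded) — the smallest start
#' index and the largest end index over all robust tiles. `NULL` when
#' no tile is robust.
#'
#' @inheritParams derive_robust_range
#' @return `NULL`, or a list with `start`, `end`, `start_value`,
#'   `end_value`.
#' @export
derive_margin <- function(matrix) {
  rt <- matrix$tiles[matrix$tiles$robust, ]
  if (!nrow(rt)) return(NULL)
  a <- min(rt$start); b <- max(rt$end)
  list(start = a, end = b,
       start_value = matrix$grid$values[a], end_value = matrix$grid$values[b])
}

#' Conditional-robustness categorisation
#'
#' A feature that failed the robust criteria on the full grid is
#' *conditionally robust* when its matrix has at least one robust tile,
#' and *non-robust* otherwise. Bundles the robust range (contiguous)
#' nested inside the robustness margin (outermost); together they make
#' up the feature's robustness range.
#'
#' @inheritParams derive_robust_range
#' @return A `radr_range` object with `feature_name`, `category`
#'   (`"conditionally_robust"` / `"non_robust"`), `robust_range`,
#'   `margin` and the `grid`.
#' @export
classify_conditional <- function(matrix) {
  margin <- derive_margin(matrix)
  structure(
    list(feature_name = matrix$feature_name,
         category = if (is.null(margin)) "non_robust" else "conditionally_robust",
         robust_range = derive_robust_range(matrix),
         margin = margin, grid = matrix$grid),
    class = "radr_range"
  )
}

#' @export
print.radr_range <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "none" else
    sprintf("[%s, %s]", format(iv$start_value), format(iv$end_value))
  cat(sprintf("<radr_range> %s: %s; robust range %s, margin %s\n",
              x$feature_name, x$category, fmt(x$robust_range), fmt(x$margin)))
  invisible(x)
}

#' Global robustness range for a scenario
#'
#' A radiomics study extracts all features at one common setting, so
#' the per-feature robustness ranges are aggregated: for every grid
#' value, count the conditionally robust features whose robustness
#' margin contains it (and, as a second variant, whose robust range
#' contains it), then take the longest contiguous run of grid values
#' whose margin count reaches the cut-off of at least half the
#' conditionally robust features (`ceiling(n / 2)`). Run-length ties
#' prefer the run containing the histogram maximum, then the run with
#' the larger parameter values.
#'
#' @param ranges list of `radr_range` objects (from
#'   [classify_conditional()]); non-robust entries are ignored.
#' @param grid the scenario [parameter_grid()].
#' @return A `radr_global_range` object: `n_conditionally_robust`,
#'   `cutoff`, `histogram` (tibble with per-grid-value counts for both
#'   variants), `global_range` (interval or `NULL`), and
#'   `argmax_values` per variant.
#' @export
aggregate_global_range <- function(ranges, grid) {
  ranges <- Filter(function(r) r$category == "conditionally_robust", ranges)
  if (!length(ranges)) abort("no conditionally robust features to aggregate")
  n <- length(grid$values)
  count_hits <- function(get) {
    counts <- integer(n)
    for (r in ranges) {
      iv <- get(r)
      if (!is.null(iv)) counts[iv$start:iv$end] <- counts[iv$start:iv$end] + 1L
    }
    counts
  }
  margin_counts <- count_hits(function(r) r$margin)
  range_counts <- count_hits(function(r) r$robust_range)
  cutoff <- as.integer(ceiling(length(ranges) / 2))

  global <- longest_qualifying_run(margin_counts >= cutoff, margin_counts)
  if (!is.null(global)) {
    global$start_value <- grid$values[global$start]
    global$end_value <- grid$values[global$end]
  }
  structure(
    list(scheme = grid$scheme, algorithm = grid$algorithm, grid = grid,
         n_conditionally_robust = length(ranges), cutoff = cutoff,
         histogram = tibble(parameter_value = grid$values,
                            margin_count = margin_counts,
                            robust_range_count = range_counts),
         global_range = global,
         argmax_values = list(
           margin = grid$values[margin_counts == max(margin_counts)],
           robust_range = if (max(range_counts) > 0)
             grid$values[range_counts == max(range_counts)] else numeric())),
    class = "radr_global_range"
  )
}

# Longest run of TRUE in `ok`; ties -> run containing max(counts), then
# larger parameter values (later run).
longest_qualifying_run <- function(ok, counts) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])
  peaks <- which(counts == max(counts))
  runs$has_peak <- vapply(seq_len(nrow(runs)), function(i)
    any(peaks >= runs$start[i] & peaks <= runs$end[i]), logical(1))
  runs <- runs[order(-runs$len, -runs$has_peak, -runs$end), ]
  list(start = runs$start[1L], end = runs$end[1L])
}

#' @export
print.radr_global_range <- function(x, ...) {
  gr <- x$global_range
  cat(sprintf(
    "<radr_global_range> %s/%s: %d conditionally robust, cutoff %d, global range %s\n",
    x$scheme, x$algorithm, x$n_conditionally_robust, x$cutoff,
    if (is.null(gr)) "none" else
      sprintf("[%s, %s] %s", format(gr$start_value), format(gr$end_value),
              x$grid$unit)))
  invisible(x)
}
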