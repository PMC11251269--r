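#' Parameter grids for image-processing scenarios
#'
#' A parameter grid is the ordered set of values of a single
#' image-processing parameter explored in one scenario: intensity bin
#' width in SUV (fixed bin width, `"FBW"`), number of intensity bins
#' (fixed bin number, `"FBN"`), or isotropic voxel size in mm (one grid
#' per interpolator). Grids are constructed from integer step counts and
#' scaled, so every value equals `start + k * step` exactly and tile
#' indexing is never defeated by accumulated floating-point step error.
#'
#' @param scheme `"discretisation"` or `"interpolation"`.
#' @param algorithm one of `"FBW"`, `"FBN"` (discretisation) or
#'   `"linear"`, `"nearest_neighbour"`, `"b_spline"`, `"gaussian"`
#'   (interpolation).
#' @param values strictly increasing numeric vector of parameter values.
#'   If `NULL`, the default study grid for `algorithm` is built:
#'   bin widths 0.05 to 1.50 SUV in 0.05 SUV steps (30 values), bin
#'   numbers 8 to 256 in steps of 8 (32 values), or voxel sizes 0.8 to
#'   3.5 mm in 0.1 mm steps (28 values).
#' @param label free-text label; defaults to the algorithm name.
#'
#' @return A `radr_grid` object: a list with elements `scheme`,
#'   `algorithm`, `values`, `label`, `unit` (`"SUV"`, `"bins"` or
#'   `"mm"`) and `digits` (the canonical decimal precision used when
#'   matching feature-table parameter values to the grid).
#' @examples
#' g <- parameter_grid("discretisation", "FBW")
#' length(g$values)   # 30
#' range(g$values)    # 0.05 1.50
#' @export
parameter_grid <- function(scheme, algorithm, values = NULL, label = algorithm) {
  scheme <- match.arg(scheme, c("discretisation", "interpolation"))
  algorithm <- match.arg(algorithm, names(radr_algorithms))
  if (radr_algorithms[[algorithm]]$scheme != scheme) {
    abort(sprintf("algorithm '%s' belongs to the '%s' scheme, not '%s'",
                  algorithm, radr_algorithms[[algorithm]]$scheme, scheme))
  }
  info <- radr_algorithms[[algorithm]]
  if (is.null(values)) values <- info$default()
  if (!is.numeric(values) || length(values) < 2L) {
    abort("a parameter grid needs at least 2 numeric values")
  }
  if (any(!is.finite(values)) || any(diff(values) <= 0)) {
    abort("grid values must be finite and strictly increasing")
  }
  if (algorithm == "FBN" && any(values != as.integer(values) | values <= 0)) {
    abort("FBN grid values must be positive integers (bin counts)")
  }
  structure(
    list(scheme = scheme, algorithm = algorithm,
         values = as.numeric(values), label = label,
         unit = info$unit, digits = info$digits),
    class = "radr_grid"
  )
}

# scheme membership, units, canonical rounding precision and default grid
# builders (integer step counts, then scaled).
radr_algorithms <- list(
  FBW = list(scheme = "discretisation", unit = "SUV", digits = 2L,
             default = function() (1:30) * 5 / 100),
  FBN = list(scheme = "discretisation", unit = "bins", digits = 0L,
             default = function() (1:32) * 8),
  linear = list(scheme = "interpolation", unit = "mm", digits = 1L,
                default = function() (8:35) / 10),
  nearest_neighbour = list(scheme = "interpolation", unit = "mm", digits = 1L,
                           default = function() (8:35) / 10),
  b_spline = list(scheme = "interpolation", unit = "mm", digits = 1L,
                  default = function() (8:35) / 10),
  gaussian = list(scheme = "interpolation", unit = "mm", digits = 1L,
                  default = function() (8:35) / 10)
)

#' @export
print.radr_grid <- function(x, ...) {
  cat(sprintf("<radr_grid> %s / %s: %d values from %s to %s %s\n",
              x$scheme, x$algorithm, length(x$values),
              format(x$values[1]), format(x$values[length(x$values)]),
              x$unit))
  invisible(x)
}

#' Default scenario grids
#'
#' Enumerates the six default scenarios: FBW and FBN discretisation plus
#' the four interpolators (linear, nearest-neighbour, B-spline,
#' Gaussian), whose parameter counts sum to 30 + 32 + 4 x 28 = 174.
#'
#' @return A named list of six [parameter_grid()] objects.
#' @examples
#' sum(lengths(lapply(enumerate_default_scenarios(), `[[`, "values")))  # 174
#' @export
enumerate_default_scenarios <- function() {
  algs <- names(radr_algorithms)
  setNames(
    lapply(algs, function(a) parameter_grid(radr_algorithms[[a]]$scheme, a)),
    algs
  )
}

#' Number of start-end range tiles for a grid
#'
#' Every ordered pair of distinct grid values (start < end) defines one
#' candidate parameter range, so an n-value grid yields `choose(n, 2)`
#' off-diagonal tiles: 435 for the 30-value bin-width grid, 496 for the
#' 32-value bin-number grid, and 378 for each 28-value voxel-size grid.
#'
#' @param n_parameters number of grid values (>= 2).
#' @return Integer tile count.
#' @export
n_range_tiles <- function(n_parameters) {
  if (!is.numeric(n_parameters) || length(n_parameters) != 1L ||
      n_parameters < 2 || n_parameters != round(n_parameters)) {
    abort("n_parameters must be a single integer >= 2")
  }
  as.integer(choose(n_parameters, 2))
}

# Canonical rounding to the grid's decimal precision; used everywhere a
# feature-table parameter value is matched against grid values so that
# matching is exact, never nearest-neighbour.
canonicalise_parameter <- function(x, grid) round(x, grid$digits)

# Index of each value of x in the grid after canonical rounding; NA where
# a value is not on the grid.
grid_index <- function(x, grid) {
  match(canonicalise_parameter(x, grid), canonicalise_parameter(grid$values, grid))
}
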