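#' Feature profiles for synthetic cohorts
#'
#' Three response shapes cover the behaviours the pipeline must
#' distinguish: `profile_flat()` — no dependency on the parameter
#' (a robust feature); `profile_dependency()` — one of the eight
#' invertible forms over the whole grid (a correctable feature);
#' `profile_plateau()` — the dependency below a breakpoint, flat above
#' it and continuous at it (a conditionally robust feature whose
#' robustness range sits at the large-parameter end, as observed for
#' real PET features whose response stabilises at coarse bin widths or
#' voxel sizes).
#'
#' @param beta baseline feature value (intercept).
#' @param function_id one of [dependency_functions].
#' @param alpha dependency coefficient.
#' @param scale_s log-argument multiplier (see [default_scale()]).
#' @param breakpoint parameter value above which the response is flat;
#'   must lie inside the grid.
#' @return A profile list consumed by [cohort_spec()].
#' @export
profile_flat <- function(beta = 1) {
  list(kind = "flat", alpha = 0, beta = beta,
       function_id = "lin", scale_s = 1, breakpoint = NULL)
}

#' @rdname profile_flat
#' @export
profile_dependency <- function(function_id, alpha, beta, scale_s = 1) {
  function_id <- match.arg(function_id, dependency_functions)
  list(kind = "dependency", alpha = alpha, beta = beta,
       function_id = function_id, scale_s = scale_s, breakpoint = NULL)
}

#' @rdname profile_flat
#' @export
profile_plateau <- function(breakpoint, function_id, alpha, beta,
                            scale_s = 1) {
  function_id <- match.arg(function_id, dependency_functions)
  list(kind = "plateau", alpha = alpha, beta = beta,
       function_id = function_id, scale_s = scale_s, breakpoint = breakpoint)
}

#' Synthetic cohort specification
#'
#' Defines a seeded cohort of subjects whose feature-response curves
#' over a parameter grid follow designed profiles with subject-level
#' random effects and additive Gaussian noise:
#' `value(i, x) = (alpha + a_i) g(x) + (beta + b_i) + e`, with
#' `a_i ~ N(0, (slope_sd * alpha)^2)`, `b_i ~ N(0, intercept_sd^2)`
#' and `e ~ N(0, noise_sd(x)^2)` (`noise_sd` scalar, or one value per
#' grid value for heteroscedastic noise). Identical spec and seed give
#' bit-identical output.
#'
#' @param grid a [parameter_grid()].
#' @param features named list of profiles ([profile_flat()] and
#'   friends); names become feature names.
#' @param n_subjects cohort size (>= 2).
#' @param intercept_sd SD of the per-subject intercept shift, feature
#'   units.
#' @param slope_sd SD of the per-subject slope perturbation as a
#'   fraction of `alpha`.
#' @param noise_sd additive noise SD, feature units; scalar or one per
#'   grid value.
#' @param seed integer RNG seed.
#' @return A `radr_cohort_spec` list.
#' @export
cohort_spec <- function(grid, features, n_subjects = 30,
                        intercept_sd = 0.1, slope_sd = 0.05,
                        noise_sd = 0.01, seed = 1L) {
  if (n_subjects < 2) abort("n_subjects must be >= 2")
  if (any(noise_sd < 0)) abort("noise_sd must be >= 0")
  if (!length(noise_sd) %in% c(1L, length(grid$values))) {
    abort("noise_sd must be a scalar or one value per grid value")
  }
  if (is.null(names(features)) || any(names(features) == "")) {
    abort("features must be a named list of profiles")
  }
  for (f in names(features)) {
    p <- features[[f]]
    if (identical(p$kind, "plateau") &&
        (p$breakpoint <= grid$values[1] ||
         p$breakpoint > grid$values[length(grid$values)])) {
      abort(sprintf("breakpoint of '%s' must lie inside the grid", f))
    }
  }
  structure(list(grid = grid, features = features,
                 n_subjects = as.integer(n_subjects),
                 intercept_sd = intercept_sd, slope_sd = slope_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "radr_cohort_spec")
}

#' Generate a synthetic cohort feature table
#'
#' Draws the cohort defined by a [cohort_spec()]. For each feature the
#' per-subject slope and intercept effects are drawn before the noise,
#' so refining the grid leaves the subject effects unchanged. Plateau
#' profiles evaluate the dependency at `min(x, breakpoint)`, making
#' the curve continuous at the breakpoint.
#'
#' @param spec a `radr_cohort_spec`.
#' @return A [feature_table()] tibble.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "radr_cohort_spec"))
  grid <- spec$grid
  x <- grid$values
  n <- spec$n_subjects
  noise <- rep(spec$noise_sd, length.out = length(x))
  subjects <- sprintf("S%03d", seq_len(n))
  set.seed(spec$seed)
  out <- purrr::imap(spec$features, function(p, fname) {
    a <- rnorm(n, 0, spec$slope_sd * abs(p$alpha))
    b <- rnorm(n, 0, spec$intercept_sd)
    eff_x <- if (identical(p$kind, "plateau")) pmin(x, p$breakpoint) else x
    g <- if (p$alpha == 0) rep(0, length(x))
         else dependency_g(p$function_id, eff_x, p$scale_s)
    mu <- outer(p$alpha + a, g) + (p$beta + b)  # n x n_par
    eps <- matrix(rnorm(n * length(x), 0, rep(noise, each = n)), n, length(x))
    vals <- mu + eps
    tibble(
      subject_id = rep(subjects, times = length(x)),
      feature_name = fname,
      scheme = grid$scheme, algorithm = grid$algorithm,
      parameter_value = rep(x, each = n),
      value = as.vector(vals)
    )
  })
  feature_table(dplyr::bind_rows(out))
}
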