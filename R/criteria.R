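#' Robustness criteria
#'
#' A feature is *robust* over a parameter range when its mean
#' within-subject percentage coefficient of variation and the magnitude
#' of its repeated-measures correlation with the parameter both fall
#' strictly below empirical thresholds: CV_mean < 10% and |r_rm| < 0.5
#' by default.
#'
#' @param cv_threshold CV_mean threshold in percent (> 0).
#' @param rrm_threshold |r_rm| threshold, unitless in (0, 1].
#' @return A `radr_criteria` list.
#' @export
robust_criteria <- function(cv_threshold = 10, rrm_threshold = 0.5) {
  if (!is.numeric(cv_threshold) || cv_threshold <= 0 ||
      !is.numeric(rrm_threshold) || rrm_threshold <= 0) {
    abort("both thresholds must be strictly positive")
  }
  structure(list(cv_threshold = as.numeric(cv_threshold),
                 rrm_threshold = as.numeric(rrm_threshold)),
            class = "radr_criteria")
}

#' Apply the robust criteria to a set of metrics
#'
#' Both inequalities are strict: a feature sitting exactly on a
#' threshold (CV_mean = 10%, |r_rm| = 0.5) is not robust.
#'
#' @param metrics a `radr_metrics` object from [feature_metrics()], or
#'   anything with `cv_mean` and `rrm_abs` components.
#' @param criteria a [robust_criteria()] object.
#' @return `TRUE` iff `cv_mean < cv_threshold` and
#'   `rrm_abs < rrm_threshold`.
#' @export
is_robust <- function(metrics, criteria = robust_criteria()) {
  isTRUE(metrics$cv_mean < criteria$cv_threshold) &&
    isTRUE(metrics$rrm_abs < criteria$rrm_threshold)
}

#' Read / write a flat YAML pipeline configuration
#'
#' The configuration holds the robust thresholds, the random seed and
#' optional per-algorithm grid overrides (`grids: {FBW: [..], ...}`),
#' giving a single file that reproduces a run.
#'
#' @param path YAML file path.
#' @return A list with elements `criteria` ([robust_criteria()]),
#'   `seed` and `grids` (named list of [parameter_grid()]).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  crit <- robust_criteria(
    cv_threshold = cfg$cv_threshold %||% 10,
    rrm_threshold = cfg$rrm_threshold %||% 0.5
  )
  grids <- enumerate_default_scenarios()
  for (alg in names(cfg$grids %||% list())) {
    grids[[alg]] <- parameter_grid(radr_algorithms[[alg]]$scheme, alg,
                                   values = as.numeric(cfg$grids[[alg]]))
  }
  list(criteria = crit, seed = cfg$seed %||% 1L, grids = grids)
}

#' @param config a list as returned by [read_pipeline_config()].
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- list(
    cv_threshold = config$criteria$cv_threshold,
    rrm_threshold = config$criteria$rrm_threshold,
    seed = config$seed,
    grids = lapply(config$grids, `[[`, "values")
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
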