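#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy robustness metrics
#'
#' One row per metrics object: CV_mean (percent), signed and absolute
#' repeated-measures correlation with its 95% CI, degrees of freedom,
#' counts, and any degeneracy flags (collapsed with `;`).
#'
#' @param x a `radr_metrics` object.
#' @param ... unused.
#' @return A one-row tibble.
#' @method tidy radr_metrics
#' @export
tidy.radr_metrics <- function(x, ...) {
  tibble(
    feature_name = x$feature_name %||% NA_character_,
    algorithm = x$algorithm %||% NA_character_,
    cv_mean = x$cv_mean, rrm = x$rrm, rrm_abs = x$rrm_abs,
    rrm_ci_low = x$ci_low, rrm_ci_high = x$ci_high, df = x$df,
    n_subjects = x$n_subjects, n_parameters = x$n_parameters,
    n_cv_degenerate = x$n_cv_degenerate,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname tidy.radr_metrics
#' @method glance radr_metrics
#' @export
glance.radr_metrics <- function(x, ...) tidy.radr_metrics(x, ...)

#' Tidy a robustness matrix into its tiles
#'
#' @param x a `radr_matrix` object.
#' @param ... unused.
#' @return A tibble with one row per start-end tile.
#' @method tidy radr_matrix
#' @export
tidy.radr_matrix <- function(x, ...) {
  dplyr::mutate(x$tiles, feature_name = x$feature_name,
                algorithm = x$grid$algorithm, .before = 1L)
}

#' @rdname tidy.radr_matrix
#' @method glance radr_matrix
#' @export
glance.radr_matrix <- function(x, ...) {
  tibble(feature_name = x$feature_name, algorithm = x$grid$algorithm,
         n_tiles = nrow(x$tiles), n_robust_tiles = sum(x$tiles$robust))
}

#' Tidy a robustness range
#'
#' @param x a `radr_range` object.
#' @param ... unused.
#' @return A one-row tibble with the category and both intervals in
#'   parameter units (`NA` where absent).
#' @method tidy radr_range
#' @export
tidy.radr_range <- function(x, ...) {
  iv <- function(z, f) if (is.null(z)) NA_real_ else z[[f]]
  tibble(
    feature_name = x$feature_name, algorithm = x$grid$algorithm,
    category = x$category,
    robust_range_start = iv(x$robust_range, "start_value"),
    robust_range_end = iv(x$robust_range, "end_value"),
    margin_start = iv(x$margin, "start_value"),
    margin_end = iv(x$margin, "end_value")
  )
}

#' Tidy a global robustness range
#'
#' `tidy()` returns the per-grid-value histogram (margin and
#' robust-range variants) with the cutoff and membership of the chosen
#' global range; `glance()` the one-row summary.
#'
#' @param x a `radr_global_range` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy radr_global_range
#' @export
tidy.radr_global_range <- function(x, ...) {
  gr <- x$global_range
  dplyr::mutate(
    x$histogram,
    scheme = x$scheme, algorithm = x$algorithm,
    cutoff = x$cutoff,
    in_global_range = !is.null(gr) &
      .data$parameter_value >= (if (is.null(gr)) Inf else gr$start_value) &
      .data$parameter_value <= (if (is.null(gr)) -Inf else gr$end_value)
  )
}

#' @rdname tidy.radr_global_range
#' @method glance radr_global_range
#' @export
glance.radr_global_range <- function(x, ...) {
  gr <- x$global_range
  tibble(
    scheme = x$scheme, algorithm = x$algorithm,
    n_conditionally_robust = x$n_conditionally_robust, cutoff = x$cutoff,
    global_start = if (is.null(gr)) NA_real_ else gr$start_value,
    global_end = if (is.null(gr)) NA_real_ else gr$end_value,
    argmax_margin = paste(format(x$argmax_values$margin), collapse = ";"),
    argmax_robust_range = paste(format(x$argmax_values$robust_range),
                                collapse = ";")
  )
}

#' Tidy a fitted dependency model
#'
#' `tidy()` gives the coefficient table (`alpha`, `beta`); `glance()`
#' the fit summary (function id, AIC, convergence).
#'
#' @param x a `radr_model` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy radr_model
#' @export
tidy.radr_model <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @rdname tidy.radr_model
#' @method glance radr_model
#' @export
glance.radr_model <- function(x, ...) {
  tibble(function_id = x$function_id, alpha = x$alpha, beta = x$beta,
         scale_s = x$scale_s, aic = x$aic, n_points = x$n_points,
         converged = x$converged, iterations = x$iterations)
}

#' Tidy a correction result
#'
#' One row per corrected feature: the eight per-function AICs
#' (`aic_lin` ... `aic_invlog`), the selected model and coefficients,
#' CV_mean and |r_rm| (with CIs) before and after correction, the
#' Wilcoxon p-value, the CI-overlap outcome, the metric deltas and the
#' correctability category.
#'
#' @param x a `radr_correction` object.
#' @param ... unused.
#' @return A one-row tibble.
#' @method tidy radr_correction
#' @export
tidy.radr_correction <- function(x, ...) {
  aics <- setNames(rep(NA_real_, length(dependency_functions)),
                   paste0("aic_", dependency_functions))
  for (f in x$all_fits %||% list()) aics[paste0("aic_", f$function_id)] <- f$aic
  b <- x$metrics_before; a <- x$metrics_after
  dplyr::bind_cols(
    tibble(feature_name = x$feature_name, scheme = x$scheme,
           algorithm = x$algorithm),
    as_tibble(as.list(aics)),
    tibble(
      best_function = if (is.null(x$best_model)) NA_character_
                      else x$best_model$function_id,
      alpha = if (is.null(x$best_model)) NA_real_ else x$best_model$alpha,
      beta = if (is.null(x$best_model)) NA_real_ else x$best_model$beta,
      cv_mean_before = b$cv_mean,
      cv_mean_after = if (is.null(a)) NA_real_ else a$cv_mean,
      rrm_abs_before = b$rrm_abs,
      rrm_abs_after = if (is.null(a)) NA_real_ else a$rrm_abs,
      rrm_ci_low_before = b$ci_low, rrm_ci_high_before = b$ci_high,
      rrm_ci_low_after = if (is.null(a)) NA_real_ else a$ci_low,
      rrm_ci_high_after = if (is.null(a)) NA_real_ else a$ci_high,
      wilcoxon_p = x$wilcoxon_p, ci_overlap = x$ci_overlap,
      delta_cv = x$delta_cv, delta_rrm = x$delta_rrm,
      category = x$category, reason = x$reason %||% NA_character_
    )
  )
}

#' @rdname tidy.radr_correction
#' @method glance radr_correction
#' @export
glance.radr_correction <- function(x, ...) {
  tibble(feature_name = x$feature_name, algorithm = x$algorithm,
         category = x$category,
         best_function = if (is.null(x$best_model)) NA_character_
                         else x$best_model$function_id,
         wilcoxon_p = x$wilcoxon_p, delta_cv = x$delta_cv,
         delta_rrm = x$delta_rrm)
}

#' Tidy a scenario report
#'
#' `tidy()` returns the per-feature category rows; `glance()` the
#' scenario-level counts.
#'
#' @param x a `radr_report` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy radr_report
#' @export
tidy.radr_report <- function(x, ...) {
  dplyr::mutate(x$features, scheme = x$scheme, algorithm = x$algorithm,
                .before = 1L)
}

#' @rdname tidy.radr_report
#' @method glance radr_report
#' @export
glance.radr_report <- function(x, ...) {
  dplyr::bind_cols(tibble(scheme = x$scheme, algorithm = x$algorithm),
                   as_tibble(x$counts))
}
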