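#' The eight candidate dependency functions
#'
#' The cohort-level dependency of a feature on the processing parameter
#' x is modelled as `f(x) = alpha * g(x) + beta` with g drawn from
#' eight invertible forms, in this canonical order: `lin` (x), `quad`
#' (x^2), `cub` (x^3), `inv` (1/x), `inv2` (1/x^2), `inv3` (1/x^3),
#' `log` (log(s*x)) and `invlog` (1/log(s*x)). The multiplier `s`
#' applies to the log-family functions only and exists to keep the
#' log argument away from 1 (where log = 0 breaks the inverse form):
#' bin widths are multiplied by 100 and voxel sizes by 10; bin numbers
#' (>= 8) need no scaling (`s = 1`).
#'
#' @format A character vector of the eight function ids in canonical
#'   order.
#' @export
dependency_functions <- c("lin", "quad", "cub", "inv", "inv2", "inv3",
                          "log", "invlog")

# g(x) for a function id; s applies only to the log family.
dependency_g <- function(function_id, x, scale_s = 1) {
  switch(function_id,
    lin = x, quad = x^2, cub = x^3,
    inv = 1 / x, inv2 = 1 / x^2, inv3 = 1 / x^3,
    log = log(scale_s * x),
    invlog = 1 / log(scale_s * x),
    abort(sprintf("unknown function_id '%s'", function_id)))
}

#' Default log-argument multiplier for a grid
#'
#' 100 for bin-width grids (SUV), 10 for voxel-size grids (mm), 1 for
#' bin-number grids.
#'
#' @param grid a [parameter_grid()].
#' @return The scale multiplier.
#' @export
default_scale <- function(grid) {
  switch(grid$unit, SUV = 100, mm = 10, 1)
}

#' Fit one dependency function to a cohort mean curve
#'
#' Robust regression of the per-grid-value cohort mean feature values
#' on `g(x)` by iteratively reweighted least squares: Huber
#' downweighting (tuning constant 1.345) combined multiplicatively
#' with intrinsic weights, supplied as the reciprocal of the feature
#' variance across subjects at each grid value. Convergence when the
#' coefficient change falls below 1e-8 or after 50 iterations. The AIC
#' is computed from the intrinsically weighted Gaussian log-likelihood
#' at the converged fit, `n * log(wRSS / n) + 2k` with `k = 3` (alpha,
#' beta, noise scale) — constant across candidates, so only relative
#' values matter for selection.
#'
#' @param x parameter values (>= 4 grid points).
#' @param y cohort mean feature value at each `x`.
#' @param weights intrinsic weights (reciprocal cross-subject
#'   variances), finite and positive.
#' @param function_id one of [dependency_functions].
#' @param scale_s log-argument multiplier (see [default_scale()]).
#' @param huber_c Huber tuning constant.
#' @param tol,max_iter IRLS convergence controls.
#' @return A `radr_model` list: `function_id`, `alpha`, `beta`,
#'   `scale_s`, `aic`, `n_points`, `converged`, `iterations`.
#' @examples
#' x <- (1:30) / 10
#' fit_dependency(x, 2 / x + 5, rep(1, 30), "inv")[c("alpha", "beta")]
#' @export
fit_dependency <- function(x, y, weights, function_id, scale_s = 1,
                           huber_c = 1.345, tol = 1e-8, max_iter = 50L) {
  function_id <- match.arg(function_id, dependency_functions)
  n <- length(x)
  if (n < 4L) abort("dependency fits need at least 4 grid points")
  if (length(y) != n || length(weights) != n) {
    abort("x, y and weights must have equal length")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("intrinsic weights must be finite and positive")
  }
  g <- dependency_g(function_id, x, scale_s)
  if (any(!is.finite(g))) {
    return(radr_model(function_id, NA, NA, scale_s, Inf, n, FALSE, 0L))
  }
  # transform to a homoscedastic problem with the intrinsic weights,
  # then Huber-IRLS on the standardised residuals
  sw <- sqrt(weights)
  X <- cbind(alpha = g * sw, beta = sw)
  ys <- y * sw
  if (sd(g) < 1e-12) {  # singular design: g constant on the grid
    return(radr_model(function_id, NA, NA, scale_s, Inf, n, FALSE, 0L))
  }
  beta_hat <- qr.coef(qr(X), ys)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- ys - X %*% beta_hat
    sigma <- median(abs(r)) / 0.6745
    if (sigma < 1e-12) { converged <- TRUE; break }
    w_h <- pmin(1, huber_c * sigma / abs(as.vector(r)))
    swh <- sqrt(w_h)
    new_beta <- qr.coef(qr(X * swh), ys * swh)
    if (max(abs(new_beta - beta_hat)) < tol) {
      beta_hat <- new_beta; converged <- TRUE; break
    }
    beta_hat <- new_beta
  }
  fitted <- beta_hat[1L] * g + beta_hat[2L]
  wrss <- sum(weights * (y - fitted)^2)
  aic <- n * log(wrss / n) + 2 * 3
  radr_model(function_id, unname(beta_hat[1L]), unname(beta_hat[2L]),
             scale_s, aic, n, converged, iter)
}

radr_model <- function(function_id, alpha, beta, scale_s, aic, n_points,
                       converged, iterations) {
  structure(list(function_id = function_id, alpha = alpha, beta = beta,
                 scale_s = scale_s, aic = aic, n_points = n_points,
                 converged = converged, iterations = iterations),
            class = "radr_model")
}

#' @export
print.radr_model <- function(x, ...) {
  cat(sprintf("<radr_model> %s: alpha = %.6g, beta = %.6g, AIC = %.4g%s\n",
              x$function_id, x$alpha, x$beta, x$aic,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Fit the full dependency library for one feature
#'
#' Computes the cohort mean curve (mean across subjects at each grid
#' value) and the intrinsic weights (reciprocal cross-subject
#' variances, floored at `var_floor` to avoid infinite weights at
#' grid values where subjects agree exactly), then fits all eight
#' dependency functions.
#'
#' @inheritParams feature_metrics
#' @param scale_s log-argument multiplier; defaults to
#'   [default_scale()] for the grid.
#' @param var_floor lower bound for cross-subject variances.
#' @return A named list of eight `radr_model` objects in canonical
#'   order.
#' @export
fit_dependency_library <- function(table, feature, grid,
                                   scale_s = default_scale(grid),
                                   var_floor = 1e-12) {
  Y <- feature_value_matrix(table, feature, grid)
  y <- colMeans(Y)
  v <- apply(Y, 2L, var)
  n_floored <- sum(v < var_floor)
  if (n_floored) {
    radr_log("%s: %d grid value(s) with cross-subject variance below %g (floored)",
             feature, n_floored, var_floor)
  }
  w <- 1 / pmax(v, var_floor)
  setNames(
    lapply(dependency_functions, function(fid)
      fit_dependency(grid$values, y, w, fid, scale_s = scale_s)),
    dependency_functions
  )
}

#' Select the best dependency model by AIC
#'
#' The converged fit with the lowest AIC wins; exact ties are broken
#' by the canonical function order ([dependency_functions]).
#'
#' @param fits list of `radr_model` objects.
#' @return The winning `radr_model`, or `NULL` when no fit converged.
#' @export
select_best_model <- function(fits) {
  fits <- fits[order(match(vapply(fits, `[[`, "", "function_id"),
                           dependency_functions))]
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$alpha),
               logical(1))
  if (!any(ok)) return(NULL)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  aics[!ok] <- Inf
  fits[[which.min(aics)]]  # which.min takes the first minimum: canonical order
}

#' Apply the rearranged-form correction
#'
#' Removes the fitted dependency by inverting the best model for every
#' subject: `corrected(x) = (f(x) - beta) / g(x)`, with the
#' cohort-level `beta` shared by all subjects. For data following
#' `alpha * g(x) + beta` exactly, the corrected series is the constant
#' `alpha`. The corrected table is tagged (attribute `corrected`) and
#' a tagged table is refused as input, since the correction is not
#' idempotent.
#'
#' @inheritParams feature_metrics
#' @param model the selected `radr_model`.
#' @return The scenario slice for `feature` with corrected values,
#'   tagged `corrected = TRUE`.
#' @export
apply_correction <- function(table, feature, grid, model) {
  if (isTRUE(attr(table, "corrected"))) {
    abort("table is already corrected; the correction is not idempotent")
  }
  if (!isTRUE(model$converged)) abort("cannot correct with a non-converged model")
  slice <- require_complete(table, grid, features = feature)
  g <- dependency_g(model$function_id, slice$parameter_value, model$scale_s)
  if (any(abs(g) < 1e-12)) {
    abort("g(x) vanishes at a grid value; correction undefined (check scale_s)")
  }
  slice$value <- (slice$value - model$beta) / g
  attr(slice, "corrected") <- TRUE
  slice
}

#' Evaluate a correction and categorise correctability
#'
#' Compares the robustness metrics before and after correction. The
#' per-subject CVs are compared with a two-sided paired Wilcoxon
#' signed-rank test, and the 95% CIs of |r_rm| before and after are
#' checked for overlap. The correction is *statistically significant*
#' when p < 0.05, the CIs do not overlap, and both metrics decreased.
#' A significantly corrected feature is *correctable* if the corrected
#' metrics satisfy the robust criteria, *moderately correctable* if
#' not; features without a significant directional improvement are
#' *not correctable*.
#'
#' @inheritParams feature_metrics
#' @param corrected the corrected slice from [apply_correction()].
#' @param model the `radr_model` used (recorded in the result).
#' @param criteria a [robust_criteria()] object.
#' @param all_fits optional full fit library (recorded for reporting).
#' @return A `radr_correction` object; see [tidy.radr_correction()].
#' @export
evaluate_correction <- function(table, corrected, feature, grid, model,
                                criteria = robust_criteria(),
                                all_fits = NULL) {
  before <- feature_metrics(table, feature, grid)
  after <- feature_metrics(corrected, feature, grid)
  cv_b <- before$cv_per_subject
  cv_a <- after$cv_per_subject[names(cv_b)]
  ok <- !is.na(cv_b) & !is.na(cv_a)
  diffs <- cv_a[ok] - cv_b[ok]
  if (!length(diffs) || all(diffs == 0)) {
    p <- NA_real_
    reason <- "all paired CV differences zero or no valid pairs"
  } else {
    p <- suppressWarnings(wilcox.test(cv_a[ok], cv_b[ok], paired = TRUE)$p.value)
    reason <- NA_character_
  }
  overlap <- ci_overlap(
    ci_or_point(before$ci_low, before$ci_high, before$rrm_abs),
    ci_or_point(after$ci_low, after$ci_high, after$rrm_abs))
  delta_cv <- after$cv_mean - before$cv_mean
  delta_rrm <- after$rrm_abs - before$rrm_abs
  significant <- isTRUE(p < 0.05) && !overlap && delta_cv < 0 && delta_rrm < 0
  category <- if (!significant) "not_correctable"
  else if (is_robust(after, criteria)) "correctable"
  else "moderately_correctable"
  structure(
    list(feature_name = feature, scheme = grid$scheme,
         algorithm = grid$algorithm, best_model = model,
         all_fits = all_fits, corrected = corrected,
         metrics_before = before, metrics_after = after,
         wilcoxon_p = p, ci_overlap = overlap,
         delta_cv = delta_cv, delta_rrm = delta_rrm,
         category = category, reason = reason),
    class = "radr_correction"
  )
}

# A zero-variance corrected feature has r_rm = 0 with no finite CI;
# represent it as the degenerate point interval for the overlap check.
ci_or_point <- function(lo, hi, point) {
  if (is.na(lo) || is.na(hi)) c(point, point) else c(lo, hi)
}

ci_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Fit, select, correct and categorise one feature
#'
#' Convenience wrapper running the whole correction pathway for one
#' feature of one scenario: [fit_dependency_library()],
#' [select_best_model()], [apply_correction()] and
#' [evaluate_correction()]. When no fit converges the feature is
#' reported `not_correctable` with a reason.
#'
#' @inheritParams fit_dependency_library
#' @param criteria a [robust_criteria()] object.
#' @return A `radr_correction` object.
#' @export
correct_feature <- function(table, feature, grid,
                            criteria = robust_criteria(),
                            scale_s = default_scale(grid),
                            var_floor = 1e-12) {
  fits <- fit_dependency_library(table, feature, grid,
                                 scale_s = scale_s, var_floor = var_floor)
  best <- select_best_model(fits)
  if (is.null(best)) {
    before <- feature_metrics(table, feature, grid)
    return(structure(
      list(feature_name = feature, scheme = grid$scheme,
           algorithm = grid$algorithm, best_model = NULL, all_fits = fits,
           corrected = NULL, metrics_before = before, metrics_after = NULL,
           wilcoxon_p = NA_real_, ci_overlap = NA,
           delta_cv = NA_real_, delta_rrm = NA_real_,
           category = "not_correctable", reason = "no dependency fit converged"),
      class = "radr_correction"))
  }
  corrected <- apply_correction(table, feature, grid, best)
  evaluate_correction(table, corrected, feature, grid, best,
                      criteria = criteria, all_fits = fits)
}

#' @export
print.radr_correction <- function(x, ...) {
  cat(sprintf("<radr_correction> %s (%s): %s", x$feature_name, x$algorithm,
              x$category))
  if (!is.null(x$best_model)) {
    cat(sprintf(" [%s; dCV = %+.2f%%, d|r_rm| = %+.3f, p = %.3g]",
                x$best_model$function_id, x$delta_cv, x$delta_rrm,
                x$wilcoxon_p))
  }
  cat("\n")
  invisible(x)
}
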