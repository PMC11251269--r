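#' Within-subject percentage coefficient of variation
#'
#' `100 * s / |m|` where `s` is the sample standard deviation (n - 1
#' denominator) and `m` the mean of one subject's feature values across
#' the parameter values of a range. Constant input gives 0 exactly. A
#' non-constant subject whose |mean| falls below `eps` (default 1e-8 in
#' feature units) is degenerate: the CV is not computed (returns `NA`)
#' and the caller excludes and counts the subject. Radiomic features
#' such as skewness can legitimately cross zero, where a percentage CV
#' is meaningless.
#'
#' @param values numeric vector, one subject's feature values (>= 2).
#' @param eps degenerate-mean threshold in feature units.
#' @return CV in percent, or `NA_real_` for a degenerate mean.
#' @export
within_subject_cv <- function(values, eps = 1e-8) {
  if (length(values) < 2L) abort("within-subject CV needs at least 2 values")
  if (any(!is.finite(values))) abort("feature values must be finite")
  s <- sd(values)
  if (s == 0) return(0)
  m <- mean(values)
  if (abs(m) < eps) return(NA_real_)
  100 * s / abs(m)
}

#' Repeated-measures correlation coefficient
#'
#' The common within-subject correlation between the parameter `x` and
#' the feature value `y`, estimated by the ANCOVA formulation with
#' subject-specific intercepts and a shared slope: after centring `x`
#' and `y` within each subject, the shared slope `b` is fitted by least
#' squares and
#' `r_rm = sign(b) * sqrt(SS_measure / (SS_measure + SS_error))`
#' with `SS_measure = b^2 * sum(xc^2)` and `SS_error` the residual sum
#' of squares, on `N - k - 1` degrees of freedom for `N` observations
#' from `k` subjects. This addresses the non-independence of feature
#' values measured repeatedly on the same subject.
#'
#' The 95% CI uses the Fisher z-transform with standard error
#' `1 / sqrt(df - 1)` (the Pearson `1 / sqrt(n - 3)` rule at effective
#' sample size `df + 2`); `NA` when `df < 2`. If the within-subject
#' variance of `y` is zero everywhere (a feature flat in the parameter,
#' e.g. any shape feature under discretisation) the correlation is
#' defined as 0 with a `zero_variance` flag.
#'
#' @param x numeric parameter values.
#' @param y numeric feature values, same length.
#' @param subject_id subject identifier vector, same length.
#' @return A list with `rrm`, `rrm_abs`, `ci_low`, `ci_high` (bounds on
#'   `|r_rm|`), `df`, `n_subjects`, `n_obs` and `flags`.
#' @examples
#' x <- rep(1:5, 3); id <- rep(letters[1:3], each = 5)
#' rmcorr(x, 3 * x + rep(c(0, 10, 20), each = 5), id)$rrm  # 1
#' @export
rmcorr <- function(x, y, subject_id) {
  if (length(x) != length(y) || length(x) != length(subject_id)) {
    abort("x, y and subject_id must have equal length")
  }
  sid <- as.character(subject_id)
  counts <- table(sid)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("rmcorr needs >= 2 subjects with >= 2 observations each")
  }
  xc <- x - stats::ave(x, sid)
  yc <- y - stats::ave(y, sid)
  sxx <- sum(xc^2)
  if (sxx == 0) abort("x is constant within every subject; slope undefined")
  syy <- sum(yc^2)
  flags <- character()
  k <- length(counts)
  n <- length(x)
  df <- n - k - 1L
  if (syy == 0) {
    return(list(rrm = 0, rrm_abs = 0, ci_low = NA_real_, ci_high = NA_real_,
                df = df, n_subjects = k, n_obs = n, flags = "zero_variance"))
  }
  b <- sum(xc * yc) / sxx
  ss_measure <- b^2 * sxx
  ss_error <- sum((yc - b * xc)^2)
  r <- sign(b) * sqrt(ss_measure / (ss_measure + ss_error))
  r <- max(-1, min(1, r))
  ci <- rrm_abs_ci(r, df)
  list(rrm = r, rrm_abs = abs(r), ci_low = ci[1], ci_high = ci[2],
       df = df, n_subjects = k, n_obs = n, flags = flags)
}

# Fisher-z CI on the signed r_rm folded onto the magnitude scale: the
# |r| interval is [0, max|bound|] when the signed interval straddles 0,
# otherwise [min|bound|, max|bound|].
rrm_abs_ci <- function(r, df, level = 0.95) {
  if (df < 2) return(c(NA_real_, NA_real_))
  se <- 1 / sqrt(df - 1)
  zc <- qnorm(1 - (1 - level) / 2)
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
  lo <- tanh(z - zc * se)
  hi <- tanh(z + zc * se)
  if (lo <= 0 && hi >= 0) c(0, max(abs(lo), abs(hi)))
  else c(min(abs(lo), abs(hi)), max(abs(lo), abs(hi)))
}

# Workhorse: both robustness metrics from a subjects x parameters value
# matrix (rownames = subject ids) and the parameter vector x.
metrics_from_matrix <- function(Y, x, eps = 1e-8, strict = FALSE) {
  stopifnot(is.matrix(Y), ncol(Y) == length(x), ncol(Y) >= 2L, nrow(Y) >= 1L)
  sds <- apply(Y, 1L, sd)
  means <- rowMeans(Y)
  cvs <- ifelse(sds == 0, 0,
                ifelse(abs(means) < eps, NA_real_, 100 * sds / abs(means)))
  names(cvs) <- rownames(Y)
  n_degenerate <- sum(is.na(cvs))
  flags <- if (n_degenerate) "zero_mean_subjects" else character()
  if (strict && n_degenerate) {
    abort(sprintf("%d subject(s) with |mean| < %g; strict mode refuses to drop them",
                  n_degenerate, eps))
  }
  if (all(is.na(cvs))) abort("no non-degenerate subjects left for CV_mean")
  cv_mean <- mean(cvs, na.rm = TRUE)

  xc <- x - mean(x)
  yc <- Y - means
  sxx <- nrow(Y) * sum(xc^2)
  if (sxx == 0) abort("parameter constant within subjects; r_rm undefined")
  syy <- sum(yc^2)
  n <- length(Y)
  k <- nrow(Y)
  df <- n - k - 1L
  if (syy == 0) {
    rrm <- 0; ci <- c(NA_real_, NA_real_)
    flags <- c(flags, "zero_variance_feature")
  } else {
    b <- sum(sweep(yc, 2L, xc, `*`)) / sxx
    ss_measure <- b^2 * sxx
    ss_error <- sum((yc - matrix(b * xc, k, ncol(Y), byrow = TRUE))^2)
    rrm <- max(-1, min(1, sign(b) * sqrt(ss_measure / (ss_measure + ss_error))))
    ci <- rrm_abs_ci(rrm, df)
  }
  structure(
    list(cv_mean = cv_mean, cv_per_subject = cvs,
         n_cv_degenerate = n_degenerate,
         rrm = rrm, rrm_abs = abs(rrm), ci_low = ci[1], ci_high = ci[2],
         df = df, n_subjects = k, n_parameters = ncol(Y), flags = flags),
    class = "radr_metrics"
  )
}

# Reshape one feature's scenario slice into a complete subjects x
# parameters matrix ordered by the grid (optionally an index subset).
feature_value_matrix <- function(table, feature, grid, indices = NULL) {
  slice <- require_complete(table, grid, features = feature)
  if (is.null(indices)) indices <- seq_along(grid$values)
  keep_vals <- canonicalise_parameter(grid$values[indices], grid)
  slice <- slice[slice$parameter_value %in% keep_vals, ]
  subjects <- sort(unique(slice$subject_id))
  Y <- matrix(NA_real_, length(subjects), length(indices),
              dimnames = list(subjects, format(keep_vals)))
  i <- match(slice$subject_id, subjects)
  j <- match(slice$parameter_value, keep_vals)
  Y[cbind(i, j)] <- slice$value
  Y
}

#' Robustness metrics for one feature over a parameter range
#'
#' Computes the per-subject CVs, their mean (CV_mean) and the
#' repeated-measures correlation with 95% CI for one feature of one
#' scenario, over the whole grid or an index sub-range. Subjects with a
#' degenerate (near-zero) mean are excluded from CV_mean and counted;
#' `strict = TRUE` raises an error instead.
#'
#' @param table a [feature_table()].
#' @param feature feature name.
#' @param grid the scenario [parameter_grid()].
#' @param indices optional integer grid indices (default: full grid).
#' @param eps degenerate-mean threshold (see [within_subject_cv()]).
#' @param strict error (rather than exclude) on degenerate subjects.
#' @return A `radr_metrics` object; see [tidy.radr_metrics()].
#' @export
feature_metrics <- function(table, feature, grid, indices = NULL,
                            eps = 1e-8, strict = FALSE) {
  Y <- feature_value_matrix(table, feature, grid, indices)
  x <- grid$values[indices %||% seq_along(grid$values)]
  m <- metrics_from_matrix(Y, x, eps = eps, strict = strict)
  m$feature_name <- feature
  m$algorithm <- grid$algorithm
  m
}

#' Robustness metrics table for a scenario
#'
#' One row per feature present in the scenario: CV_mean, r_rm, |r_rm|
#' with 95% CI, counts, degenerate flags, and the robust verdict under
#' `criteria`.
#'
#' @inheritParams feature_metrics
#' @param criteria a [robust_criteria()] object.
#' @return A tibble, one row per feature.
#' @export
metrics_table <- function(table, grid, criteria = robust_criteria(),
                          eps = 1e-8, strict = FALSE) {
  slice <- scenario_slice(table, grid)
  features <- sort(unique(slice$feature_name))
  if (!length(features)) abort("no features found for this scenario")
  purrr::map_dfr(features, function(f) {
    m <- feature_metrics(table, f, grid, eps = eps, strict = strict)
    dplyr::mutate(tidy(m), robust = is_robust(m, criteria))
  })
}

#' @export
print.radr_metrics <- function(x, ...) {
  cat(sprintf(
    "<radr_metrics>%s CV_mean = %.3f%%, r_rm = %.4f (|r_rm| 95%% CI %.4f-%.4f), %d subjects x %d parameters%s\n",
    if (!is.null(x$feature_name)) paste0(" ", x$feature_name, ":") else "",
    x$cv_mean, x$rrm, x$ci_low, x$ci_high, x$n_subjects, x$n_parameters,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
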