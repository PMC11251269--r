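#' Run the full robustness pipeline for one scenario
#'
#' Stages, per feature: (1) robustness metrics on the full grid and
#' the robust verdict; (2) for features failing the criteria, the
#' pairwise robustness matrix and conditional categorisation (robust
#' range + margin); (3) for the same non-robust pool, dependency
#' correction and correctability categorisation — the two mitigation
#' strategies are applied in parallel, not either/or; (4) aggregation
#' of the conditionally robust features' margins into the scenario's
#' global robustness range. Incomplete scenarios error before any
#' stage runs.
#'
#' @inheritParams metrics_table
#' @param verbose log per-stage feature counts.
#' @return A `radr_report` object with `features` (one row per
#'   feature), `metrics`, `matrices`, `ranges`, `corrections`,
#'   `global_range` and `counts`.
#' @export
run_scenario <- function(table, grid, criteria = robust_criteria(),
                         eps = 1e-8, verbose = FALSE) {
  slice <- require_complete(table, grid)
  features <- sort(unique(slice$feature_name))
  radr_log("scenario %s/%s: %d features, %d subjects entering",
           grid$scheme, grid$algorithm, length(features),
           length(unique(slice$subject_id)), verbose = verbose)

  metrics <- metrics_table(slice, grid, criteria, eps = eps)
  robust_features <- metrics$feature_name[metrics$robust]
  pool <- setdiff(features, robust_features)
  radr_log("stage 1 (full-grid criteria): %d robust, %d enter range/correction analysis",
           length(robust_features), length(pool), verbose = verbose)

  matrices <- list(); ranges <- list(); corrections <- list()
  for (f in pool) {
    m <- compute_robustness_matrix(slice, f, grid, criteria, eps = eps)
    matrices[[f]] <- m
    ranges[[f]] <- classify_conditional(m)
    corrections[[f]] <- correct_feature(slice, f, grid, criteria)
  }
  cond <- vapply(ranges, function(r) r$category, "") == "conditionally_robust"
  radr_log("stage 2 (range analysis): %d conditionally robust, %d non-robust",
           sum(cond), sum(!cond), verbose = verbose)
  corr_cat <- vapply(corrections, function(cr) cr$category, "")
  radr_log("stage 3 (correction): %d correctable, %d moderately correctable, %d not correctable",
           sum(corr_cat == "correctable"),
           sum(corr_cat == "moderately_correctable"),
           sum(corr_cat == "not_correctable"), verbose = verbose)

  global <- if (any(cond)) aggregate_global_range(ranges, grid) else NULL
  radr_log("stage 4 (global range): %s", if (is.null(global)) "skipped" else
    sprintf("cutoff %d over %d features", global$cutoff,
            global$n_conditionally_robust), verbose = verbose)

  iv_chr <- function(iv) if (is.null(iv)) NA_character_ else
    sprintf("[%s, %s]", format(iv$start_value), format(iv$end_value))
  feature_rows <- purrr::map_dfr(features, function(f) {
    robust <- f %in% robust_features
    r <- ranges[[f]]; cr <- corrections[[f]]
    tibble(
      feature_name = f, robust = robust,
      conditional_category = if (robust) "not_applicable" else r$category,
      robust_range = if (robust) NA_character_ else iv_chr(r$robust_range),
      margin = if (robust) NA_character_ else iv_chr(r$margin),
      correctability_category = if (robust) "not_applicable" else cr$category,
      best_function = if (robust || is.null(cr$best_model)) NA_character_
                      else cr$best_model$function_id,
      delta_cv = if (robust) NA_real_ else cr$delta_cv,
      delta_rrm = if (robust) NA_real_ else cr$delta_rrm
    )
  })
  counts <- list(
    n_features = length(features),
    robust = length(robust_features),
    conditionally_robust = sum(cond),
    non_robust = sum(!cond),
    correctable = sum(corr_cat == "correctable"),
    moderately_correctable = sum(corr_cat == "moderately_correctable"),
    not_correctable = sum(corr_cat == "not_correctable")
  )
  structure(
    list(scheme = grid$scheme, algorithm = grid$algorithm, grid = grid,
         criteria = criteria, features = feature_rows, metrics = metrics,
         matrices = matrices, ranges = ranges, corrections = corrections,
         global_range = global, counts = counts),
    class = "radr_report"
  )
}

#' @export
print.radr_report <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(
    "<radr_report> %s/%s: %d features | robust %d, conditionally robust %d, non-robust %d | correctable %d, moderately %d, not %d\n",
    x$scheme, x$algorithm, c0$n_features, c0$robust,
    c0$conditionally_robust, c0$non_robust, c0$correctable,
    c0$moderately_correctable, c0$not_correctable))
  invisible(x)
}

#' Cross-scenario summary
#'
#' Counts and proportions per category per scenario, plus the list of
#' features robust in every scenario analysed.
#'
#' @param reports list of `radr_report` objects.
#' @return A list with `by_scenario` (tibble) and `always_robust`
#'   (character vector).
#' @export
summarise_scenarios <- function(reports) {
  if (!length(reports)) abort("at least one scenario report is required")
  by_scenario <- purrr::map_dfr(reports, function(r) {
    c0 <- r$counts
    tibble(
      scheme = r$scheme, algorithm = r$algorithm,
      n_features = c0$n_features,
      robust = c0$robust,
      conditionally_robust = c0$conditionally_robust,
      non_robust = c0$non_robust,
      correctable = c0$correctable,
      moderately_correctable = c0$moderately_correctable,
      not_correctable = c0$not_correctable,
      prop_robust = c0$robust / c0$n_features,
      prop_conditionally_robust = c0$conditionally_robust / c0$n_features,
      prop_non_robust = c0$non_robust / c0$n_features
    )
  })
  robust_sets <- lapply(reports, function(r)
    r$features$feature_name[r$features$robust])
  always_robust <- sort(Reduce(intersect, robust_sets))
  list(by_scenario = by_scenario, always_robust = always_robust)
}

#' Write the canonical CSV outputs of a scenario report
#'
#' Emits `metrics.csv`, `matrix.csv` (all tiles, tidy), `ranges.csv`,
#' `global_range.csv` (histogram plus the chosen range), and
#' `correction.csv` (the eight per-function AICs, the chosen model,
#' before/after metrics, test outcomes, category), plus `report.csv`
#' with the per-feature category rows.
#'
#' @param report a `radr_report`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_scenario_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name))
  w(report$metrics, "metrics.csv")
  if (length(report$matrices)) {
    w(purrr::map_dfr(report$matrices, tidy), "matrix.csv")
  }
  if (length(report$ranges)) {
    w(purrr::map_dfr(report$ranges, tidy), "ranges.csv")
  }
  if (!is.null(report$global_range)) {
    w(tidy(report$global_range), "global_range.csv")
  }
  if (length(report$corrections)) {
    w(purrr::map_dfr(report$corrections, tidy), "correction.csv")
  }
  w(report$features, "report.csv")
  invisible(dir)
}
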