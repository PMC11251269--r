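#' Long-format radiomic feature tables
#'
#' The pipeline's universal input is a long-format table with one row
#' per subject x feature x scenario x parameter value. Columns:
#' `subject_id` (character), `feature_name` (character), `scheme`
#' (`"discretisation"` / `"interpolation"`), `algorithm`,
#' `parameter_value` (numeric, in the scenario's unit: SUV, bins, mm)
#' and `value` (the feature value). The key
#' (subject_id, feature_name, scheme, algorithm, parameter_value) must
#' be unique; missing cells are surfaced by [completeness_report()],
#' never imputed.
#'
#' @param x a data frame with the columns above.
#' @return A validated tibble (class `radr_feature_table`).
#' @export
feature_table <- function(x) {
  required <- c("subject_id", "feature_name", "scheme", "algorithm",
                "parameter_value", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$subject_id <- as.character(x$subject_id)
  x$feature_name <- as.character(x$feature_name)
  x$scheme <- as.character(x$scheme)
  x$algorithm <- as.character(x$algorithm)
  if (!is.numeric(x$parameter_value) || !is.numeric(x$value)) {
    abort("parameter_value and value must be numeric")
  }
  bad_scheme <- setdiff(unique(x$scheme), c("discretisation", "interpolation"))
  if (length(bad_scheme)) {
    abort(paste0("unknown scheme(s): ", paste(bad_scheme, collapse = ", ")))
  }
  bad_alg <- setdiff(unique(x$algorithm), names(radr_algorithms))
  if (length(bad_alg)) {
    abort(paste0("unknown algorithm(s): ", paste(bad_alg, collapse = ", ")))
  }
  key <- paste(x$subject_id, x$feature_name, x$scheme, x$algorithm,
               x$parameter_value, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf(
      "duplicate (subject, feature, scheme, algorithm, parameter) key at row(s): %s",
      paste(head(dup, 10L), collapse = ", ")))
  }
  class(x) <- unique(c("radr_feature_table", class(x)))
  x
}

#' Read / write a feature table as CSV
#'
#' Plain UTF-8 comma-separated text with a header; numeric values are
#' written with [format()] at 15 significant digits, which round-trips
#' doubles through decimal text exactly for the value magnitudes that
#' occur in radiomic feature tables.
#'
#' @param path file path.
#' @return [read_feature_table()] returns a validated
#'   `radr_feature_table` tibble; [write_feature_table()] returns
#'   `path` invisibly.
#' @export
read_feature_table <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    feature_name = readr::col_character(),
    scheme = readr::col_character(),
    algorithm = readr::col_character(),
    parameter_value = readr::col_double(),
    value = readr::col_double()
  )))
  problems <- readr::problems(raw)
  if (nrow(problems)) {
    abort(sprintf("malformed CSV: first problem at row %d (%s)",
                  problems$row[1], problems$expected[1]))
  }
  bad <- which(is.na(raw$parameter_value) | is.na(raw$value))
  if (length(bad)) {
    abort(sprintf("non-numeric or missing value at data row(s): %s",
                  paste(head(bad, 10L), collapse = ", ")))
  }
  tbl <- feature_table(raw)
  if (!is.null(attr(raw, "corrected"))) attr(tbl, "corrected") <- TRUE
  tbl
}

#' @param table a feature table ([feature_table()]).
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  out <- dplyr::mutate(
    as_tibble(table),
    parameter_value = format(.data$parameter_value, digits = 15,
                             scientific = FALSE, trim = TRUE),
    value = format(.data$value, digits = 15, trim = TRUE)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Scenario completeness report
#'
#' For one scenario (scheme + algorithm) and grid, lists every
#' (subject, feature, parameter) cell that is absent from the table. A
#' complete scenario has every subject observed at every grid value for
#' every feature. Missing cells are reported, never imputed.
#'
#' @param table a feature table.
#' @param grid a [parameter_grid()] defining the scenario.
#' @return A tibble with columns `subject_id`, `feature_name`,
#'   `parameter_value` of missing cells (zero rows when complete).
#' @export
completeness_report <- function(table, grid) {
  slice <- scenario_slice(table, grid)
  subjects <- unique(slice$subject_id)
  features <- unique(slice$feature_name)
  if (!length(subjects) || !length(features)) {
    return(tibble(subject_id = character(), feature_name = character(),
                  parameter_value = numeric()))
  }
  full <- tidyr::expand_grid(
    subject_id = subjects, feature_name = features,
    parameter_value = grid$values
  )
  have <- dplyr::mutate(
    slice[, c("subject_id", "feature_name", "parameter_value")],
    parameter_value = grid$values[grid_index(.data$parameter_value, grid)]
  )
  dplyr::anti_join(full, have,
                   by = c("subject_id", "feature_name", "parameter_value"))
}

# Rows of `table` belonging to the grid's scenario, with parameter values
# canonically rounded and restricted to the grid.
scenario_slice <- function(table, grid) {
  sl <- table[table$scheme == grid$scheme & table$algorithm == grid$algorithm, ]
  idx <- grid_index(sl$parameter_value, grid)
  sl <- sl[!is.na(idx), ]
  sl$parameter_value <- canonicalise_parameter(sl$parameter_value, grid)
  sl
}

# Error unless the scenario is complete for the given features (all by
# default); returns the slice restricted to those features.
require_complete <- function(table, grid, features = NULL) {
  slice <- scenario_slice(table, grid)
  if (!is.null(features)) {
    absent <- setdiff(features, unique(slice$feature_name))
    if (length(absent)) {
      abort(sprintf("feature(s) not present in scenario %s/%s: %s",
                    grid$scheme, grid$algorithm,
                    paste(absent, collapse = ", ")))
    }
    slice <- slice[slice$feature_name %in% features, ]
  }
  miss <- completeness_report(slice, grid)
  if (nrow(miss)) {
    ex <- utils::head(miss, 5L)
    abort(sprintf(
      "incomplete scenario %s/%s: %d missing cell(s), e.g. %s",
      grid$scheme, grid$algorithm, nrow(miss),
      paste(sprintf("(%s, %s, %s)", ex$subject_id, ex$feature_name,
                    format(ex$parameter_value)), collapse = "; ")))
  }
  slice
}
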