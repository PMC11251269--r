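#' Correlogram of a robustness matrix
#'
#' Upper-triangular tile plot over start and end parameter values,
#' filled by a robustness metric, with robust tiles outlined and the
#' derived robust range / margin overlaid as nested squares.
#'
#' @param object a `radr_matrix`.
#' @param fill `"cv_mean"` or `"rrm_abs"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot radr_matrix
#' @export
autoplot.radr_matrix <- function(object, fill = c("cv_mean", "rrm_abs"), ...) {
  fill <- match.arg(fill)
  tiles <- tidy(object)
  rng <- derive_robust_range(object)
  mar <- derive_margin(object)
  step <- min(diff(object$grid$values))
  sq <- function(iv, col) {
    if (is.null(iv)) return(NULL)
    ggplot2::annotate("rect",
                      xmin = iv$start_value - step / 2, xmax = iv$end_value + step / 2,
                      ymin = iv$start_value - step / 2, ymax = iv$end_value + step / 2,
                      colour = col, fill = NA, linewidth = 0.8)
  }
  ggplot2::ggplot(tiles, ggplot2::aes(x = .data$end_value,
                                      y = .data$start_value)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]]),
                       width = step, height = step) +
    ggplot2::geom_tile(data = tiles[tiles$robust, ],
                       width = step, height = step,
                       colour = "black", fill = NA, linewidth = 0.3) +
    sq(mar, "goldenrod") + sq(rng, "gold") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (fill == "cv_mean")
      expression(CV[mean] ~ "(%)") else expression("|" * r[rm] * "|")) +
    ggplot2::labs(
      x = sprintf("end value (%s)", object$grid$unit),
      y = sprintf("start value (%s)", object$grid$unit),
      title = sprintf("%s - %s", object$feature_name, object$grid$algorithm)) +
    ggplot2::theme_minimal()
}

#' Global robustness-range histogram
#'
#' Per-grid-value counts of conditionally robust features whose margin
#' (or robust range) contains the value, the half-of-features cutoff,
#' and the chosen global range shaded.
#'
#' @param object a `radr_global_range`.
#' @param variant `"margin"` or `"robust_range"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot radr_global_range
#' @export
autoplot.radr_global_range <- function(object,
                                       variant = c("margin", "robust_range"),
                                       ...) {
  variant <- match.arg(variant)
  col <- paste0(variant, "_count")
  h <- object$histogram
  gr <- object$global_range
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$parameter_value,
                                       y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = sprintf("parameter value (%s)", object$grid$unit),
                  y = "conditionally robust features",
                  title = sprintf("%s / %s global robustness range",
                                  object$scheme, object$algorithm)) +
    ggplot2::theme_minimal()
  if (!is.null(gr)) {
    step <- min(diff(object$grid$values))
    p <- p + ggplot2::annotate("rect",
                               xmin = gr$start_value - step / 2,
                               xmax = gr$end_value + step / 2,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "gold")
  }
  p
}

#' Before/after dumbbell plot of a correction
#'
#' Per-subject CVs before and after dependency correction, joined per
#' subject, with CV_mean marked.
#'
#' @param object a `radr_correction`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot radr_correction
#' @export
autoplot.radr_correction <- function(object, ...) {
  if (is.null(object$metrics_after)) {
    abort("no correction was applied; nothing to plot")
  }
  b <- object$metrics_before$cv_per_subject
  a <- object$metrics_after$cv_per_subject[names(b)]
  df <- tibble(subject_id = rep(names(b), 2L),
               stage = rep(c("before", "after"), each = length(b)),
               cv = c(b, a))
  df$stage <- factor(df$stage, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$cv)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.4, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.25,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(y = "within-subject CV (%)", x = NULL,
                  title = sprintf("%s (%s): %s", object$feature_name,
                                  object$algorithm, object$category)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
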