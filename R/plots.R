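#' Kernel density plot of one feature by group
#'
#' Overlaid per-group Gaussian kernel density curves (one panel), the way
#' feature distributions are compared across scanners before and after
#' harmonization.
#'
#' @inheritParams kde_curves
#' @return A ggplot object.
#' @export
plot_feature_density <- function(table, feature, group = "batch_id",
                                 grid_size = 512L) {
  curves <- kde_curves(table, feature, group = group, grid_size = grid_size)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$x, y = .data$density,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = feature, y = "density", colour = group) +
    ggplot2::theme_minimal()
}

#' Z-score heatmap of a feature table
#'
#' Exams (rows, grouped by batch) by features (columns), colour = z-score
#' truncated at `limit` for display.
#'
#' @param table A feature table.
#' @param limit Absolute z-score display cap (default 3).
#' @return A ggplot object.
#' @export
plot_zscore_heatmap <- function(table, limit = 3) {
  z <- zscore_matrix(table)
  long <- tidyr::pivot_longer(z, cols = -c("exam_id", "batch_id"),
                              names_to = "feature", values_to = "z")
  long$exam_id <- factor(long$exam_id, levels = rev(z$exam_id))
  long$feature <- factor(long$feature, levels = feature_columns(table))
  long$z <- pmax(pmin(long$z, limit), -limit)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$exam_id,
                                     fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-limit, limit)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank()) +
    ggplot2::labs(x = "feature", y = "exam", fill = "z")
}

#' Plot a study report
#'
#' Mean per-feature Cohen's F by experiment, original vs harmonized, one
#' facet per feature family -- the report-table comparison at a glance.
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("family", "experiment",
                  original = "mean_cohens_f_original",
                  harmonized = "mean_cohens_f_harmonized") |>
    tidyr::pivot_longer(c("original", "harmonized"),
                        names_to = "stage", values_to = "mean_cohens_f")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$experiment),
                               y = .data$mean_cohens_f,
                               fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "experiment", y = "mean Cohen's F", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
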