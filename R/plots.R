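# ggplot2 graphics for the main result types.

#' Plot traced vessel segments
#'
#' Draws each ordered segment as a path, colored by segment, in raster
#' orientation (row axis reversed).
#'
#' @param segments Segment tibble from [extract_segments()].
#' @return A ggplot object.
#' @export
plot_segments <- function(segments) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               group = interaction(.data$image_id,
                                                   .data$segment_id),
                               color = factor(.data$segment_id))) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", color = "segment") +
    ggplot2::theme_minimal()
}

#' Plot metric distributions by severity grade
#'
#' Boxplots of a chosen image-level feature per grade: a quick check that
#' tortuosity rises with the severity label.
#'
#' @param labeled Labeled feature tibble from [join_labels()].
#' @param metric Feature column name (default `"dm_avg"`).
#' @return A ggplot object.
#' @export
plot_grade_separation <- function(labeled, metric = "dm_avg") {
  ggplot2::ggplot(labeled,
                  ggplot2::aes(x = .data$grade, y = .data[[metric]],
                               fill = .data$grade)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "severity grade", y = metric) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a cross-validation report
#'
#' @param object A `severity_cv` from [cross_validate_severity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.severity_cv <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion_matrix))
  names(cm) <- c("actual", "predicted", "count")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("accuracy %.3f, kappa %.3f",
                                  object$accuracy, object$kappa)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
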