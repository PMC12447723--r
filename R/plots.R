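#' Plot a ROC curve with the rAUC region highlighted
#'
#' @param object A `splice_roc` from [roc_points()].
#' @param min_tpr,max_fpr Bounds of the restricted region.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_roc <- function(object, min_tpr = 0.5, max_fpr = 0.1, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::annotate("rect", xmin = 0, xmax = max_fpr, ymin = min_tpr,
                      ymax = 1, fill = "grey85") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (rAUC = %.3f in shaded region)",
                      rauc(object, min_tpr, max_fpr))) +
    ggplot2::theme_minimal()
}

#' Plot training/validation cost curves of a CNN fit
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_cost", "validation_cost"),
                            names_to = "set", values_to = "cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$cost,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy cost", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of activation-rate differences
#'
#' Dark red cells fire preferentially on positive sites, dark blue on
#' negatives; position runs along the pooled window axis with the splice
#' boundary near the center.
#'
#' @param object An `activation_diff` matrix from [activation_rate_diff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activation_diff <- function(object, ...) {
  df <- tibble(
    feature = rep(seq_len(nrow(object)), times = ncol(object)),
    position = rep(seq_len(ncol(object)), each = nrow(object)),
    diff = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$feature,
                                   fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "Pooled position", y = "Feature",
                  fill = "Rate\ndifference") +
    ggplot2::theme_minimal()
}

#' Plot a calibration table
#'
#' @param object A `calibration_table`.
#' @param ... Unused.
#' @return A ggplot object of calibrated score against bin midpoint.
#' @export
autoplot.calibration_table <- function(object, ...) {
  df <- dplyr::mutate(object$bins, mid = (.data$bin + 0.5) / object$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Raw model score bin", y = "Calibrated score (2 log2 odds)") +
    ggplot2::theme_minimal()
}
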