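#' Plot the ROC curve of an evaluation report
#'
#' @param object An `eval_report` carrying ROC points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) abort_input("report carries no ROC points.")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - Sp)",
                  y = "True-positive rate (Sn)",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Bar chart of discriminant feature weights
#'
#' Visualizes which features favor the DNA-binding class (positive
#' weights) versus the non-binding class, in feature order: the 20 residue
#' compositions followed by the sequence-order factors.
#'
#' @param weights Tibble from [discriminant_weights()].
#' @return A ggplot.
#' @export
plot_discriminant_weights <- function(weights) {
  weights$feature <- factor(weights$feature, levels = weights$feature)
  ggplot2::ggplot(weights,
                  ggplot2::aes(x = .data$feature, y = .data$weight,
                               fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Discriminant weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heat map of a (lambda, omega) parameter scan
#'
#' @param scan Tibble from [run_paramscan()].
#' @param metric Which metric column to fill by (default `"acc"`).
#' @return A ggplot.
#' @export
plot_param_grid <- function(scan, metric = "acc") {
  ggplot2::ggplot(scan,
                  ggplot2::aes(x = factor(.data$omega), y = factor(.data$lambda),
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data[[metric]])),
                       colour = "white", size = 3) +
    ggplot2::labs(x = "omega", y = "lambda", fill = metric) +
    ggplot2::theme_minimal()
}
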