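#' Plot a ROC curve
#'
#' @param object An `"hrd_roc"` from [eval_roc()] or [biomarker_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrd_roc <- function(object, ...) {
  df <- dplyr::arrange(object$curve, 1 - .data$specificity,
                       .data$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f, PR-AUC = %.3f",
                                  object$auc, object$pr_auc)) +
    ggplot2::theme_minimal()
}

#' Plot the relative influence of model components
#'
#' @param object An `"hrd_model"`.
#' @param top_n How many components to show (default all retained).
#' @param ... Unused.
#' @return A ggplot bar chart of final-fit relative influence.
#' @export
autoplot.hrd_model <- function(object, top_n = NULL, ...) {
  inf <- relative_influence(object)
  inf <- dplyr::arrange(inf, dplyr::desc(.data$influence))
  if (!is.null(top_n)) inf <- utils::head(inf, top_n)
  inf$label <- factor(inf$label, levels = rev(inf$label))
  ggplot2::ggplot(inf, ggplot2::aes(x = .data$influence, y = .data$label)) +
    ggplot2::geom_col(fill = "#B2182B") +
    ggplot2::labs(x = "Relative influence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare per-class distributions of selected components
#'
#' @param features A feature-matrix tibble.
#' @param labels Labels tibble or aligned vector (HRD/HRP).
#' @param components Component labels to show (default the two headline
#'   biomarkers).
#' @return A ggplot of per-class count distributions.
#' @export
plot_component_counts <- function(features, labels,
                                  components = c("BP10MB[1]",
                                                 "SS[>7 & <=8]")) {
  y <- align_labels(features, labels)
  df <- features[, c("sample_id", components), drop = FALSE] |>
    dplyr::mutate(label = ifelse(y == 1, "HRD", "HRP")) |>
    tidyr::pivot_longer(dplyr::all_of(components), names_to = "component",
                        values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(HRD = "#B2182B", HRP = "#2166AC")) +
    ggplot2::labs(x = NULL, y = "Component count") +
    ggplot2::theme_minimal()
}
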