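#' Plot per-condition prediction accuracy
#'
#' Boxplots of prediction accuracy by condition, faceted by category when
#' several are present.
#'
#' @param object A `condition_comparison` or accuracy tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_comparison <- function(object, ...) {
  plot_accuracy(object$accuracy)
}

#' @rdname autoplot.condition_comparison
#' @param accuracy_table Long-format accuracy tibble.
#' @export
plot_accuracy <- function(accuracy_table) {
  p <- ggplot2::ggplot(accuracy_table,
                       ggplot2::aes(x = .data$condition, y = .data$accuracy,
                                    fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::labs(x = "fMRI condition", y = "prediction accuracy (r)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (length(unique(accuracy_table$category)) > 1) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Plot node-behavior covariances of a fit
#'
#' @param object A `latentsna_mcmc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.latentsna_mcmc <- function(object, ...) {
  dat <- tidy(object)
  dat$node_id <- factor(dat$node_id, levels = dat$node_id)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$node_id, y = .data$covariance,
                                    fill = .data$covariance > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = "node", y = "node-behavior covariance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Radar-style profile of biomarker counts per functional system
#'
#' The spider-plot substrate: per-system counts of selected biomarker
#' nodes on a polar axis with all systems shown (zero counts included).
#'
#' @param object A `system_counts` tibble from [count_by_system()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.system_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$system, y = .data$count,
                                       group = 1)) +
    ggplot2::geom_polygon(fill = "#2166ac", alpha = 0.3) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "biomarker count") +
    ggplot2::theme_minimal()
}
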