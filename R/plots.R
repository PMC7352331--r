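# ggplot2 views of the main result types. These are working plots for
# exploring a screen, not publication figures.

#' Dose-response curves
#'
#' @param curves Curve table from [viability_curves()] (or a well table,
#'   which is collapsed first).
#' @param cell_lines,drugs Optional subsets.
#' @return A ggplot.
#' @export
plot_dose_response <- function(curves, cell_lines = NULL, drugs = NULL) {
  if ("viability_raw" %in% names(curves)) curves <- viability_curves(curves)
  if (!is.null(cell_lines)) curves <- curves[curves$cell_line %in% cell_lines, ]
  if (!is.null(drugs)) curves <- curves[curves$drug %in% drugs, ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$dose_molar,
                                       y = .data$viability,
                                       colour = .data$cell_line)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug)) +
    ggplot2::labs(x = "dose (M)", y = "viability fraction",
                  colour = "cell line") +
    ggplot2::theme_minimal()
}

#' Median-centered AUC heat map
#'
#' Cell lines x drugs tile map on the blue (sensitive) - white - red
#' (resistant) scale conventional for screen summaries.
#'
#' @param auc AUC tibble; centered values are computed if missing.
#' @return A ggplot.
#' @export
plot_auc_heatmap <- function(auc) {
  if (!"auc_centered" %in% names(auc)) auc <- median_center(auc)
  ggplot2::ggplot(auc, ggplot2::aes(x = .data$drug, y = .data$cell_line,
                                    fill = .data$auc_centered)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, top_n = 15, ...) {
  top <- as_tibble(object) %>%
    group_by(.data$drug) %>%
    arrange(dplyr::desc(abs(.data$mean_weight)), .by_group = TRUE) %>%
    dplyr::slice_head(n = top_n) %>%
    ungroup() %>%
    mutate(direction = ifelse(.data$mean_weight > 0,
                              "resistance", "sensitivity"))
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$mean_weight,
    y = stats::reorder(.data$gene, abs(.data$mean_weight)),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("(%.0f%%)",
                                                    100 * .data$frequency)),
                       hjust = -0.1, size = 2.8) +
    ggplot2::scale_fill_manual(values = c(resistance = "#b2182b",
                                          sensitivity = "#2166ac")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug), scales = "free_y") +
    ggplot2::labs(x = "average bootstrap weight", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot mutant_sensitivity_report
#' @export
autoplot.mutant_sensitivity_report <- function(object, ...) {
  gene <- attr(object, "gene", exact = TRUE)
  ec <- tidyr::unnest(as_tibble(object)[, c("drug", "ecdf")], "ecdf")
  ggplot2::ggplot(ec, ggplot2::aes(x = .data$response, y = .data$cum_frac,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug)) +
    ggplot2::labs(x = "median-centered AUC", y = "cumulative fraction",
                  colour = gene) +
    ggplot2::theme_minimal()
}
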