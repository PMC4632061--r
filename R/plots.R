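#' Plot a control-coefficient table
#'
#' Point estimates with percentile bootstrap intervals, one panel per enzyme,
#' compounds on the y axis in canonical order.
#'
#' @param object A `gsl_lambda_table` from [estimate_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsl_lambda_table <- function(object, ...) {
  df <- object[!object$missing_arm, , drop = FALSE]
  df$compound <- factor(df$compound, levels = rev(compound_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$compound)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~enzyme) +
    ggplot2::labs(x = "flux control coefficient λ (95% bootstrap CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-map style plot of proportional concentration changes
#'
#' Tile plot of the proportional change `(T_C - U_C) / U_C` per contrast and
#' compound, with significance stars, mirroring the study's heat-map figures.
#'
#' @param table Output of [proportional_change_table()].
#' @return A ggplot object.
#' @export
plot_proportional_change <- function(table) {
  df <- table
  df$compound <- factor(df$compound, levels = rev(compound_names()))
  df$stars <- sig_codes(df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$compound,
                                   fill = .data$prop_change)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "prop.\nchange") +
    ggplot2::theme_minimal()
}

#' Plot the expression meta-analysis
#'
#' Mean proportional expression change per gene across experiments with
#' standard-error bars.
#'
#' @param meta Output of [aggregate_expression()].
#' @return A ggplot object.
#' @export
plot_expression_meta <- function(meta) {
  df <- meta
  df$gene <- stats::reorder(df$gene, df$mean_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$mean_change)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_change - .data$se,
                   ymax = .data$mean_change + .data$se), width = 0.2,
      na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "proportional expression change") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
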