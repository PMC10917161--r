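#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of group connectivity summaries
#'
#' Tile heatmaps of the per-group mean, difference and SD matrices at one
#' scale — the "average graphs" view of a two-group cohort.
#'
#' @param object An `fcp_conn_summary`.
#' @param scale Scale to display (default: finest present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcp_conn_summary
#' @export
autoplot.fcp_conn_summary <- function(object, scale = min(object$scale), ...) {
  df <- tidy(object)
  df <- df[df$scale == scale, ]
  df$from <- factor(df$from, unique(df$from))
  df$to <- factor(df$to, levels(df$from))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(title = paste0("Connectivity summaries, scale ", scale),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Node-wise group differences by scale
#'
#' t statistics per node, faceted by scale, with uncorrected and
#' FDR-significant nodes marked.
#'
#' @param object An `fcp_nodewise` tibble.
#' @param metric Metric to display (default: first present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcp_nodewise
#' @export
autoplot.fcp_nodewise <- function(object, metric = object$metric[1], ...) {
  df <- object[object$metric == metric, ]
  sig <- dplyr::case_when(df$significant_fdr ~ "FDR",
                          df$significant_uncorrected ~ "uncorrected",
                          TRUE ~ "n.s.")
  df$sig <- factor(sig, c("n.s.", "uncorrected", "FDR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_id, y = .data$t_statistic,
                                   color = .data$sig)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~scale, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_color_manual(
      values = c(n.s. = "grey50", uncorrected = "orange", FDR = "red"),
      drop = FALSE) +
    ggplot2::labs(title = paste0("Node-wise group differences: ", metric),
                  x = "node", y = "t (patient - control)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Global metrics across scales by group
#'
#' @param global_tbl Tibble from [global_metric_table()].
#' @return A ggplot of group-mean global clustering and efficiency per scale.
#' @export
plot_global_metrics <- function(global_tbl) {
  df <- global_tbl |>
    tidyr::pivot_longer(c("global_clustering", "global_efficiency"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$scale, .data$group, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$scale), y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "scale (1 = finest)", y = "group mean") +
    ggplot2::theme_minimal()
}
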