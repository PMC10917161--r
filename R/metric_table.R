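#' Threshold a cohort's connectivity matrices
#'
#' Applies [proportional_threshold()] to every row of a connectivity tibble.
#'
#' @param conn Tibble from [cohort_connectivity()].
#' @param p Retained fraction (default 0.5).
#' @param mode Ranking mode, `"signed"` (default) or `"absolute"`.
#' @return The tibble with an added `adj` list-column of binary adjacency
#'   matrices.
#' @export
threshold_connectivity <- function(conn, p = 0.5,
                                   mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  dplyr::mutate(conn,
                adj = purrr::map(.data$conn, proportional_threshold,
                                 p = p, mode = mode))
}

#' Tidy per-node graph metrics for a cohort
#'
#' Computes clustering coefficient, local efficiency and betweenness
#' centrality for every subject's binary graph at every scale.
#'
#' @param graphs Tibble with an `adj` list-column
#'   (from [threshold_connectivity()]).
#' @param h Hierarchy used to attach node ids (default: packaged atlas).
#' @param normalized Normalize betweenness by `(N-1)(N-2)/2`? Default `TRUE`.
#' @return Tidy tibble: `subject_id`, `group`, `scale`, `node_id`,
#'   `node_name`, `metric`, `value`.
#' @export
metric_table <- function(graphs, h = fcp_hierarchy(), normalized = TRUE) {
  purrr::map_dfr(seq_len(nrow(graphs)), function(i) {
    s <- graphs$scale[i]
    gm <- graph_metrics(graphs$adj[[i]], normalized = normalized)
    gm$node |>
      tidyr::pivot_longer(c("clustering", "local_efficiency", "betweenness"),
                          names_to = "metric", values_to = "value") |>
      dplyr::transmute(subject_id = graphs$subject_id[i],
                       group = graphs$group[i], scale = s,
                       node_id = h$parcels[[s]]$id[match(.data$node,
                                                         h$parcels[[s]]$name)],
                       node_name = .data$node, metric = .data$metric,
                       value = .data$value)
  })
}

#' Global graph metrics for a cohort
#'
#' @inheritParams metric_table
#' @return Tibble: `subject_id`, `group`, `scale`, `global_clustering`,
#'   `global_efficiency`.
#' @export
global_metric_table <- function(graphs) {
  purrr::map_dfr(seq_len(nrow(graphs)), function(i) {
    g <- graph_metrics(graphs$adj[[i]])$global
    tibble::tibble(subject_id = graphs$subject_id[i], group = graphs$group[i],
                   scale = graphs$scale[i],
                   global_clustering = g$global_clustering,
                   global_efficiency = g$global_efficiency)
  })
}

#' Write a tidy metric table as TSV
#'
#' @param metric_tbl Tidy metric tibble.
#' @param path Output path.
#' @export
write_metric_tsv <- function(metric_tbl, path) {
  readr::write_tsv(metric_tbl, path, progress = FALSE)
  invisible(path)
}
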