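#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a node-wise test table
#'
#' @param x An `fcp_nodewise` tibble.
#' @param ... Unused.
#' @return Tibble with one row per (metric, scale): number of nodes, counts
#'   of uncorrected and FDR-corrected significant nodes, and the minimum p.
#' @method glance fcp_nodewise
#' @export
glance.fcp_nodewise <- function(x, ...) {
  x |>
    dplyr::group_by(.data$metric, .data$scale) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      n_sig_uncorrected = sum(.data$significant_uncorrected),
      n_sig_fdr = sum(.data$significant_fdr),
      min_p = min(.data$p_value), .groups = "drop")
}
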