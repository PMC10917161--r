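#' Average voxel time courses into node time courses
#'
#' For each parcel at `scale`, the unweighted mean of its member voxels'
#' time series. Node columns follow the atlas order at that scale.
#'
#' @param ts Time-by-voxel numeric matrix.
#' @param labels Finest-scale parcel id per voxel column.
#' @param h An `fcp_hierarchy`.
#' @param scale Target scale.
#' @return Time-by-node matrix with parcel names as column names.
#' @export
extract_node_timecourses <- function(ts, labels, h, scale = 1) {
  check_scale(h, scale)
  if (ncol(ts) != length(labels)) {
    stop("labels must have one entry per voxel column", call. = FALSE)
  }
  lab_s <- coarsen_labels(h, labels, scale)
  ids <- h$parcels[[scale]]$id
  empty <- setdiff(ids, lab_s)
  if (length(empty)) {
    stop("no voxels for node(s) ",
         paste(h$parcels[[scale]]$name[match(empty, ids)], collapse = ", "),
         " at scale ", scale, call. = FALSE)
  }
  idx <- match(lab_s, ids)
  ind <- matrix(0, length(lab_s), length(ids))   # voxel-to-node indicator
  ind[cbind(seq_along(idx), idx)] <- 1
  out <- sweep(ts %*% ind, 2, colSums(ind), "/")
  colnames(out) <- h$parcels[[scale]]$name
  out
}

#' Pearson functional connectivity matrix
#'
#' Sample Pearson correlations between all node pairs, with the diagonal
#' (self-self connections) set to 0.
#'
#' @param node_ts Time-by-node matrix (>= 3 time points; every column must
#'   have nonzero variance).
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
pearson_connectivity <- function(node_ts) {
  if (nrow(node_ts) < 3) stop("need at least 3 time points", call. = FALSE)
  v <- apply(node_ts, 2, stats::sd)
  if (any(v == 0)) {
    stop("zero-variance node series: ",
         paste(colnames(node_ts)[v == 0], collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(node_ts)
  diag(m) <- 0
  m
}

#' Binarize a connectivity matrix by proportional threshold
#'
#' Ranks the `N(N-1)/2` distinct node pairs by connectivity value, descending,
#' and keeps the top `round(P * N(N-1)/2)` as unweighted edges; everything
#' else, including the diagonal, becomes 0. By default ranking is on the
#' signed value (a strong negative correlation is a weak connection); set
#' `mode = "absolute"` to rank by magnitude. Ties at the cutoff are broken by
#' (row, column) order so results are deterministic. Rounding is half-up, so
#' an odd pair count at P = 0.5 keeps the extra edge (15 pairs -> 8 edges).
#'
#' @param m Symmetric numeric matrix (diagonal ignored).
#' @param p Retained fraction in `[0, 1]` (default 0.5).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return 0/1 adjacency matrix with attribute `retained_fraction`.
#' @export
proportional_threshold <- function(m, p = 0.5, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  n <- nrow(m)
  if (n != ncol(m)) stop("matrix must be square", call. = FALSE)
  ut <- which(upper.tri(m))
  vals <- m[ut]
  if (mode == "absolute") vals <- abs(vals)
  n_edges <- round_half_up(p * length(ut))
  adj <- matrix(0L, n, n, dimnames = dimnames(m))
  if (n_edges > 0) {
    # order() is stable, and upper.tri indices run in column-major (row,
    # column) order, so cutoff ties resolve deterministically
    keep <- ut[order(-vals)[seq_len(n_edges)]]
    adj[keep] <- 1L
    adj <- adj + t(adj)
  }
  attr(adj, "retained_fraction") <- p
  adj
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-subject, per-scale connectivity matrices for a cohort
#'
#' Runs [extract_node_timecourses()] and [pearson_connectivity()] for every
#' subject at the requested scales.
#'
#' @param cohort An `fcp_cohort`.
#' @param h Hierarchy (default: taken from the cohort's design, else the
#'   packaged atlas).
#' @param scales Scales to build (default: all).
#' @return A tibble: `subject_id`, `group`, `scale`, `conn` (list of
#'   correlation matrices).
#' @export
cohort_connectivity <- function(cohort, h = cohort_hierarchy(cohort),
                                scales = seq_len(h$n_scales)) {
  labels <- attr(cohort, "labels")
  tidyr::expand_grid(
    dplyr::tibble(subject_id = cohort$subject_id, group = cohort$group,
                  ts = cohort$ts),
    scale = as.integer(scales)) |>
    dplyr::mutate(
      conn = purrr::map2(ts, scale, function(x, s) {
        pearson_connectivity(extract_node_timecourses(x, labels, h, s))
      })) |>
    dplyr::select("subject_id", "group", "scale", "conn")
}

cohort_hierarchy <- function(cohort) {
  d <- attr(cohort, "design")
  if (!is.null(d)) d$hierarchy else fcp_hierarchy()
}

#' Nodal strength of a connectivity matrix
#'
#' Mean connectivity of each node to all other nodes (off-diagonal row
#' mean of the correlation matrix). The most direct node-wise measure of
#' inter-node coupling, and the natural statistic for detecting a nodal
#' loss of connectivity before any binarization.
#'
#' @param m Connectivity matrix with zero diagonal.
#' @return Named numeric vector, one value per node.
#' @export
node_strength <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  rowSums(m) / (n - 1)
}

#' Tidy nodal strength table for a cohort
#'
#' @param conn Tibble from [cohort_connectivity()].
#' @param h Hierarchy used to attach node ids.
#' @return Tidy metric tibble with `metric = "strength"`.
#' @export
strength_table <- function(conn, h = fcp_hierarchy()) {
  purrr::map_dfr(seq_len(nrow(conn)), function(i) {
    s <- conn$scale[i]
    v <- node_strength(conn$conn[[i]])
    tibble::tibble(subject_id = conn$subject_id[i], group = conn$group[i],
                   scale = s, node_id = h$parcels[[s]]$id,
                   node_name = h$parcels[[s]]$name,
                   metric = "strength", value = unname(v))
  })
}

#' Write / read a square matrix as TSV with node ids
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- tibble::add_column(df, node = rownames(m) %||% as.character(seq_len(nrow(m))),
                           .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Binary graph as an edge-list tibble
#'
#' @param adj 0/1 adjacency matrix.
#' @return Tibble `from`, `to` (upper-triangle pairs with an edge).
#' @export
graph_edgelist <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  nm <- rownames(adj) %||% as.character(seq_len(nrow(adj)))
  tibble::tibble(from = nm[idx[, 1]], to = nm[idx[, 2]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
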