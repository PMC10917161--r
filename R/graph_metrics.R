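#' Node clustering coefficients of a binary graph
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` is the number of triangles
#' through node i and `k_i` its degree; nodes with degree < 2 get `C_i = 0`
#' (the Brain Connectivity Toolbox convention, so values are comparable with
#' the neuroimaging literature).
#'
#' @param adj Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return Numeric vector of `C_i` in `[0, 1]`, named by node.
#' @export
clustering_coefficients <- function(adj) {
  check_adjacency(adj)
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  names(ci) <- rownames(adj)
  ci
}

#' Global clustering coefficient
#'
#' The mean of the node clustering coefficients.
#'
#' @inheritParams clustering_coefficients
#' @return A number in `[0, 1]`.
#' @export
global_clustering <- function(adj) mean(clustering_coefficients(adj))

#' All-pairs shortest path lengths (unweighted)
#'
#' Breadth-first distances; disconnected pairs are `Inf`, the diagonal 0.
#'
#' @inheritParams clustering_coefficients
#' @return N x N matrix of hop counts.
#' @export
shortest_path_lengths <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  # simultaneous BFS from all sources via boolean matrix products:
  # `frontier[s, v]` marks nodes first reached from s at the current step
  reach <- adj > 0
  frontier <- reach & is.infinite(d)
  step <- 1
  while (any(frontier)) {
    d[frontier] <- step
    frontier <- ((frontier %*% reach) > 0) & is.infinite(d)
    step <- step + 1
  }
  d
}

#' Global efficiency
#'
#' Mean of the inverse shortest path lengths over ordered node pairs
#' (i != j); disconnected pairs contribute 0, so no connectivity
#' precondition is needed (coarse-scale thresholded graphs may be
#' disconnected). Single-node and edgeless graphs give 0.
#'
#' @inheritParams clustering_coefficients
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- shortest_path_lengths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency
#'
#' `E_i` is the global efficiency of the subgraph induced on the neighbors
#' of node i (i itself excluded); nodes with degree < 2 get `E_i = 0`.
#'
#' @inheritParams clustering_coefficients
#' @return Numeric vector in `[0, 1]`, named by node.
#' @export
local_efficiency <- function(adj) {
  check_adjacency(adj)
  k <- rowSums(adj)
  ei <- vapply(seq_len(nrow(adj)), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(adj[i, ] > 0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  names(ei) <- rownames(adj)
  ei
}

#' Node betweenness centrality (Brandes, unweighted)
#'
#' `B_i` is the number of shortest paths between other node pairs that pass
#' through i, counted fractionally when a pair has several shortest paths.
#' With `normalized = TRUE` (default) the raw value is divided by
#' `(N-1)(N-2)/2`, the number of pairs that could route through i, so values
#' are comparable across scales with different node counts.
#'
#' @inheritParams clustering_coefficients
#' @param normalized Divide by `(N-1)(N-2)/2`? Default `TRUE`.
#' @return Numeric vector, named by node.
#' @export
betweenness_centrality <- function(adj, normalized = TRUE) {
  check_adjacency(adj)
  n <- nrow(adj)
  bc <- numeric(n)
  nbrs <- apply(adj > 0, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    # single-source shortest-path counts (BFS), then dependency accumulation
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (w in nbrs[[v]]) {
        if (dist[w] == dist[v] + 1L && sigma[w] > 0) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2  # undirected: every pair counted from both endpoints
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(adj)
  bc
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (any(adj != 0 & adj != 1)) {
    stop("adjacency must be binary (0/1)", call. = FALSE)
  }
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal",
                                call. = FALSE)
  if (any(adj != t(adj))) stop("adjacency must be symmetric", call. = FALSE)
  invisible(adj)
}

#' All local and global graph metrics of one binary graph
#'
#' @inheritParams betweenness_centrality
#' @return A list with `node` (tibble: node, clustering, local_efficiency,
#'   betweenness) and `global` (tibble: global_clustering,
#'   global_efficiency).
#' @export
graph_metrics <- function(adj, normalized = TRUE) {
  ci <- clustering_coefficients(adj)
  list(
    node = tibble::tibble(
      node = names(ci) %||% as.character(seq_along(ci)),
      clustering = unname(ci),
      local_efficiency = unname(local_efficiency(adj)),
      betweenness = unname(betweenness_centrality(adj, normalized))),
    global = tibble::tibble(
      global_clustering = mean(ci),
      global_efficiency = global_efficiency(adj)))
}
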