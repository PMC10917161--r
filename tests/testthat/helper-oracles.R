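# Independent brute-force graph oracles. These deliberately share no code
# with the package: Floyd-Warshall instead of BFS, explicit triple/pair
# enumeration instead of matrix algebra, path-count dynamic programming
# instead of Brandes accumulation.

bf_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + adj[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
# shells, then pair-wise through-node accumulation
bf_betweenness <- function(adj, normalized = FALSE) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(max(maxd, 1))) {
    for (s in seq_len(n)) {
      for (t in which(d[s, ] == len)) {
        pred <- which(adj[, t] == 1 & d[s, ] == len - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != i && t != i && is.finite(d[s, t]) &&
            d[s, i] + d[i, t] == d[s, t]) {
          b[i] <- b[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

# adjacency from an upper-triangle edge selection
adj_from_edges <- function(n, edge_idx) {
  adj <- matrix(0L, n, n)
  adj[which(upper.tri(adj))[edge_idx]] <- 1L
  adj + t(adj)
}

random_adjacency <- function(n, p = NULL, n_edges = NULL) {
  n_pairs <- n * (n - 1) / 2
  if (is.null(n_edges)) n_edges <- rbinom(1, n_pairs, p)
  adj_from_edges(n, sample.int(n_pairs, n_edges))
}

expect_metrics_match_oracle <- function(adj, tol = 1e-12) {
  expect_equal(unname(clustering_coefficients(adj)), bf_clustering(adj),
               tolerance = tol)
  expect_equal(unname(shortest_path_lengths(adj)), unname(bf_distances(adj)))
  expect_equal(global_efficiency(adj), bf_global_efficiency(adj),
               tolerance = tol)
  expect_equal(unname(local_efficiency(adj)), bf_local_efficiency(adj),
               tolerance = tol)
  expect_equal(unname(betweenness_centrality(adj, normalized = FALSE)),
               bf_betweenness(adj), tolerance = tol)
}

# small named graphs used across tests
graph_k <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L; adj
}
graph_star <- function(n) {
  adj <- matrix(0L, n, n); adj[1, -1] <- 1L; adj[-1, 1] <- 1L; adj
}
graph_path <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}
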