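test_that("node time courses are voxel means in atlas order", {
  toy <- toy_hierarchy()
  labs <- c(1L, 1L, 2L, 3L)
  ts <- cbind(c(1, 3, 5), c(3, 5, 7), c(0, 1, 2), c(9, 9, 9))
  nt <- extract_node_timecourses(ts, labs, toy, 1)
  expect_identical(colnames(nt), c("a", "b", "c"))
  expect_equal(nt[, "a"], c(2, 4, 6))          # mean of the two voxels
  expect_equal(nt[, "b"], c(0, 1, 2))
  # identical copies average to themselves
  ts2 <- cbind(c(1, 2, 3), c(1, 2, 3))
  h1 <- single_parcel_hierarchy()
  expect_equal(extract_node_timecourses(ts2, c(1L, 1L), h1, 1)[, "only"],
               c(1, 2, 3))
  expect_error(extract_node_timecourses(ts[, 1:2], c(1L, 1L), toy, 1),
               "no voxels for node")
})

test_that("coarse node series are voxel-count-weighted means of children", {
  co <- generate_cohort(cohort_design(
    fcp_hierarchy(), n_patients = 1, n_controls = 1, seed = 41,
    voxels_per_parcel = c(rep(2L, 42), rep(5L, 42))))   # unequal sizes
  h <- fcp_hierarchy()
  labs <- attr(co, "labels")
  nt1 <- extract_node_timecourses(co$ts[[1]], labs, h, 1)
  nt2 <- extract_node_timecourses(co$ts[[1]], labs, h, 2)
  vox_n <- table(factor(labs, levels = h$parcels[[1]]$id))
  anc2 <- h$ancestor[[2]][h$parcels[[1]]$id]
  for (q in h$parcels[[2]]$id[c(1, 20, 58)]) {
    kids <- which(anc2 == q)
    w <- as.numeric(vox_n[kids])
    expect_equal(nt2[, match(q, h$parcels[[2]]$id)],
                 nt1[, kids, drop = FALSE] %*% (w / sum(w)) |> as.vector(),
                 tolerance = 1e-12)
  }
})

test_that("Pearson connectivity matches the textbook formula", {
  # independent oracle: explicit sum formula, no stats::cor
  pearson_oracle <- function(x, y) {
    n <- length(x)
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    sxx <- sum(x^2) - sum(x)^2 / n
    syy <- sum(y^2) - sum(y)^2 / n
    sxy / sqrt(sxx * syy)
  }
  ts <- cbind(a = c(2.1, 4.3, 1.2, 5.5, 3.3, 0.7),
              b = c(1.0, 2.2, 6.1, 4.0, 2.5, 3.3),
              c = c(9.9, 1.1, 4.2, 3.7, 5.0, 2.8))
  m <- pearson_connectivity(ts)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], pearson_oracle(ts[, i], ts[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m))
  # affine invariance and anticorrelation
  x <- stats::rnorm(10)
  expect_equal(pearson_connectivity(cbind(x, 2 * x + 1))[1, 2], 1)
  expect_equal(pearson_connectivity(cbind(x, -x))[1, 2], -1)
  expect_error(pearson_connectivity(cbind(x, rep(1, 10))), "zero-variance")
  expect_error(pearson_connectivity(cbind(x[1:2], x[1:2] * 2)), "3 time")
})

test_that("proportional threshold keeps exactly the strongest pairs", {
  # 4 nodes, six distinct values: the 3 largest pairs must become edges
  m <- matrix(0, 4, 4)
  vals <- c(0.9, -0.2, 0.5, 0.1, 0.7, -0.8)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  adj <- proportional_threshold(m, 0.5)
  expect_identical(sum(adj) / 2, 3)
  keep <- which(upper.tri(m))[order(-vals)[1:3]]   # brute-force sort oracle
  expect_true(all(adj[keep] == 1))
  # limiting cases
  expect_true(all(proportional_threshold(m, 1)[upper.tri(m)] == 1))
  expect_identical(sum(proportional_threshold(m, 0)), 0L)
  # absolute-value mode promotes the -0.8 pair
  adj_abs <- proportional_threshold(m, 0.5, mode = "absolute")
  keep_abs <- which(upper.tri(m))[order(-abs(vals))[1:3]]
  expect_true(all(adj_abs[keep_abs] == 1))
  expect_identical(sum(adj_abs) / 2, 3)
})

test_that("edge count equals round(P * n_pairs) at every paper scale", {
  set.seed(99)
  for (n in c(84, 58, 16, 6, 4)) {
    for (p in c(0.2, 0.5, 0.8)) {
      x <- matrix(stats::rnorm(n * n), n)
      m <- (x + t(x)) / 2; diag(m) <- 0
      expect_identical(sum(proportional_threshold(m, p)) / 2,
                       floor(p * n * (n - 1) / 2 + 0.5))
    }
  }
  # half-up rounding: 6 nodes -> 15 pairs -> 8 edges at P = 0.5
  x <- matrix(stats::rnorm(36), 6); m <- (x + t(x)) / 2; diag(m) <- 0
  expect_identical(sum(proportional_threshold(m, 0.5)) / 2, 8)
})

test_that("binarization is invariant to strictly increasing transforms", {
  set.seed(7)
  x <- matrix(stats::rnorm(400), 20)
  m <- (x + t(x)) / 2; diag(m) <- 0
  for (f in list(function(v) atan(v), function(v) v^3,
                 function(v) stats::pnorm(v))) {
    mt <- f(m); diag(mt) <- 0
    expect_identical(proportional_threshold(m, 0.4),
                     proportional_threshold(mt, 0.4),
                     info = "rank-preserving transform changed the graph")
  }
})

test_that("connectivity matrices have the published shapes at five scales", {
  co <- small_cohort(n_per_group = 1, voxels_per_parcel = 1, seed = 2)
  conn <- cohort_connectivity(co)
  shapes <- vapply(conn$conn, nrow, integer(1))
  expect_identical(shapes[order(conn$scale)][seq(1, 10, 2)] |> unname(),
                   c(84L, 58L, 16L, 6L, 4L))
})

test_that("matrices and edge lists round-trip through TSV", {
  x <- matrix(stats::rnorm(16), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m <- (x + t(x)) / 2; diag(m) <- 0
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  expect_equal(read_matrix_tsv(p), m, tolerance = 1e-12)
  el <- graph_edgelist(proportional_threshold(m, 0.5))
  expect_named(el, c("from", "to"))
  expect_identical(nrow(el), 3L)
})

test_that("nodal strength is the off-diagonal row mean", {
  m <- matrix(c(0, .5, -.1, .5, 0, .3, -.1, .3, 0), 3)
  expect_equal(unname(node_strength(m)), c(.2, .4, .1))
})
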