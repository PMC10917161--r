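make_conn_tbl <- function(pat_mats, ctl_mats, scale = 1) {
  tibble::tibble(
    subject_id = c(sprintf("p%d", seq_along(pat_mats)),
                   sprintf("c%d", seq_along(ctl_mats))),
    group = factor(rep(c("patient", "control"),
                       c(length(pat_mats), length(ctl_mats))),
                   levels = c("patient", "control")),
    scale = scale, conn = c(pat_mats, ctl_mats))
}

sym4 <- function(seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(16), 4)
  m <- (x + t(x)) / 2; diag(m) <- 0; m
}

test_that("connectivity summaries match direct elementwise arithmetic", {
  pats <- list(sym4(1), sym4(2), sym4(3))
  ctls <- list(sym4(4), sym4(5), sym4(6))
  sm <- summarize_connectivity(make_conn_tbl(pats, ctls))
  # direct loops, independent of the apply-based implementation
  mp <- matrix(0, 4, 4); mc <- matrix(0, 4, 4)
  for (m in pats) mp <- mp + m / 3
  for (m in ctls) mc <- mc + m / 3
  expect_equal(sm$mean_patient[[1]], mp, tolerance = 1e-12)
  expect_equal(sm$difference[[1]], mc - mp, tolerance = 1e-12)
  sd_elem <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    sd_elem[i, j] <- stats::sd(c(pats[[1]][i, j], pats[[2]][i, j],
                                 pats[[3]][i, j]))
  }
  expect_equal(sm$sd_patient[[1]], sd_elem, tolerance = 1e-12)
})

test_that("degenerate groups give zero difference and zero spread", {
  m <- sym4(7)
  sm <- summarize_connectivity(make_conn_tbl(list(m, m), list(m, m)))
  expect_equal(sm$difference[[1]], matrix(0, 4, 4))
  expect_equal(sm$sd_patient[[1]], matrix(0, 4, 4))
  expect_equal(sm$sd_control[[1]], matrix(0, 4, 4))
  expect_error(summarize_connectivity(make_conn_tbl(list(m), list(m, m))),
               ">= 2 subjects")
  tall <- make_conn_tbl(list(m, m), list(m, sym4(1)[1:3, 1:3]))
  expect_error(summarize_connectivity(tall), "mismatch")
})

test_that("pooled t matches the hand-computed textbook value", {
  tbl <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    group = factor(rep(c("patient", "control"), each = 3),
                   levels = c("patient", "control")),
    scale = 1L, node_id = 1L, node_name = "a", metric = "m",
    value = c(1, 2, 3, 4, 5, 6))
  res <- nodewise_ttest(tbl)
  expect_equal(res$t_statistic, -3.674, tolerance = 5e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-3.6742346, 4), tolerance = 1e-6)
  # swapping group labels negates t, p unchanged
  tbl2 <- tbl
  tbl2$group <- factor(rep(c("control", "patient"), each = 3),
                       levels = c("patient", "control"))
  res2 <- nodewise_ttest(tbl2)
  expect_equal(res2$t_statistic, -res$t_statistic)
  expect_equal(res2$p_value, res$p_value)
  # identical groups: t = 0, p = 1
  tbl3 <- tbl
  tbl3$value <- c(1, 2, 3, 1, 2, 3)
  res3 <- nodewise_ttest(tbl3)
  expect_equal(res3$t_statistic, 0)
  expect_equal(res3$p_value, 1)
  # constant metric at a node: warning and p = 1
  tbl4 <- tbl
  tbl4$value <- rep(5, 6)
  expect_warning(res4 <- nodewise_ttest(tbl4), "zero pooled variance")
  expect_equal(res4$p_value, 1)
})

test_that("Welch mode reproduces stats::t.test", {
  withr::with_seed(8, {
    x <- stats::rnorm(10); y <- stats::rnorm(12, sd = 3)
  })
  tbl <- tibble::tibble(
    subject_id = sprintf("s%d", 1:22),
    group = factor(rep(c("patient", "control"), c(10, 12)),
                   levels = c("patient", "control")),
    scale = 1L, node_id = 1L, node_name = "a", metric = "m",
    value = c(x, y))
  res <- nodewise_ttest(tbl, welch = TRUE)
  ref <- stats::t.test(x, y)
  expect_equal(res$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # and pooled mode reproduces var.equal = TRUE
  res_p <- nodewise_ttest(tbl)
  ref_p <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res_p$t_statistic, unname(ref_p$statistic), tolerance = 1e-12)
})

test_that("BH step-up follows the worked examples and p.adjust", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$reject))
  expect_true(all(fdr_bh(rep(0.001, 8))$reject))
  expect_equal(fdr_bh(0.037)$q, 0.037)        # m = 1: q = p
  # independent oracle: stats::p.adjust
  withr::with_seed(9, p <- stats::runif(50)^2)
  expect_equal(fdr_bh(p)$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values are monotone and rejections form a prefix", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      p <- stats::runif(sample(5:40, 1))
      r <- fdr_bh(p, alpha = 0.1)
      ord <- order(p)
      expect_true(all(diff(r$q[ord]) >= -1e-15))
      expect_true(all(r$q >= p - 1e-15))              # q >= p elementwise
      rej_sorted <- r$reject[ord]
      if (any(rej_sorted)) {
        expect_true(all(rej_sorted[seq_len(max(which(rej_sorted)))]))
      }
    }
  })
})

test_that("FDR families are per metric-scale and flags are consistent", {
  co <- small_cohort(n_per_group = 4, voxels_per_parcel = 1, seed = 19)
  al <- cohort_alff(co, scales = c(1, 5))
  res <- nodewise_ttest(al)
  expect_s3_class(res, "fcp_nodewise")
  expect_true(all(res$fdr_q >= res$p_value - 1e-15))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  # family-wise q equals applying fdr_bh inside each scale by hand
  for (s in c(1, 5)) {
    sub <- res[res$scale == s, ]
    expect_equal(sub$fdr_q, fdr_bh(sub$p_value)$q, tolerance = 1e-12)
  }
  g <- glance(res)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$n_nodes == c(84L, 4L)))
})
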