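#' Population summaries of connectivity matrices
#'
#' Elementwise per-group mean, control-minus-patient difference, and
#' per-group sample standard deviation of the unthresholded correlation
#' matrices, per scale — the "average graph / difference / spread" view of a
#' two-group cohort.
#'
#' @param conn Tibble from [cohort_connectivity()] (columns `subject_id`,
#'   `group`, `scale`, `conn`); needs >= 2 subjects per group.
#' @return An `fcp_conn_summary`: tibble with one row per scale and
#'   list-columns `mean_patient`, `mean_control`, `difference`
#'   (control - patient), `sd_patient`, `sd_control`.
#' @export
summarize_connectivity <- function(conn) {
  stack_stat <- function(mats, f) {
    dims <- vapply(mats, dim, integer(2))
    if (any(dims != dims[, 1])) stop("matrix shape mismatch", call. = FALSE)
    a <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
    out <- apply(a, c(1, 2), f)
    dimnames(out) <- dimnames(mats[[1]])
    out
  }
  out <- conn |>
    dplyr::group_by(.data$scale) |>
    dplyr::group_modify(function(df, key) {
      pat <- df$conn[df$group == "patient"]
      ctl <- df$conn[df$group == "control"]
      if (length(pat) < 2 || length(ctl) < 2) {
        stop("need >= 2 subjects per group at scale ", key$scale,
             call. = FALSE)
      }
      mp <- stack_stat(pat, mean)
      mc <- stack_stat(ctl, mean)
      tibble::tibble(mean_patient = list(mp), mean_control = list(mc),
                     difference = list(mc - mp),
                     sd_patient = list(stack_stat(pat, stats::sd)),
                     sd_control = list(stack_stat(ctl, stats::sd)))
    }) |>
    dplyr::ungroup()
  class(out) <- c("fcp_conn_summary", class(out))
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: with p-values sorted ascending, `q_(i) = min_{j >= i}
#' m p_(j) / j`, clipped to 1; reject where `q <= alpha`. Rejections form a
#' prefix of the sorted p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false discovery rate (default 0.05).
#' @return A list with `q` (q-values, input order) and `reject` (logical).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q = q, reject = q <= alpha)
}

#' Node-wise two-sample t-tests with FDR correction
#'
#' For every (metric, scale, node) cell of a tidy metric table, a two-tailed
#' two-sample Student's t-test (pooled variance by default; `welch = TRUE`
#' for unequal variances) comparing patients against controls, followed by
#' Benjamini-Hochberg correction applied per (metric, scale) family. The t
#' statistic is `patient mean - control mean` over its standard error, so
#' negative t means patients lower. A node where the pooled variance is zero
#' gets t = 0, p = 1 with a warning.
#'
#' @param metric_tbl Tidy tibble with columns `subject_id`, `group`,
#'   `scale`, `node_id`, `node_name`, `metric`, `value` (e.g. from
#'   [metric_table()] or [cohort_alff()]).
#' @param alpha Significance / FDR level (default 0.05).
#' @param welch Use the Welch (unequal-variance) test? Default `FALSE`
#'   (classical pooled-variance Student's test).
#' @return An `fcp_nodewise` tibble: `metric`, `scale`, `node_id`,
#'   `node_name`, `mean_patient`, `mean_control`, `t_statistic`, `df`,
#'   `p_value`, `fdr_q`, `significant_uncorrected`, `significant_fdr`.
#' @export
nodewise_ttest <- function(metric_tbl, alpha = 0.05, welch = FALSE) {
  res <- metric_tbl |>
    dplyr::group_by(.data$metric, .data$scale, .data$node_id,
                    .data$node_name) |>
    dplyr::group_modify(function(df, key) {
      x <- df$value[df$group == "patient"]
      y <- df$value[df$group == "control"]
      if (length(x) < 2 || length(y) < 2) {
        stop("need >= 2 subjects per group per node", call. = FALSE)
      }
      tt <- two_sample_t(x, y, welch)
      tibble::tibble(mean_patient = mean(x), mean_control = mean(y),
                     t_statistic = tt$t, df = tt$df, p_value = tt$p)
    }) |>
    dplyr::ungroup()
  res <- res |>
    dplyr::group_by(.data$metric, .data$scale) |>
    dplyr::mutate(fdr_q = fdr_bh(.data$p_value, alpha)$q) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant_uncorrected = .data$p_value < alpha,
                  significant_fdr = .data$fdr_q <= alpha)
  class(res) <- c("fcp_nodewise", class(res))
  attr(res, "alpha") <- alpha
  res
}

two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      warning("zero variance in both groups; t set to 0, p to 1")
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (mean(x) - mean(y)) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      warning("zero pooled variance; t set to 0, p to 1")
      return(list(t = 0, df = df, p = 1))
    }
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @method tidy fcp_conn_summary
#' @export
tidy.fcp_conn_summary <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    purrr::map_dfr(
      c("mean_patient", "mean_control", "difference", "sd_patient",
        "sd_control"),
      function(stat) {
        m <- x[[stat]][[i]]
        nm <- rownames(m) %||% as.character(seq_len(nrow(m)))
        idx <- which(upper.tri(m), arr.ind = TRUE)
        tibble::tibble(scale = x$scale[i], statistic = stat,
                       from = nm[idx[, 1]], to = nm[idx[, 2]],
                       value = m[idx])
      })
  })
}
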