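#' Assemble subject-by-node feature matrices
#'
#' Builds the per-scale feature vectors (one column per node of the
#' requested scale) or their all-scale concatenation (finest scale first,
#' nodes in atlas order within scale) for one metric. With the packaged
#' atlas the per-scale dimensions are 84/58/16/6/4 and the concatenation has
#' 168 columns.
#'
#' @param metric_tbl Tidy metric tibble (`subject_id`, `group`, `scale`,
#'   `node_id`, `node_name`, `metric`, `value`).
#' @param metric Which metric to extract (e.g. `"clustering"`, `"alff"`).
#' @param scales Integer scales to include, or `"all"` (default) for the
#'   concatenation of every scale present.
#' @return An `fcp_features` object: list with `x` (subjects x features
#'   matrix), `features` (tibble `scale`, `node_id`, `node_name`, `metric`),
#'   `labels` (+1 patient / -1 control), `subject_id`, `group`.
#' @export
assemble_features <- function(metric_tbl, metric, scales = "all") {
  tbl <- metric_tbl[metric_tbl$metric == metric, ]
  if (!nrow(tbl)) stop("no rows for metric '", metric, "'", call. = FALSE)
  if (identical(scales, "all")) scales <- sort(unique(tbl$scale))
  tbl <- tbl[tbl$scale %in% scales, ]
  subj <- unique(tbl[, c("subject_id", "group")])
  subj <- subj[order(subj$subject_id), ]   # row-order invariance
  feats <- unique(tbl[, c("scale", "node_id", "node_name")])
  feats <- feats[order(feats$scale, feats$node_id), ]
  feats$metric <- metric

  key_f <- paste(tbl$scale, tbl$node_id)
  col <- match(key_f, paste(feats$scale, feats$node_id))
  row <- match(tbl$subject_id, subj$subject_id)
  x <- matrix(NA_real_, nrow(subj), nrow(feats),
              dimnames = list(subj$subject_id,
                              paste0("s", feats$scale, "_", feats$node_name)))
  x[cbind(row, col)] <- tbl$value
  if (anyNA(x)) {
    miss <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing value for subject ", rownames(x)[miss[1]], ", feature ",
         colnames(x)[miss[2]], call. = FALSE)
  }
  structure(list(
    x = x, features = tibble::as_tibble(feats),
    labels = ifelse(subj$group == "patient", 1L, -1L),
    subject_id = subj$subject_id, group = subj$group),
    class = "fcp_features")
}

#' @export
print.fcp_features <- function(x, ...) {
  cat("<fcp_features> ", nrow(x$x), " subjects x ", ncol(x$x), " features (",
      x$features$metric[1], ", scales ",
      paste(sort(unique(x$features$scale)), collapse = ","), ")\n", sep = "")
  invisible(x)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated SVM classification of feature matrices
#'
#' Stratified k-fold cross-validation of a support vector machine (LIBSVM
#' via e1071; linear kernel and cost 1 by default). Within every fold,
#' features are standardized using training-fold statistics only, the SVM is
#' fit on the training folds and the held-out fold is predicted; confusion
#' counts are pooled across folds. With the patient class positive:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, all reported as percentages.
#'
#' @param fm An `fcp_features` object (or a plain list with `x` and
#'   `labels`).
#' @param k_folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param kernel,cost SVM kernel and regularization constant
#'   (defaults `"linear"`, 1).
#' @return An `fcp_cv_report`: list with `specificity`, `sensitivity`,
#'   `accuracy` (percentages), `confusion` (pooled TP/TN/FP/FN), `folds`
#'   (per-fold tibble), and `config`.
#' @export
crossval_svm <- function(fm, k_folds = 10, seed = 1,
                         kernel = "linear", cost = 1) {
  x <- fm$x
  y <- fm$labels
  if (length(unique(y)) < 2) stop("both labels must be present", call. = FALSE)
  if (nrow(x) < k_folds) stop("need at least k_folds subjects", call. = FALSE)
  fold <- stratified_folds(y, k_folds, seed)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      stop("training folds must contain both classes; reduce k_folds",
           call. = FALSE)
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sdev <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdev[sdev == 0] <- 1   # degenerate (constant) features pass through
    xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
    fit <- e1071::svm(xs[tr, , drop = FALSE], factor(y[tr], c(-1, 1)),
                      kernel = kernel, cost = cost, scale = FALSE)
    pred <- as.integer(as.character(
      stats::predict(fit, xs[!tr, , drop = FALSE])))
    truth <- y[!tr]
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_test = sum(!tr),
      tp = sum(pred == 1 & truth == 1), tn = sum(pred == -1 & truth == -1),
      fp = sum(pred == 1 & truth == -1), fn = sum(pred == -1 & truth == 1))
  }
  folds <- dplyr::bind_rows(per_fold)
  conf <- colSums(folds[, c("tp", "tn", "fp", "fn")])
  report <- structure(list(
    sensitivity = 100 * conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]),
    specificity = 100 * conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]),
    accuracy = 100 * (conf[["tp"]] + conf[["tn"]]) / sum(conf),
    confusion = as.list(conf), folds = folds,
    config = list(kernel = kernel, cost = cost, k_folds = k_folds,
                  seed = seed, pooling = "pooled confusion counts",
                  standardization = "training-fold z-scoring")),
    class = "fcp_cv_report")
  report
}

#' Classification rates from pooled confusion counts
#'
#' @param tp,tn,fp,fn Pooled confusion counts, patient class positive.
#' @return Tibble with `sensitivity`, `specificity`, `accuracy` as
#'   percentages.
#' @export
confusion_rates <- function(tp, tn, fp, fn) {
  tibble::tibble(sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' @export
print.fcp_cv_report <- function(x, ...) {
  cat(sprintf(
    "<fcp_cv_report> %d-fold CV (%s kernel, C=%g, seed %d)\n",
    x$config$k_folds, x$config$kernel, x$config$cost, x$config$seed))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @method tidy fcp_cv_report
#' @export
tidy.fcp_cv_report <- function(x, ...) x$folds

#' @method glance fcp_cv_report
#' @export
glance.fcp_cv_report <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, tp = x$confusion$tp,
                 tn = x$confusion$tn, fp = x$confusion$fp,
                 fn = x$confusion$fn, k_folds = x$config$k_folds,
                 kernel = x$config$kernel, cost = x$config$cost,
                 seed = x$config$seed)
}

#' Write a feature matrix as TSV
#'
#' Columns are named `s<scale>_<node_name>`; the first two columns are
#' subject id and group.
#'
#' @param fm An `fcp_features`.
#' @param path Output path.
#' @export
write_features_tsv <- function(fm, path) {
  df <- tibble::as_tibble(fm$x)
  df <- tibble::add_column(df, subject_id = fm$subject_id,
                           group = as.character(fm$group), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
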