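#' Run the multi-scale network pipeline end to end
#'
#' Orchestrates the stages `simulate` (synthetic cohort), `connect`
#' (node time courses + Pearson connectivity + proportional thresholding),
#' `metrics` (graph metrics), `alff` (node-averaged ALFF), `stats`
#' (connectivity summaries and node-wise t-tests with FDR) and `classify`
#' (per-scale and combined SVM cross-validation), writing every intermediate
#' artifact as TSV/JSON under the output directory plus a machine-readable
#' run manifest (parameters, seed, package version, per-artifact md5
#' hashes). Stages are validated before any work starts; a failing stage
#' aborts with an error naming it. Runs with the same config and seed
#' produce identical artifacts.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Recognised fields (all optional): `out_dir`, `seed`,
#'   `stages`, `design` (arguments of [cohort_design()] except the
#'   hierarchy), `hierarchy_table` (path for [load_hierarchy()]; default the
#'   packaged atlas), `scales`, `threshold_p`, `threshold_mode`, `band`,
#'   `alpha`, `k_folds`, `svm` (`kernel`, `cost`), `metrics` (metric names
#'   to classify on).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with `manifest` (the manifest as a list),
#'   `out_dir`, and the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "connect", "metrics", "alff", "stats",
                  "classify")
  cfg <- utils::modifyList(list(
    out_dir = tempfile("fcp_run_"), seed = 1L, stages = stages_all,
    design = list(), hierarchy_table = NULL, scales = NULL,
    threshold_p = 0.5, threshold_mode = "signed", band = c(0.01, 0.1),
    alpha = 0.05, k_folds = 10, svm = list(kernel = "linear", cost = 1),
    metrics = c("clustering", "local_efficiency", "betweenness", "alff")),
    config)
  if (!is.null(seed)) cfg$seed <- seed
  unknown <- setdiff(cfg$stages, stages_all)
  if (length(unknown)) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  h <- if (is.null(cfg$hierarchy_table)) fcp_hierarchy() else
    load_hierarchy(cfg$hierarchy_table)
  scales <- if (is.null(cfg$scales)) seq_len(h$n_scales) else
    as.integer(cfg$scales)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  results <- list()
  add_artifact <- function(path) artifacts <<- c(artifacts, path)

  run_stage <- function(name, f) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    design <- do.call(cohort_design,
                      c(list(hierarchy = h, seed = cfg$seed,
                             band = cfg$band), cfg$design))
    results$cohort <<- generate_cohort(design)
    dir <- file.path(out, "cohort")
    write_cohort_tsv(results$cohort, dir)
    add_artifact(list.files(dir, full.names = TRUE))
  })

  needs_cohort <- function() {
    if (is.null(results$cohort)) {
      stop("no cohort available (did the simulate stage run?)")
    }
  }

  run_stage("connect", function() {
    needs_cohort()
    conn <- cohort_connectivity(results$cohort, h, scales)
    results$conn <<- conn
    results$graphs <<- threshold_connectivity(conn, cfg$threshold_p,
                                              cfg$threshold_mode)
    dir <- file.path(out, "connectivity")
    dir.create(dir, showWarnings = FALSE)
    for (i in seq_len(nrow(conn))) {
      p <- file.path(dir, sprintf("%s_scale%d.tsv", conn$subject_id[i],
                                  conn$scale[i]))
      write_matrix_tsv(conn$conn[[i]], p)
      add_artifact(p)
    }
  })

  run_stage("metrics", function() {
    if (is.null(results$graphs)) stop("no graphs (run the connect stage)")
    results$metrics <<- metric_table(results$graphs, h)
    results$global <<- global_metric_table(results$graphs)
    p1 <- file.path(out, "node_metrics.tsv")
    p2 <- file.path(out, "global_metrics.tsv")
    write_metric_tsv(results$metrics, p1)
    write_metric_tsv(results$global, p2)
    add_artifact(c(p1, p2))
  })

  run_stage("alff", function() {
    needs_cohort()
    results$alff <<- cohort_alff(results$cohort, h, scales, cfg$band)
    p <- file.path(out, "alff.tsv")
    write_metric_tsv(results$alff, p)
    add_artifact(p)
  })

  run_stage("stats", function() {
    if (is.null(results$conn)) stop("no connectivity (run connect)")
    metric_all <- dplyr::bind_rows(results$metrics, results$alff)
    if (is.null(metric_all) || !nrow(metric_all)) {
      stop("no metric tables (run the metrics and/or alff stages)")
    }
    results$summary <<- summarize_connectivity(results$conn)
    results$tests <<- nodewise_ttest(metric_all, cfg$alpha)
    p <- file.path(out, "nodewise_tests.tsv")
    readr::write_tsv(results$tests, p, progress = FALSE)
    add_artifact(p)
    for (i in seq_len(nrow(results$summary))) {
      for (stat in c("difference", "sd_patient", "sd_control")) {
        f <- file.path(out, sprintf("conn_%s_scale%d.tsv", stat,
                                    results$summary$scale[i]))
        write_matrix_tsv(results$summary[[stat]][[i]], f)
        add_artifact(f)
      }
    }
  })

  run_stage("classify", function() {
    metric_all <- dplyr::bind_rows(results$metrics, results$alff)
    if (is.null(metric_all) || !nrow(metric_all)) {
      stop("no metric tables (run the metrics and/or alff stages)")
    }
    reports <- list()
    for (m in intersect(cfg$metrics, unique(metric_all$metric))) {
      for (sc in c(as.list(scales), list("all"))) {
        fm <- assemble_features(metric_all, m, sc)
        rep <- crossval_svm(fm, cfg$k_folds, cfg$seed,
                            cfg$svm$kernel, cfg$svm$cost)
        key <- if (identical(sc, "all")) "combined" else paste0("scale", sc)
        reports[[paste(m, key, sep = "_")]] <- glance(rep)
      }
    }
    results$classification <<- dplyr::bind_rows(reports, .id = "features")
    p <- file.path(out, "classification.json")
    jsonlite::write_json(results$classification, p, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    add_artifact(p)
  })

  manifest <- list(
    package = "fcpyramid",
    version = as.character(utils::packageVersion("fcpyramid")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[c("threshold_p", "threshold_mode", "band", "alpha",
                       "k_folds", "svm", "scales", "metrics", "design")],
    artifacts = lapply(sort(unlist(artifacts)), function(f) {
      list(file = sub(paste0("^", out, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(list(manifest = manifest, out_dir = out), results))
}
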