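#!/usr/bin/env Rscript
# Thin shell entry point: run the full pipeline from a YAML config.
#   Rscript -e 'source(system.file("pipeline.R", package = "fcpyramid"))' \
#     --args --config cfg.yaml --seed 1 --out results/
suppressPackageStartupMessages(library(fcpyramid))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
cfg <- get_arg("--config")
cfg <- if (is.null(cfg)) list() else yaml::read_yaml(cfg)
out <- get_arg("--out"); if (!is.null(out)) cfg$out_dir <- out
seed <- get_arg("--seed")
res <- run_pipeline(cfg, seed = if (is.null(seed)) NULL else as.integer(seed))
cat("pipeline complete:", res$out_dir, "\n")
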