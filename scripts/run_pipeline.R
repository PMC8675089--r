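#!/usr/bin/env Rscript
# Thin shell entry point for the full analysis pipeline.
#
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--config cfg.yaml]
#                                  [--seed <int>] [--demo] [--verbose]
#
# --config takes a YAML pipeline configuration (see
# trustgame::write_pipeline_config); without it the canonical defaults are
# used, or the small demonstration configuration with --demo. --seed
# overrides the configuration's master seed.

suppressPackageStartupMessages(library(trustgame))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = NULL, config = NULL, seed = NULL,
            demo = FALSE, verbose = FALSE)
i <- 1L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else if (a == "--config") { opt$config <- args[i + 1L]; i <- i + 2L }
  else if (a == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (a == "--demo") { opt$demo <- TRUE; i <- i + 1L }
  else if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1L }
  else stop(sprintf("unknown argument: %s", a))
}
if (is.null(opt$out)) stop("--out <directory> is required")

config <- if (!is.null(opt$config)) {
  read_pipeline_config(opt$config)
} else if (opt$demo) {
  demo_config()
} else {
  pipeline_config()
}
if (!is.null(opt$seed)) config$seed <- opt$seed

run <- run_pipeline(config, opt$out, verbose = opt$verbose)
print(run)
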