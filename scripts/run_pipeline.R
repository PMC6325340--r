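#!/usr/bin/env Rscript
# Thin command-line wrapper around benthosurvey::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 1]
#                                       [--outdir out/] [--no-effort]

suppressPackageStartupMessages({
  library(benthosurvey)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (optional)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration seed"),
  make_option("--outdir", type = "character", default = "out",
              help = "output directory for CSV tables and ASCII grids"),
  make_option("--no-effort", action = "store_true", default = FALSE,
              dest = "no_effort",
              help = "skip the sampling-effort evaluation stage"))))

cfg <- if (is.null(opts$config)) run_config() else read_run_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed

res <- run_pipeline(cfg, outdir = opts$outdir, effort = !opts$no_effort)
print(res)
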