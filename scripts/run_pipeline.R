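#!/usr/bin/env Rscript
# Thin command-line wrapper over ndbar::run_ndba_pipeline().
#   Rscript scripts/run_pipeline.R --config run.yaml --out outdir/ --seed 1

suppressPackageStartupMessages(library(ndbar))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

config_path <- get_arg("--config")
out_dir <- get_arg("--out", "ndba_out")
seed <- get_arg("--seed")

config <- tryCatch({
  cfg <- if (is.null(config_path)) ndba_config() else read_run_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}, error = function(e) {
  message("Configuration error: ", conditionMessage(e))
  quit(status = 1)
})

run <- run_ndba_pipeline(config, out_dir = out_dir)
print(run)
message("outputs written to ", out_dir)
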