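#!/usr/bin/env Rscript
# Step 2 — gate the simulated wells (compensation, viability, singlets,
# FMO positivity) and assemble the percent-positive matrix. Reads the
# manifest written by step 1; writes the matrix, per-well gate summaries
# (QC report) and the condition dendrogram under results/screen_run/.
#
# Run from the repository root after 01_simulate_screen.R.

suppressPackageStartupMessages(library(htfc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- pipeline_config(out_dir = "results/screen_run", seed = seed,
                       format = "fcs")
out <- run_screen(cfg)

qc <- read.csv(out$qc, skip = 1)
cat(sprintf("gated %d wells; %d passed QC (>= %d analysis events)\n",
            nrow(qc), sum(qc$qc_pass), cfg$gate$min_events))
mat <- read.csv(out$matrix, skip = 1, check.names = FALSE)
cat("percent-positive matrix:", nrow(mat), "conditions x",
    ncol(mat) - 1, "antigens ->", out$matrix, "\n")
cat("outputs:", paste(unlist(out), collapse = "\n         "), "\n")
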