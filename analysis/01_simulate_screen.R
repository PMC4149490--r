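#!/usr/bin/env Rscript
# Step 1 — simulate the screen's raw data: the demonstration mixed-lineage
# pool stained across the packaged 24-antibody panel, untreated and after
# the planted enzymatic-digestion perturbation. Writes one FCS 3.0 file per
# well plus a JSON manifest of seeds and planted truth.
#
# Run from the repository root: Rscript analysis/01_simulate_screen.R [seed]

suppressPackageStartupMessages(library(htfc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- pipeline_config(out_dir = "results/screen_run", seed = seed,
                       format = "fcs")
manifest <- run_simulate(cfg)

man <- jsonlite::read_json(manifest)
cat("conditions simulated:", paste(names(man$conditions), collapse = ", "), "\n")
cat("wells per condition: ", length(man$conditions$untreated$files), "\n")
cat("manifest:            ", manifest, "\n")
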