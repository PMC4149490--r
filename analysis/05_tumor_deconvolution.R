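#!/usr/bin/env Rscript
# Step 5 — intratumoral heterogeneity: co-stain the synthetic tumor with
# the CD45 / CD31 / CD34 / TE7 lineage panel, deconvolve each antibody
# well into immune, endothelial, fibroblast and cancer populations, build
# a per-population percent-positive matrix, and rank candidate fibroblast
# markers (high on pure fibroblasts, low on the non-immune, non-endothelial
# tumor fraction).
#
# Run from the repository root: Rscript analysis/05_tumor_deconvolution.R [seed]

suppressPackageStartupMessages(library(htfc))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

map <- demo_plate_map()
pops <- demo_tumor_populations()
noise <- demo_tumor_noise(events_per_well = 5000)
cfg <- gate_config(min_events = 500)
costains <- demo_costains()
cs_channels <- vapply(costains, `[[`, "", "channel_name")

wells <- simulate_screen_plate(map, pops, noise, seed = seed,
                               costains = costains, sample_id = "TUMOR1")
wells <- lapply(wells, apply_compensation, spill = noise$spillover)

wm <- map$wells
key <- paste(wm$plate, wm$well, sep = "/")
unstained <- wells[[key[wm$antigen == "CONTROL" & wm$fluorochrome == "NONE"][1]]]
via_thr <- fmo_threshold(unstained, cfg$viability_channel,
                         cfg$viability_fmo_percentile)
cs_thr <- sapply(cs_channels, function(ch) {
  fmo_threshold(unstained, ch, cfg$positivity_fmo_percentile)
})

# per-fluorochrome panel thresholds from the buffer-only controls
panel_thr <- sapply(c("PE", "FITC", "APC"), function(fl) {
  ctrl <- wells[[key[wm$antigen == "CONTROL" & wm$fluorochrome == fl][1]]]
  g <- gate_events(ctrl, cfg, via_thr)
  fmo_threshold(event_table(ctrl[g$masks$analysis, , drop = FALSE]),
                fluorochrome_channel(fl), cfg$positivity_fmo_percentile)
})
names(panel_thr) <- fluorochrome_channel(c("PE", "FITC", "APC"))

spec <- costain_gate_spec()
pop_names <- vapply(spec$rules, `[[`, "", "population")
rows <- setNames(vector("list", length(pop_names)), pop_names)
abund <- c()
for (i in which(wm$antigen != "CONTROL")) {
  ev <- wells[[key[i]]]
  ch <- fluorochrome_channel(wm$fluorochrome[i])
  g <- gate_events(ev, cfg, via_thr)
  masks <- deconvolve_lineages(ev, spec, cs_thr)
  if (!length(abund)) {
    abund <- sapply(masks, function(m) mean(m[g$masks$analysis]))
  }
  for (p in pop_names) {
    sel <- g$masks$analysis & masks[[p]]
    rows[[p]][wm$antigen[i]] <-
      100 * sum(ev[sel, ch] > panel_thr[[ch]]) / sum(sel)
  }
}

cat("recovered population fractions (first well):\n")
print(round(abund, 3))
mat <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(data.frame(population = rownames(mat), round(mat, 2),
                     check.names = FALSE),
          "results/tumor_population_profiles.csv", row.names = FALSE)

# candidate fibroblast markers: pure fibroblast profile vs the
# CD45-/CD31-negative tumor fraction (cancer + fibroblast contamination)
cand <- rank_candidates(mat["fibroblast", , drop = FALSE],
                        mat["cancer", , drop = FALSE])
cat("\ncandidate fibroblast markers (reference >= 50%, target <= 20%):\n")
print(cand, row.names = FALSE)
write.csv(cand, "results/caf_candidates.csv", row.names = FALSE)
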