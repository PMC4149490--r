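---
title: "Methods: simulation, gating and screening statistics in htfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, gating and screening statistics in htfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htfc)
```

## The measurement model

High-throughput flow cytometry (HT-FC) screens hundreds of cell-surface
antibodies by staining one antibody per well of a 96-well plate and
acquiring a fixed number of events per well. The screen's central product
is a *percent-positive matrix*: for each sample (or cell subpopulation) and
each antigen, the percentage of viable singlet cells whose fluorescence in
the antibody's detector channel exceeds a fluorescence-minus-one (FMO)
threshold. Everything downstream — treatment-lability calls, replicate
reproducibility, clustering, candidate-marker discovery — operates on this
matrix.

`htfc` implements the computational side of that screen end to end, driven
by a synthetic event generator, so every stage can be verified against
planted ground truth without instrument data.

## The synthetic event generator

Each well draws `events_per_well` events from a mixture of populations
(`population_spec`). The per-event signal model, all on linear scale:

* **Fluorescence.** Every channel carries log-normal autofluorescence,
  `10^N(mu_af, sd_af)` (default `mu_af = 2.0`, `sd_af = 0.25` log10
  units). An event that is positive for the stained antigen (with
  probability `positive_fraction`) *adds* a log-normal stain component
  (default `10^N(4.0, 0.3)`). The sum of two log-normals reproduces the
  bimodal negative/positive structure FMO gating assumes, and values are
  always positive. A handful of demo antigens (CAIX, CD104, CD140b, CD26,
  CD146, CD10) use dim stain modes (`mu ~ 3.0-3.3`) that overlap the FMO
  threshold — these are what make replicate runs disagree realistically.
* **Spillover.** True signals are mixed by right-multiplication with a
  spillover matrix `S` (unit diagonal, small nonnegative off-diagonals);
  the gating pipeline compensates by multiplying with `solve(S)`, mirroring
  instrument-side compensation.
* **Dead cells.** A `dead_fraction` of events (default 5%) draws its
  viability-dye channel from a bright mode (`10^N(3.5, 0.2)`), roughly
  100-fold above the live mode's median — the dye-bright dead population a
  DAPI gate removes.
* **Doublets.** A `doublet_fraction` (default 5%) has FSC-A and FSC-W
  doubled with FSC-H unchanged — the standard pulse-geometry approximation
  that area and width scale with aggregate size while height does not.
* **Replicate jitter.** Each well draws one `N(0, intensity_jitter_sd)`
  shift per fluorescence channel, applied to both autofluorescence and
  stain log10 means. This is the run-to-run staining/instrument drift that
  reproducibility experiments measure. The default (0.08 log10 units) was
  chosen so that triplicate runs of the demo sample land in the
  0.81–0.97 Spearman range regarded as acceptable platform
  reproducibility; it is a config field, not a constant.

Per-well seeds derive from the master seed by a stable base-31 string hash
of `"plate/well"` modulo 2^31−1 (`well_seed()`), so plates are reproducible
well-by-well and can be generated in any order.

What the generator does **not** emulate: acquisition-time drift within a
run, well-to-well carryover, non-linear detector response, and
spectrally realistic spillover coefficients. Passing tests therefore
demonstrate the correctness of the analysis logic under the stated model,
not robustness to every instrument artifact.

## Gating

The screen's manual gates are replaced by deterministic automatic
equivalents, applied in a fixed order (viability → singlets → positivity);
the percent-positive denominator is viable singlets.

* **FMO thresholds** are empirical percentiles (default 99.9th) of the
  matched control well's signal, using the linear-interpolation quantile:
  with sorted values `x_(1..n)` and `h = (n-1)p + 1`, the threshold is
  `x_(floor(h)) + (h - floor(h)) * (x_(floor(h)+1) - x_(floor(h)))`. The
  99.9th percentile implies a ~0.1% false-positive floor in unstained
  wells, a contract the test suite checks. Positivity is *strictly greater
  than* the threshold; with continuous simulated data, ties have measure
  zero (for integer-quantized data this choice makes the gate
  conservative).
* **Viability.** The threshold is the configured percentile of a *no-dye*
  control (plate-map row with `fluorochrome = NONE`), whose viability
  channel carries live-mode autofluorescence only. A dye-stained control
  contains the dead-cell mode itself, so a high percentile of it would sit
  inside the dead population; the unstained control anchors the cut at the
  top of the live mode instead. This is the package's reproducible
  equivalent of drawing a manual gate between the live and dye-bright
  modes.
* **Singlets.** Events with `FSC-W <= 1.5 x median(FSC-W)` are kept. With
  a tight singlet width distribution and area-doubled doublets, the 1.5x
  median cut sits far (>4 sd) from both modes.
* **QC.** Wells with fewer than `min_events` viable singlet events are
  flagged and reported as *missing*, never zero — missingness feeds the
  imputation step. The default is 5000 analysis events, half the
  10,000-events-per-well acquisition floor, leaving headroom for expected
  dead-cell and doublet losses; a threshold at the full acquisition floor
  would flag every well, since gates only remove events.
* **Lineage deconvolution.** Co-stain rules are evaluated in order with
  first-match-wins semantics (immune: CD45+; endothelial: CD45− CD31+
  CD34+; fibroblast: CD45− TE7+; cancer: quad-negative), so masks are
  disjoint and, with "unassigned", cover all events. Ordered rules make
  the CD45+CD31+ event an immune cell by construction rather than an
  ambiguity.

## Screening statistics

* **Detection limit.** Antigens below 1 percent positive are treated as
  undetected; the filter is inclusive at exactly 1%.
* **Lability classifier.** An antigen is *labile* ("both") when
  `|treated - untreated| >= 5` percentage points **and** the bidirectional
  fold change `max(u', t') / min(u', t') >= 2`, where `u', t'` are the two
  values clamped below at the detection limit. Clamping keeps folds finite
  at zero and stops sub-detection noise from manufacturing huge ratios;
  the max/min form treats gains and losses symmetrically (treatments can
  increase detectability, not only destroy epitopes). Single-criterion
  calls are reported as `abs_only` / `fold_only`. Integer "influenced"
  percentages are truncated toward zero.
* **Reproducibility.** Spearman's rank correlation over antigens observed
  in both runs, average ranks for ties, missing pairs dropped; two-sided
  p-value by exhaustive permutation for n ≤ 8 shared antigens and by the
  t approximation otherwise, with the method reported alongside the
  estimate. The correlation is computed on percent-positive values, the
  same scale the replicate scatter plots use.
* **Candidate ranking.** Candidate markers must average ≥ 50% on the pure
  reference population and ≤ 20% on the comparison fraction, ranked by the
  mean difference with alphabetical tie-breaks. The 50/20 defaults are the
  package's own operationalization of "highly expressed on the reference,
  low on the target"; both are config fields and echoed in the output.

## Profile analytics

* **k-NN imputation** (default k = 10): a missing cell takes the mean of
  its column over the k nearest rows. Row distance is the root mean square
  difference over mutually observed columns — equivalently, squared
  Euclidean distance rescaled by the fraction of columns shared — so rows
  with different missingness patterns compete on the same scale. Only rows
  observing the target column are eligible neighbours; k truncates to the
  available rows. Imputed values can therefore never leave the observed
  range of their column.
* **Clustering** uses the Pearson correlation distance `1 - r` between
  sample rows with complete linkage. Correlation distance ranges over
  [0, 2] and is not a metric (no triangle inequality) — acceptable for
  agglomeration, which only compares dissimilarities. Clustering operates
  on raw percent-positive rows; mean centering is applied only on the PCA
  path. The agglomerator is the naive O(n^3) algorithm with an explicit
  tie-break (merge the pair whose smallest member leaf indices are
  lexicographically smallest), so trees are identical across platforms;
  profile matrices in this domain are small enough that cubic cost is
  irrelevant.
* **Tree cutting** removes the k−1 highest merges and numbers clusters by
  first leaf appearance. **PCA** is the spectral decomposition of the
  covariance of column-centered data (via `prcomp`), with each component's
  sign fixed so its largest-magnitude loading is positive.
* **Newick export** writes the ultrametric convention: a leaf merged at
  height h sits at depth h/2, so cophenetic distances in the exported tree
  equal merge heights.

## Numerical and format choices

* FCS 3.0 files are written as list-mode float32, little-endian, channel
  names in `$PnN`; values round-trip within float32 relative precision
  (~1e-7). Plate maps are plain CSV and round-trip byte-identically.
* All simulation is seeded; identical seeds give identical event tables,
  and pipeline outputs carry the master seed plus a config hash.
* Degenerate inputs fail loudly and name the offender: constant rows in
  correlation, fully missing columns in imputation, singular spillover
  matrices, absent co-stain channels, missing FMO controls.

## Problem sizes used in verification

The packaged study conditions are a 24-antibody single-plate panel
(8 antibodies each on PE, FITC, APC; one FMO control per fluorochrome plus
one unstained control), 10,000 events per well for recovery and
reproducibility properties, 20 seeds for the lability
sensitivity/specificity sweep, and 10 seeds of 9 samples (3 lineages × 3
replicates, 4,000–5,000 events/well) for the clustering property. These
sizes give binomial standard errors well below the effect sizes planted
and keep the whole verification suite fast on a laptop.

## Known limitations

* The generator's noise parameters are declared, not fitted to any
  instrument; absolute percent-positive values are only meaningful
  relative to the planted truth.
* Dim antigens are measured with a downward bias (part of their stain
  mode falls below the FMO cut) — exactly as in the real assay, where
  "percent positive" undercounts weakly expressing cells.
* No logicle/biexponential display transforms, mixture-model autogating,
  or bootstrap support on dendrograms; the analysis mirrors fixed-gate,
  fixed-threshold screening practice.
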