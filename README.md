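# htfc — high-throughput flow-cytometry surface-antigen screening

`htfc` is an R package plus analysis workflow for plate-based
high-throughput flow cytometry (HT-FC): screening hundreds of
fluorochrome-conjugated antibodies against cell-surface antigens, one
antibody per well of a 96-well plate. It is aimed at cytometry and
screening bioinformaticians who need the computational half of such a
screen — gating, percent-positive matrices, treatment-effect calls,
reproducibility statistics and profile clustering — as tested, scriptable
code rather than manual gating software, and at anyone who wants to
validate that logic against planted ground truth.

## What it computes

For each well the pipeline applies, in order: spillover compensation
(`observed · S⁻¹`), a viability gate (dye signal ≤ the 99.9th percentile
of an unstained control), a singlet gate (FSC-W ≤ 1.5 × median FSC-W),
and a fluorescence-minus-one (FMO) positivity gate. The screen's central
statistic per well is

```
percent positive = 100 · |{viable singlets with x_ch > t_FMO}| / |viable singlets|
```

where `t_FMO` is the 99.9th empirical percentile of the matched control
well. Rows of percent-positive values feed:

* a **treatment-lability classifier** — an antigen is *labile* when
  `|Δ| ≥ 5` percentage points **and** fold change ≥ 2, with
  `fold = max(u',t')/min(u',t')` and both values clamped at the 1%
  detection limit;
* **replicate reproducibility** — Spearman's ρ between runs of the same
  sample (exact permutation p for n ≤ 8 shared antigens);
* **lineage deconvolution** — ordered co-stain rules (CD45+ immune;
  CD45− CD31+ CD34+ endothelial; CD45− TE7+ fibroblast; quad-negative
  cancer) splitting each tumor well into subpopulation profiles;
* **candidate-marker ranking** — antigens high on a pure reference
  population, low on a comparison fraction;
* **profile analytics** — k-NN imputation (k = 10), Pearson-distance
  (`1 − r`) complete-linkage clustering, tree cuts, PCA on mean-centered
  data, Newick export.

A synthetic event generator (`simulate_well`, `simulate_screen_plate`)
plants populations, positive fractions, spillover, dead cells, doublets
and treatment perturbations, and writes FCS 3.0 files, so every stage is
verifiable against known truth. See `vignettes/htfc-methods.Rmd` for the
full model.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on the
packaged 24-antibody demo panel (`Rscript analysis/01_simulate_screen.R 1`
… `06_profile_clustering.R 1`, from the repository root, seed as the
argument). Step 3, after simulating untreated and enzyme-digested runs of
the demo cell pool and gating both:

```
category counts:
undetected unaffected   abs_only  fold_only       both    missing
         0         18          1          0          5          0
detected antigens:   24
influenced antigens: 6 (25% of detected)
labile (both criteria):  CD105, CD146, CD24, CD49f, EpCAM
planted labile set:      CD105, CD146, CD24, CD49f, EpCAM
planted lability recovered exactly
```

All five antigens planted to change by ≥ 15 points and ≥ 3-fold are
called labile, and only those (one borderline antigen moves > 5 points
but < 2-fold, hence `abs_only`). Step 4 reports replicate stability:

```
run 1 vs run 2: rho = 0.981, p = 4e-17 (t approximation, n = 24)
run 2 vs run 3: rho = 0.994, p = 1.4e-22 (t approximation, n = 24)
minimum pairwise Spearman: 0.981
```

and step 5 deconvolves the synthetic tumor (planted abundances 0.40 /
0.10 / 0.10 / 0.40 recovered as 0.390 / 0.099 / 0.095 / 0.413) and ranks
fibroblast-marker candidates, with CD90 on top (88% on pure fibroblasts
vs 2% on the cancer fraction).

Equivalent calls in R: `pipeline_config()` + `run_simulate()` +
`run_screen()`.

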