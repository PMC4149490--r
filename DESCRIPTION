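Package: htfc
Title: High-Throughput Flow-Cytometry Surface-Antigen Screening
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plate-based high-throughput flow-cytometry (HT-FC) screening of
    cell-surface antigens: a synthetic cytometry event generator with planted
    populations, spillover, dead cells and doublets; reproducible automatic
    gating (viability, singlet and fluorescence-minus-one positivity gates,
    lineage co-stain deconvolution); percent-positive matrix assembly;
    treatment-lability classification with dual absolute/fold-change criteria;
    replicate reproducibility statistics; and profile analytics (k-nearest
    neighbour imputation, Pearson-distance complete-linkage clustering, PCA,
    Newick dendrogram export). Includes an FCS 3.0 writer and reader.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
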