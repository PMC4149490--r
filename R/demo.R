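# Demonstration study conditions: a three-lineage synthetic cell pool
# screened on the packaged 24-antibody panel, and a four-population
# synthetic tumor for co-stain deconvolution. Positive fractions are the
# planted truth that gating should recover; a handful of antigens are
# deliberately dim (stain mode near the FMO threshold) so replicate runs
# disagree realistically.

.DIM_STAINS <- list(
  "CAIX" = c(3.0, 0.40), "CD104" = c(3.1, 0.40), "CD140b" = c(3.0, 0.40),
  "CD26" = c(3.1, 0.35), "CD146" = c(3.2, 0.40), "CD10" = c(3.3, 0.35)
)

.pf <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

.EPITHELIAL_PF <- .pf(
  EpCAM = 0.92, CD24 = 0.85, CD44 = 0.70, CD49f = 0.60, CD104 = 0.50,
  CAIX = 0.35, CD10 = 0.15, CD146 = 0.05, CD29 = 0.90, `HLA-ABC` = 0.85,
  CD54 = 0.25, CD26 = 0.40, CD90 = 0.02, CD73 = 0.30, CD105 = 0.10,
  CD140b = 0.05, CD45 = 0.005, CD3 = 0.002, CD19 = 0.002, CD14 = 0.002,
  CD11b = 0.005, CD56 = 0.02, CD4 = 0.002, CD8 = 0.002)

.IMMUNE_PF <- .pf(
  CD45 = 0.98, CD3 = 0.65, CD4 = 0.45, CD8 = 0.25, CD19 = 0.12,
  CD14 = 0.18, CD11b = 0.30, CD56 = 0.12, `HLA-ABC` = 0.95, CD44 = 0.85,
  CD54 = 0.45, CD29 = 0.60, CD26 = 0.30, CD24 = 0.20, CD73 = 0.05,
  CD105 = 0.02, CD90 = 0.03, CD10 = 0.08, EpCAM = 0.002,
  CD49f = 0.05, CD104 = 0.01, CAIX = 0.01, CD146 = 0.01, CD140b = 0.01)

.FIBROBLAST_PF <- .pf(
  CD90 = 0.90, CD73 = 0.85, CD105 = 0.70, CD140b = 0.55, CD146 = 0.20,
  CD44 = 0.88, CD29 = 0.95, CD54 = 0.30, `HLA-ABC` = 0.80, CD10 = 0.45,
  CD26 = 0.50, CD49f = 0.25, EpCAM = 0.01, CD24 = 0.05, CAIX = 0.05,
  CD104 = 0.03, CD45 = 0.003, CD3 = 0.002, CD4 = 0.002, CD8 = 0.002,
  CD19 = 0.002, CD14 = 0.002, CD11b = 0.005, CD56 = 0.01)

#' Demonstration mixed-lineage cell pool
#'
#' Three synthetic populations (epithelial, immune, fibroblast) with
#' distinct planted positive fractions over the packaged 24-antigen demo
#' panel — a stand-in for a pooled multi-lineage sample that maximizes
#' epitope coverage. Passing different abundances gives pure or re-mixed
#' samples of the same lineages.
#'
#' @param abundances Named fractions for `epithelial`, `immune`,
#'   `fibroblast`; must sum to 1.
#' @return List of three [population_spec]s.
#' @export
demo_populations <- function(abundances = c(epithelial = 0.5, immune = 0.3,
                                            fibroblast = 0.2)) {
  stopifnot(all(c("epithelial", "immune", "fibroblast") %in% names(abundances)))
  list(
    population_spec("epithelial", abundances[["epithelial"]], .EPITHELIAL_PF,
                    stain_intensity = .DIM_STAINS),
    population_spec("immune", abundances[["immune"]], .IMMUNE_PF,
                    stain_intensity = .DIM_STAINS),
    population_spec("fibroblast", abundances[["fibroblast"]], .FIBROBLAST_PF,
                    stain_intensity = .DIM_STAINS))
}

#' Lineage co-stain antibody set for tumor deconvolution
#'
#' CD45 (hematopoietic), CD31 and CD34 (vascular endothelial) and TE7
#' (fibroblast) on tandem-dye channels separate from the screen's PE, FITC
#' and APC detectors.
#'
#' @return List of four [antibody] objects.
#' @export
demo_costains <- function() {
  list(antibody("CD45cs", "APC-Cy7"),
       antibody("CD31", "PE-Cy7"),
       antibody("CD34", "PerCP-Cy5.5"),
       antibody("TE7", "eFluor450"))
}

#' Demonstration synthetic tumor sample
#'
#' Four populations mirroring a dissociated primary tumor: CD45+ immune
#' cells, CD45- CD31+ CD34+ vascular endothelial cells, CD45- TE7+
#' fibroblasts and quad-negative cancer cells, at the stated abundances.
#' Panel-antigen profiles make CD90 a fibroblast-enriched candidate marker.
#'
#' @param abundances Named fractions for `immune`, `endothelial`,
#'   `fibroblast`, `cancer`; must sum to 1.
#' @return List of four [population_spec]s.
#' @export
demo_tumor_populations <- function(abundances = c(immune = 0.4,
                                                  endothelial = 0.1,
                                                  fibroblast = 0.1,
                                                  cancer = 0.4)) {
  co <- function(CD45cs = 0.001, CD31 = 0.001, CD34 = 0.001, TE7 = 0.001) {
    c(CD45cs = CD45cs, CD31 = CD31, CD34 = CD34, TE7 = TE7)
  }
  list(
    population_spec("immune", abundances[["immune"]],
                    c(.IMMUNE_PF, co(CD45cs = 0.995)),
                    stain_intensity = .DIM_STAINS),
    population_spec("endothelial", abundances[["endothelial"]],
                    .pf(c(co(CD31 = 0.995, CD34 = 0.995),
                          CD146 = 0.90, CD105 = 0.80,
                          CD44 = 0.60, CD29 = 0.85, `HLA-ABC` = 0.80,
                          CD54 = 0.70, EpCAM = 0.01, CD90 = 0.05,
                          CD73 = 0.60, CD45 = 0.005)),
                    stain_intensity = .DIM_STAINS),
    population_spec("fibroblast", abundances[["fibroblast"]],
                    c(.FIBROBLAST_PF, co(TE7 = 0.995)),
                    stain_intensity = .DIM_STAINS),
    population_spec("cancer", abundances[["cancer"]],
                    c(.EPITHELIAL_PF, co()),
                    stain_intensity = .DIM_STAINS))
}

#' Technical-noise model covering the co-stain detectors
#'
#' Same defaults as [technical_noise()] but with the spillover model
#' extended over all seven fluorescence channels, as needed when co-stains
#' are simulated.
#'
#' @param ... Passed to [technical_noise()].
#' @return A [technical_noise] object.
#' @export
demo_tumor_noise <- function(...) {
  technical_noise(spillover = default_spillover(unname(.FLUOR_CHANNELS)), ...)
}

#' Demonstration enzymatic-digestion treatment
#'
#' A planted treatment perturbing a subset of panel antigens the way
#' enzymatic digestion does in the screen: strong losses of
#' protease-sensitive epitopes, one gained antigen, and sub-threshold
#' wobbles that must not be called labile.
#'
#' @return A [treatment_effect] labelled `"digestion"`. The attribute
#'   `"labile"` lists the antigens planted to satisfy both lability
#'   criteria (>= 5 point and >= 2-fold change) at the demo abundances.
#' @export
demo_digestion_treatment <- function() {
  eff <- treatment_effect("digestion", list(
    EpCAM  = list(factor = 0.15),  # strong epitope loss
    CD24   = list(factor = 0.20),
    CD49f  = list(factor = 0.25),
    CD105  = list(factor = 0.15),
    CD146  = list(set = 0.60),     # gained detection
    CD44   = list(factor = 0.97),  # sub-threshold wobbles
    CD29   = list(factor = 1.02),
    CD54   = list(factor = 1.10)))
  attr(eff, "labile") <- c("EpCAM", "CD24", "CD49f", "CD105", "CD146")
  eff
}
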