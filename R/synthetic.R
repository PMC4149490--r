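# Scatter and viability model constants (log10 scale). FSC-W is tight so a
# median-relative width cut separates singlets from area-doubled doublets.
.SCATTER <- list(
  fsc_a = c(2.30, 0.06), fsc_w = c(2.00, 0.03), ssc_a = c(1.80, 0.10)
)
.VIABILITY_CHANNEL <- "DAPI-A"
.DAPI_LIVE <- c(1.5, 0.25)   # live-cell autofluorescence in the dye channel
.DAPI_DEAD <- c(3.5, 0.20)   # dye-bright dead mode, ~100x the live median
.DEFAULT_AUTOFLUOR <- c(2.0, 0.25)
.DEFAULT_STAIN     <- c(4.0, 0.30)

#' Specify a cell population for simulation
#'
#' A population is a latent cell type contributing a fraction of the events
#' in every well. Stained fluorescence is simulated in linear scale as
#' autofluorescence plus, for antigen-positive events, a log-normal stain
#' signal; both components are parameterized on log10 scale.
#'
#' @param name Population name.
#' @param abundance Fraction of events drawn from this population; the
#'   abundances of all populations passed to a simulation must sum to 1.
#' @param positive_fraction Named numeric vector, antigen -> fraction of
#'   this population's cells expressing the antigen, in \[0, 1\].
#' @param stain_intensity Named list, antigen -> `c(log10_mean, log10_sd)`
#'   of the stained-signal distribution. Antigens not listed use the bright
#'   default `c(4.0, 0.30)`.
#' @param autofluorescence Named list, channel -> `c(log10_mean, log10_sd)`
#'   of unstained background. Channels not listed use `c(2.0, 0.25)`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, abundance, positive_fraction,
                            stain_intensity = list(),
                            autofluorescence = list()) {
  stopifnot(is.numeric(abundance), abundance >= 0, abundance <= 1,
            all(positive_fraction >= 0), all(positive_fraction <= 1),
            !is.null(names(positive_fraction)))
  for (si in stain_intensity) stopifnot(length(si) == 2L, si[2] > 0)
  for (af in autofluorescence) stopifnot(length(af) == 2L, af[2] > 0)
  structure(list(name = name, abundance = abundance,
                 positive_fraction = positive_fraction,
                 stain_intensity = stain_intensity,
                 autofluorescence = autofluorescence),
            class = "population_spec")
}

.check_populations <- function(populations) {
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, TRUE, "population_spec")))
  ab <- vapply(populations, `[[`, 0, "abundance")
  if (abs(sum(ab) - 1) > 1e-9) {
    stop("population abundances must sum to 1 (got ", sum(ab), ")")
  }
  invisible(populations)
}

#' Construct a spillover matrix
#'
#' Entry (i, j) is the fraction of channel i's true signal that appears in
#' detector channel j. The diagonal is 1; the matrix must be invertible so
#' that compensation (right-multiplication by its inverse) is defined.
#'
#' @param channels Ordered fluorescence channel names.
#' @param values Square numeric matrix, or `NULL` for the identity.
#' @return An object of class `spillover_matrix`.
#' @export
spillover_matrix <- function(channels, values = NULL) {
  n <- length(channels)
  if (is.null(values)) values <- diag(n)
  values <- as.matrix(values)
  stopifnot(nrow(values) == n, ncol(values) == n,
            all(diag(values) == 1),
            all(values >= 0), all(values[row(values) != col(values)] < 1))
  if (abs(det(values)) < 1e-12) stop("spillover matrix is singular")
  dimnames(values) <- list(channels, channels)
  structure(list(channels = channels, values = values),
            class = "spillover_matrix")
}

#' Default spillover for the demonstration instrument configuration
#'
#' Small one-way leakages among spectrally adjacent dyes; diagonally
#' dominant, hence invertible.
#'
#' @param channels Fluorescence channels to include.
#' @return A [spillover_matrix].
#' @export
default_spillover <- function(channels = c("PE-A", "FITC-A", "APC-A")) {
  all_ch <- names(.FLUOR_CHANNELS)
  S <- diag(length(channels))
  dimnames(S) <- list(channels, channels)
  leak <- list(c("FITC-A", "PE-A", 0.06), c("PE-A", "FITC-A", 0.02),
               c("PE-A", "PE-Cy7-A", 0.03), c("PerCP-Cy5.5-A", "APC-A", 0.02),
               c("APC-A", "APC-Cy7-A", 0.04))
  for (l in leak) {
    if (all(l[1:2] %in% channels)) S[l[1], l[2]] <- as.numeric(l[3])
  }
  spillover_matrix(channels, S)
}

#' Technical-noise model for simulated wells
#'
#' @param events_per_well Events acquired per well (default 10000, the
#'   screen's per-well acquisition floor).
#' @param dead_fraction Fraction of dye-bright dead events.
#' @param doublet_fraction Fraction of doublet events (FSC area and width
#'   doubled, height unchanged).
#' @param spillover A [spillover_matrix] mixing the fluorescence channels.
#' @param intensity_jitter_sd Per-well log10 shift applied to stain and
#'   autofluorescence means; models run-to-run staining variability and is
#'   the main driver of replicate-to-replicate disagreement.
#' @return An object of class `technical_noise`.
#' @export
technical_noise <- function(events_per_well = 10000L,
                            dead_fraction = 0.05,
                            doublet_fraction = 0.05,
                            spillover = default_spillover(),
                            intensity_jitter_sd = 0.08) {
  stopifnot(events_per_well >= 1L,
            dead_fraction >= 0, dead_fraction <= 1,
            doublet_fraction >= 0, doublet_fraction <= 1,
            inherits(spillover, "spillover_matrix"),
            intensity_jitter_sd >= 0)
  structure(list(events_per_well = as.integer(events_per_well),
                 dead_fraction = dead_fraction,
                 doublet_fraction = doublet_fraction,
                 spillover = spillover,
                 intensity_jitter_sd = intensity_jitter_sd),
            class = "technical_noise")
}

#' Specify a treatment perturbation of antigen detectability
#'
#' @param label Treatment label, e.g. `"trypsin"`.
#' @param effects Named list, antigen -> either `list(factor = f)`
#'   (multiply the planted positive fraction) or `list(set = p)` (replace
#'   it). Resulting fractions are clipped to \[0, 1\].
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(label, effects) {
  stopifnot(is.character(label), length(effects) >= 1L,
            !is.null(names(effects)))
  for (e in effects) {
    stopifnot(is.list(e), length(e) == 1L,
              names(e) %in% c("factor", "set"))
  }
  structure(list(label = label, effects = effects),
            class = "treatment_effect")
}

#' Apply a treatment to population specs
#'
#' @param populations List of [population_spec]s.
#' @param treatment A [treatment_effect] or `NULL` (no-op).
#' @return Modified list of population specs.
#' @export
apply_treatment <- function(populations, treatment) {
  if (is.null(treatment)) return(populations)
  stopifnot(inherits(treatment, "treatment_effect"))
  lapply(populations, function(p) {
    for (ag in names(treatment$effects)) {
      if (!ag %in% names(p$positive_fraction)) next
      e <- treatment$effects[[ag]]
      v <- if (!is.null(e$set)) e$set else p$positive_fraction[[ag]] * e$factor
      p$positive_fraction[[ag]] <- min(1, max(0, v))
    }
    p
  })
}

.get2 <- function(lst, key, default) {
  if (!is.null(lst[[key]])) lst[[key]] else default
}

#' Deterministic per-well seed
#'
#' Stable polynomial string hash (base 31 over the UTF-8 bytes of
#' `"plate/well"`, modulo the Mersenne prime 2^31 - 1) folded with the
#' master seed, so plate-level simulation is reproducible well by well and
#' parallelizable.
#'
#' @param master_seed Integer master seed.
#' @param plate,well Plate and well identifiers.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
well_seed <- function(master_seed, plate, well) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(paste0(plate, "/", well))) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Simulate one well of cytometry events
#'
#' Events are drawn from the population mixture; each event carries forward
#' and side scatter, a viability-dye channel, and the fluorescence channels
#' of the spillover model. The stained channel of an antigen-positive event
#' is autofluorescence plus a log-normal stain signal; spillover mixes the
#' fluorescence channels linearly; dead events are dye-bright; doublets have
#' FSC-A and FSC-W doubled with FSC-H unchanged. With `antibody = NULL` the
#' well is a buffer-only fluorescence-minus-one control.
#'
#' @param populations List of [population_spec]s (abundances sum to 1).
#' @param antibody An [antibody] or `NULL` for a control well.
#' @param noise A [technical_noise] model.
#' @param seed Integer seed; identical seeds give identical wells.
#' @param costains List of [antibody] objects stained in every well (lineage
#'   co-stains), or `NULL`.
#' @param viability_stain If `FALSE`, the viability dye is omitted and dead
#'   events show live-level background (the unstained control used to set
#'   the viability threshold).
#' @param metadata Named list merged into the event-table metadata.
#' @return An `event_table`: numeric event x channel matrix with a
#'   `metadata` attribute.
#' @export
simulate_well <- function(populations, antibody = NULL, noise = technical_noise(),
                          seed, costains = NULL, viability_stain = TRUE,
                          metadata = list()) {
  .check_populations(populations)
  stopifnot(inherits(noise, "technical_noise"))
  if (missing(seed)) stop("seed is required")
  stains <- c(if (!is.null(antibody)) list(antibody), costains)
  for (ab in stains) {
    stopifnot(inherits(ab, "antibody"))
    if (!ab$channel_name %in% noise$spillover$channels) {
      stop("antibody channel not in spillover model: ", ab$channel_name)
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- noise$events_per_well
  fluor_ch <- noise$spillover$channels
  jit_sd <- noise$intensity_jitter_sd
  # one per-well jitter shift per fluorescence channel (staining/instrument
  # drift), shared by autofluorescence and stain in that channel
  jitter <- stats::rnorm(length(fluor_ch), 0, jit_sd)
  names(jitter) <- fluor_ch

  ab_frac <- vapply(populations, `[[`, 0, "abundance")
  pop_idx <- sample.int(length(populations), n, replace = TRUE, prob = ab_frac)

  fsc_a <- 10^stats::rnorm(n, .SCATTER$fsc_a[1], .SCATTER$fsc_a[2])
  fsc_w <- 10^stats::rnorm(n, .SCATTER$fsc_w[1], .SCATTER$fsc_w[2])
  fsc_h <- fsc_a / fsc_w * 100    # pulse height ~ area/width
  ssc_a <- 10^stats::rnorm(n, .SCATTER$ssc_a[1], .SCATTER$ssc_a[2])
  doublet <- stats::runif(n) < noise$doublet_fraction
  fsc_a[doublet] <- fsc_a[doublet] * 2
  fsc_w[doublet] <- fsc_w[doublet] * 2

  dead <- stats::runif(n) < noise$dead_fraction
  via <- 10^stats::rnorm(n, .DAPI_LIVE[1], .DAPI_LIVE[2])
  if (viability_stain && any(dead)) {
    via[dead] <- 10^stats::rnorm(sum(dead), .DAPI_DEAD[1], .DAPI_DEAD[2])
  }

  # per-channel autofluorescence (population-specific where specified)
  fl <- matrix(0, n, length(fluor_ch), dimnames = list(NULL, fluor_ch))
  for (p in seq_along(populations)) {
    rows <- pop_idx == p
    if (!any(rows)) next
    for (ch in fluor_ch) {
      af <- .get2(populations[[p]]$autofluorescence, ch, .DEFAULT_AUTOFLUOR)
      fl[rows, ch] <- 10^stats::rnorm(sum(rows), af[1] + jitter[ch], af[2])
    }
  }
  # stain signal added for antigen-positive events
  for (ab in stains) {
    ch <- ab$channel_name
    for (p in seq_along(populations)) {
      rows <- which(pop_idx == p)
      if (!length(rows)) next
      pf <- .get2(as.list(populations[[p]]$positive_fraction),
                  ab$antigen_name, 0)
      pos <- rows[stats::runif(length(rows)) < pf]
      if (!length(pos)) next
      si <- .get2(populations[[p]]$stain_intensity, ab$antigen_name,
                  .DEFAULT_STAIN)
      fl[pos, ch] <- fl[pos, ch] +
        10^stats::rnorm(length(pos), si[1] + jitter[ch], si[2])
    }
  }
  fl <- fl %*% noise$spillover$values

  m <- cbind(`FSC-A` = fsc_a, `FSC-H` = fsc_h, `FSC-W` = fsc_w,
             `SSC-A` = ssc_a, `DAPI-A` = via, fl)
  meta <- utils::modifyList(
    list(seed = seed,
         antigen = if (is.null(antibody)) NA_character_ else antibody$antigen_name,
         channel = if (is.null(antibody)) NA_character_ else antibody$channel_name,
         truth = list(dead = dead, doublet = doublet,
                      population = vapply(populations, `[[`, "", "name")[pop_idx])),
    metadata)
  event_table(m, metadata = meta)
}

#' Construct an event table
#'
#' @param values Numeric event x channel matrix with unique column names.
#' @param metadata Named list (well, plate, sample id, seed, planted truth).
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, metadata = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1L, !is.null(colnames(values)),
            !anyDuplicated(colnames(values)), all(is.finite(values)))
  attr(values, "metadata") <- metadata
  class(values) <- c("event_table", class(values))
  values
}

#' @export
print.event_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<event_table> %d events x %d channels (%s)\n",
              nrow(x), ncol(x),
              paste(colnames(x), collapse = ", ")))
  if (!is.null(md$antigen) && !is.na(md$antigen)) {
    cat("  antibody:", md$antigen, "\n")
  }
  invisible(x)
}

#' Simulate a full screening plate (or plate set)
#'
#' One event table per plate-map well. Buffer-only CONTROL wells are
#' simulated without antibody; the `fluorochrome = "NONE"` control is also
#' simulated without the viability dye (it anchors the viability gate). A
#' treatment, if given, perturbs the planted positive fractions before
#' simulation. Per-well seeds derive from the master seed via [well_seed()].
#'
#' @param map A [plate_map].
#' @param populations List of [population_spec]s.
#' @param noise A [technical_noise] model.
#' @param treatment A [treatment_effect] or `NULL`.
#' @param seed Master integer seed.
#' @param costains List of co-stain [antibody] objects applied to antibody
#'   wells, or `NULL`.
#' @param sample_id Sample identifier recorded in well metadata.
#' @return Named list of `event_table`s keyed `"plate/well"`.
#' @export
simulate_screen_plate <- function(map, populations, noise = technical_noise(),
                                  treatment = NULL, seed, costains = NULL,
                                  sample_id = "S1") {
  stopifnot(inherits(map, "plate_map"))
  if (missing(seed)) stop("seed is required")
  populations <- apply_treatment(populations, treatment)
  wells <- map$wells
  out <- vector("list", nrow(wells))
  names(out) <- paste(wells$plate, wells$well, sep = "/")
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    is_ctrl <- w$antigen == "CONTROL"
    ab <- if (is_ctrl) NULL else antibody(w$antigen, w$fluorochrome, w$clone)
    out[[i]] <- simulate_well(
      populations, antibody = ab, noise = noise,
      seed = well_seed(seed, w$plate, w$well),
      costains = if (is_ctrl) NULL else costains,
      viability_stain = !(is_ctrl && w$fluorochrome == "NONE"),
      metadata = list(plate = w$plate, well = w$well, sample_id = sample_id,
                      control = is_ctrl, fluorochrome = w$fluorochrome,
                      treatment = if (is.null(treatment)) NA_character_
                                  else treatment$label))
  }
  out
}

# save/restore global RNG state so simulation calls do not clobber the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
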