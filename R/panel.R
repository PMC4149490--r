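# Fluorochrome -> detector channel lookup. Panel wells use the three screen
# fluorochromes; co-stains use tandem dyes on separate detectors. "NONE"
# marks an unstained control (no antibody, no viability dye): its well
# provides the live-mode reference for the viability gate.
.FLUOR_CHANNELS <- c(
  "PE"          = "PE-A",
  "FITC"        = "FITC-A",
  "APC"         = "APC-A",
  "APC-Cy7"     = "APC-Cy7-A",
  "PE-Cy7"      = "PE-Cy7-A",
  "PerCP-Cy5.5" = "PerCP-Cy5.5-A",
  "eFluor450"   = "eFluor450-A"
)

#' Map a fluorochrome to its detector channel
#'
#' @param fluorochrome Fluorochrome name, e.g. `"PE"` or `"APC-Cy7"`.
#' @return Detector channel name, e.g. `"PE-A"`.
#' @export
fluorochrome_channel <- function(fluorochrome) {
  ch <- .FLUOR_CHANNELS[fluorochrome]
  if (any(is.na(ch))) {
    stop("unknown fluorochrome: ",
         paste(fluorochrome[is.na(ch)], collapse = ", "))
  }
  unname(ch)
}

#' Construct an antibody record
#'
#' An antibody is identified by the antigen it targets and the fluorochrome
#' it is conjugated to; the fluorochrome determines the detector channel the
#' antibody reports on.
#'
#' @param antigen_name Antigen name, e.g. `"CD90"`. Must be non-empty.
#' @param fluorochrome One of `r paste(names(.FLUOR_CHANNELS), collapse=", ")`.
#' @param clone Optional clone identifier.
#' @return An object of class `antibody`.
#' @export
antibody <- function(antigen_name, fluorochrome, clone = NA_character_) {
  stopifnot(is.character(antigen_name), length(antigen_name) == 1L,
            nzchar(antigen_name))
  structure(
    list(antigen_name = antigen_name,
         fluorochrome = fluorochrome,
         clone        = clone,
         channel_name = fluorochrome_channel(fluorochrome)),
    class = "antibody")
}

#' @export
print.antibody <- function(x, ...) {
  cat(sprintf("<antibody> %s (%s -> %s)\n",
              x$antigen_name, x$fluorochrome, x$channel_name))
  invisible(x)
}

.WELL_RE <- "^[A-H]([1-9]|1[0-2])$"

.check_well <- function(well) {
  bad <- !grepl(.WELL_RE, well)
  if (any(bad)) {
    stop("malformed well coordinate (expect A1..H12, uppercase, no zero ",
         "padding): ", paste(unique(well[bad]), collapse = ", "))
  }
  invisible(well)
}

#' Construct and validate a plate map
#'
#' A plate map assigns one antibody per well across one or more 96-well
#' plates, with buffer-only CONTROL wells per fluorochrome (the
#' fluorescence-minus-one controls used to set positivity thresholds) plus,
#' optionally, an unstained control (`fluorochrome = "NONE"`) used for the
#' viability threshold.
#'
#' @param wells A data frame with columns `plate`, `well`, `antigen`,
#'   `fluorochrome`, `clone`. The token `"CONTROL"` in the `antigen` column
#'   marks control wells.
#' @param staining_volumes Named list with `antibody_volume_ul`,
#'   `buffer_volume_ul`, `cell_volume_ul` (microlitres per well; defaults
#'   2, 48, 50 give the screen's 1:50 final antibody dilution).
#' @return An object of class `plate_map`.
#' @export
plate_map <- function(wells,
                      staining_volumes = list(antibody_volume_ul = 2,
                                              buffer_volume_ul  = 48,
                                              cell_volume_ul    = 50)) {
  need <- c("plate", "well", "antigen", "fluorochrome")
  if (!all(need %in% names(wells))) {
    stop("plate map needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(wells$clone)) wells$clone <- NA_character_
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  wells$plate <- as.character(wells$plate)
  if (nrow(wells) == 0L) stop("plate map has no wells")
  .check_well(wells$well)

  key <- paste(wells$plate, wells$well)
  if (anyDuplicated(key)) {
    stop("duplicate well: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  is_ctrl <- wells$antigen == "CONTROL"
  allowed <- c(names(.FLUOR_CHANNELS), "NONE")
  bad <- !(wells$fluorochrome %in% allowed) |
    (!is_ctrl & wells$fluorochrome == "NONE")
  if (any(bad)) {
    stop("unknown fluorochrome at ", wells$plate[bad][1L], "/",
         wells$well[bad][1L], ": ", wells$fluorochrome[bad][1L])
  }
  for (p in unique(wells$plate)) {
    if (!any(is_ctrl & wells$plate == p)) {
      stop("no control well on plate ", p)
    }
  }
  ab <- wells$antigen[!is_ctrl]
  if (anyDuplicated(ab)) {
    stop("antibody assigned more than once: ",
         paste(unique(ab[duplicated(ab)]), collapse = ", "))
  }
  stopifnot(all(unlist(staining_volumes) >= 0),
            staining_volumes$antibody_volume_ul > 0)
  structure(list(plates = unique(wells$plate),
                 wells = wells,
                 staining_volumes = staining_volumes),
            class = "plate_map")
}

#' @export
print.plate_map <- function(x, ...) {
  n_ab <- sum(x$wells$antigen != "CONTROL")
  cat(sprintf("<plate_map> %d plate(s), %d antibody well(s), %d control well(s)\n",
              length(x$plates), n_ab, nrow(x$wells) - n_ab))
  invisible(x)
}

#' Load a plate map from CSV
#'
#' The plate-map dialect is a CSV with columns
#' `plate,well,antigen,fluorochrome,clone`; `"CONTROL"` in the antigen
#' column marks control wells. Round-trips losslessly through
#' [save_plate_map()].
#'
#' @param path Path to a plate-map CSV.
#' @return A validated [plate_map].
#' @export
load_plate_map <- function(path) {
  if (!file.exists(path)) stop("plate map file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  plate_map(df)
}

#' Save a plate map to CSV
#'
#' @param map A [plate_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_plate_map <- function(map, path) {
  stopifnot(inherits(map, "plate_map"))
  utils::write.csv(map$wells[, c("plate", "well", "antigen",
                                 "fluorochrome", "clone")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Antibody staining dilution factor
#'
#' Final antibody dilution in a stained well: total well volume divided by
#' the antibody aliquot volume. The screen's plate layout (2 ul antibody +
#' 48 ul buffer + 50 ul cell suspension) gives a 100 ul final volume and a
#' 1:50 dilution.
#'
#' @param antibody_volume_ul Antibody aliquot volume (ul), > 0.
#' @param buffer_volume_ul Buffer volume (ul), >= 0.
#' @param cell_volume_ul Cell suspension volume (ul), >= 0.
#' @return The fold dilution (e.g. 50 for 1:50).
#' @export
compute_staining_dilution <- function(antibody_volume_ul,
                                      buffer_volume_ul,
                                      cell_volume_ul) {
  stopifnot(buffer_volume_ul >= 0, cell_volume_ul >= 0)
  if (antibody_volume_ul <= 0) stop("antibody volume must be > 0")
  (antibody_volume_ul + buffer_volume_ul + cell_volume_ul) / antibody_volume_ul
}

#' Load the packaged table of never-staining antibodies
#'
#' The screen identified a small set of antibodies that stained no cell type
#' tested; for some of those, a cell type expected to express the antigen
#' was actually analyzed (a true detection failure), for others it was not.
#' The packaged CSV reproduces that table row for row.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame with columns `antigen`, `expected_cell_type`,
#'   `cell_type_analyzed` (logical).
#' @export
read_nonstaining_table <- function(path = system.file("extdata",
                                                      "nonstaining_antibodies.csv",
                                                      package = "htfc")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("antigen", "expected_cell_type", "cell_type_analyzed")
                %in% names(df)))
  df$cell_type_analyzed <- as.logical(df$cell_type_analyzed)
  df
}

#' Summarize never-staining antibody records
#'
#' @param records Data frame as returned by [read_nonstaining_table()].
#' @return List with `total`, `analyzed_yes` (a cell type expected to stain
#'   was analyzed and did not stain) and `analyzed_no`.
#' @export
summarize_nonstaining <- function(records) {
  stopifnot(nrow(records) >= 1L || is.data.frame(records))
  list(total        = nrow(records),
       analyzed_yes = sum(records$cell_type_analyzed),
       analyzed_no  = sum(!records$cell_type_analyzed))
}

#' Packaged 24-antibody demonstration panel
#'
#' A single-plate demonstration panel: 24 antibodies (8 each on PE, FITC and
#' APC), one buffer-only control per fluorochrome, and one unstained control
#' for the viability gate. The full screening panel is data, not a constant:
#' any panel in the same CSV dialect can be used.
#'
#' @return A [plate_map].
#' @export
demo_plate_map <- function() {
  load_plate_map(system.file("extdata", "demo_panel.csv", package = "htfc"))
}
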