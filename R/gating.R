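# Reproducible automatic equivalents of the screen's manual gates:
# empirical-percentile FMO thresholds and a median-relative FSC-W singlet
# cut. Gate order is fixed: viability -> singlets -> positivity; the
# percent-positive denominator is viable singlets.

#' Gating configuration
#'
#' @param viability_channel Viability-dye channel name.
#' @param viability_fmo_percentile Percentile of the unstained control's
#'   viability channel used as the live/dead threshold.
#' @param singlet_width_factor Multiplier on the median FSC-W; events wider
#'   than `factor x median` are called doublets.
#' @param positivity_fmo_percentile Percentile of the matched
#'   fluorescence-minus-one control used as the positivity threshold.
#' @param min_events Minimum analysis (viable singlet) events for a well to
#'   pass QC; wells below it are reported missing, not zero. The default
#'   (5000) is half the acquisition floor of 10000 collected events,
#'   leaving headroom for dead-cell and doublet losses.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(viability_channel = "DAPI-A",
                        viability_fmo_percentile = 99.9,
                        singlet_width_factor = 1.5,
                        positivity_fmo_percentile = 99.9,
                        min_events = 5000L) {
  stopifnot(viability_fmo_percentile > 50, viability_fmo_percentile <= 100,
            positivity_fmo_percentile > 50, positivity_fmo_percentile <= 100,
            singlet_width_factor > 1, min_events >= 1)
  structure(list(viability_channel = viability_channel,
                 viability_fmo_percentile = viability_fmo_percentile,
                 singlet_width_factor = singlet_width_factor,
                 positivity_fmo_percentile = positivity_fmo_percentile,
                 min_events = as.integer(min_events)),
            class = "gate_config")
}

#' Fluorescence-minus-one threshold
#'
#' The positivity cutoff for a channel is an empirical percentile of the
#' matched control's signal in that channel. Quantiles use linear
#' interpolation between order statistics (the definition of
#' `stats::quantile(type = 7)`): with sorted values x_(1) <= ... <= x_(n)
#' and h = (n - 1) p + 1, the quantile is
#' x_(floor(h)) + (h - floor(h)) (x_(floor(h)+1) - x_(floor(h))).
#'
#' @param control Control `event_table`.
#' @param channel Channel name.
#' @param percentile Percentile in (50, 100].
#' @return Threshold value.
#' @export
fmo_threshold <- function(control, channel, percentile = 99.9) {
  stopifnot(inherits(control, "event_table"))
  if (!channel %in% colnames(control)) {
    stop("channel not present in control: ", channel)
  }
  x <- control[, channel]
  if (length(x) < 100L) {
    stop("QC error: control has ", length(x), " events in ", channel,
         " (need >= 100)")
  }
  unname(stats::quantile(x, probs = percentile / 100, type = 7, names = FALSE))
}

#' Viability gate
#'
#' @param events An `event_table` containing the viability channel.
#' @param config A [gate_config].
#' @param threshold Live/dead threshold (from [fmo_threshold()] on the
#'   unstained control's viability channel).
#' @return Logical mask, `TRUE` for viable (dye-low) events.
#' @export
gate_viable <- function(events, config = gate_config(), threshold) {
  ch <- config$viability_channel
  if (!ch %in% colnames(events)) stop("missing viability channel: ", ch)
  events[, ch] <= threshold
}

#' Singlet gate
#'
#' Doublets carry roughly doubled pulse area and width at unchanged height;
#' events with FSC-W at most `singlet_width_factor` times the median FSC-W
#' are retained.
#'
#' @param events An `event_table` with `FSC-H` and `FSC-W`.
#' @param config A [gate_config].
#' @return Logical mask, `TRUE` for singlets.
#' @export
gate_singlets <- function(events, config = gate_config()) {
  if (!all(c("FSC-H", "FSC-W") %in% colnames(events))) {
    stop("missing FSC-H/FSC-W channels")
  }
  w <- events[, "FSC-W"]
  w <= config$singlet_width_factor * stats::median(w)
}

#' Compose the full gate chain for one well
#'
#' Order is fixed: viability, then singlets within all events, then
#' positivity within viable singlets. Counts are non-increasing along the
#' chain; `qc_pass` is `FALSE` when fewer than `min_events` analysis events
#' remain.
#'
#' @param events An `event_table`.
#' @param config A [gate_config].
#' @param viability_threshold Threshold for [gate_viable()].
#' @param channel Stained channel for the positivity gate, or `NA` to skip.
#' @param threshold Positivity threshold for `channel`.
#' @return An object of class `gate_result`: masks (`viable`, `singlet`,
#'   `analysis`, `positive`), counts, thresholds and `qc_pass`.
#' @export
gate_events <- function(events, config = gate_config(), viability_threshold,
                        channel = NA_character_, threshold = NA_real_) {
  viable <- gate_viable(events, config, viability_threshold)
  singlet <- gate_singlets(events, config)
  analysis <- viable & singlet
  positive <- if (!is.na(channel)) {
    analysis & events[, channel] > threshold
  } else rep(FALSE, nrow(events))
  structure(list(
    masks = list(viable = viable, singlet = singlet,
                 analysis = analysis, positive = positive),
    counts = c(total = nrow(events), viable = sum(viable),
               singlet = sum(singlet), analysis = sum(analysis),
               positive = sum(positive)),
    thresholds = c(viability = viability_threshold, positivity = threshold),
    qc_pass = sum(analysis) >= config$min_events),
    class = "gate_result")
}

#' Percent-positive within the analysis gate
#'
#' @param events An `event_table`.
#' @param gates A `gate_result` (its `analysis` mask is the denominator).
#' @param channel Stained channel name.
#' @param threshold Positivity threshold; positivity is strictly greater
#'   than the threshold.
#' @return Percent in \[0, 100\].
#' @export
percent_positive <- function(events, gates, channel, threshold) {
  mask <- gates$masks$analysis
  if (!any(mask)) stop("QC error: empty analysis mask")
  100 * sum(events[mask, channel] > threshold) / sum(mask)
}

#' Lineage co-stain gate specification
#'
#' Ordered rules assigning each event to the first matching population;
#' events matching no rule are `"unassigned"`. The default reproduces the
#' four-population tumor deconvolution: CD45+ immune cells, CD45- CD31+
#' CD34+ vascular endothelial cells, CD45- TE7+ fibroblasts, and
#' quad-negative cancer cells.
#'
#' @param rules List of rules, each `list(population =, positive = c(...),
#'   negative = c(...))` over co-stain channel names.
#' @return An object of class `costain_gate_spec`.
#' @export
costain_gate_spec <- function(rules = list(
    list(population = "immune",
         positive = "APC-Cy7-A", negative = character()),
    list(population = "endothelial",
         positive = c("PE-Cy7-A", "PerCP-Cy5.5-A"), negative = "APC-Cy7-A"),
    list(population = "fibroblast",
         positive = "eFluor450-A", negative = "APC-Cy7-A"),
    list(population = "cancer",
         positive = character(),
         negative = c("APC-Cy7-A", "PE-Cy7-A", "PerCP-Cy5.5-A", "eFluor450-A")))) {
  for (r in rules) {
    stopifnot(is.character(r$population), nzchar(r$population))
  }
  structure(list(rules = rules), class = "costain_gate_spec")
}

#' Assign events to lineage populations by ordered co-stain rules
#'
#' Rules are evaluated in order and the first match wins, so the returned
#' masks are disjoint; their union plus `"unassigned"` covers all events.
#'
#' @param events An `event_table` containing every co-stain channel.
#' @param spec A [costain_gate_spec].
#' @param thresholds Named vector, co-stain channel -> FMO threshold.
#' @return Named list of logical masks, one per population plus
#'   `"unassigned"`.
#' @export
deconvolve_lineages <- function(events, spec, thresholds) {
  stopifnot(inherits(spec, "costain_gate_spec"))
  used <- unique(unlist(lapply(spec$rules, function(r) c(r$positive, r$negative))))
  miss <- setdiff(used, colnames(events))
  if (length(miss)) stop("co-stain rule references absent channel: ",
                         paste(miss, collapse = ", "))
  miss_t <- setdiff(used, names(thresholds))
  if (length(miss_t)) stop("no threshold for co-stain channel: ",
                           paste(miss_t, collapse = ", "))
  n <- nrow(events)
  assigned <- rep(FALSE, n)
  out <- list()
  for (r in spec$rules) {
    m <- !assigned
    for (ch in r$positive) m <- m & events[, ch] > thresholds[[ch]]
    for (ch in r$negative) m <- m & events[, ch] <= thresholds[[ch]]
    out[[r$population]] <- m
    assigned <- assigned | m
  }
  out[["unassigned"]] <- !assigned
  out
}

#' Compensate fluorescence channels for spillover
#'
#' Replaces the observed fluorescence block by `observed %*% solve(S)`,
#' undoing the linear spillover mixing; scatter and viability channels are
#' untouched.
#'
#' @param events An `event_table`.
#' @param spill A [spillover_matrix] whose channels are present in `events`.
#' @return Compensated `event_table`.
#' @export
apply_compensation <- function(events, spill) {
  stopifnot(inherits(spill, "spillover_matrix"))
  miss <- setdiff(spill$channels, colnames(events))
  if (length(miss)) stop("spillover channels absent from events: ",
                         paste(miss, collapse = ", "))
  inv <- tryCatch(solve(spill$values),
                  error = function(e) stop("singular spillover matrix"))
  md <- attr(events, "metadata")
  m <- unclass(events)
  m[, spill$channels] <- m[, spill$channels] %*% inv
  attr(m, "metadata") <- NULL
  # compensation can produce small negatives; keep finite values as-is
  event_table(m, metadata = md)
}

#' Gate a simulated (or loaded) plate into per-well summaries
#'
#' Pipeline step joining event data to the plate design: compensates each
#' well (if a spillover model is given), derives the viability threshold
#' from the unstained (`fluorochrome = "NONE"`) control and one FMO
#' positivity threshold per fluorochrome from the buffer-only controls,
#' then gates every antibody well.
#'
#' @param wells Named list of `event_table`s keyed `"plate/well"` (as from
#'   [simulate_screen_plate()]).
#' @param map The [plate_map] the wells were acquired under.
#' @param config A [gate_config].
#' @param spill Optional [spillover_matrix] to compensate with.
#' @return Data frame with one row per antibody well: plate, well, antigen,
#'   channel, counts along the gate chain, thresholds, percent_positive and
#'   qc_pass (percent_positive is `NA` for QC failures).
#' @export
gate_plate <- function(wells, map, config = gate_config(), spill = NULL) {
  stopifnot(inherits(map, "plate_map"))
  wm <- map$wells
  key <- paste(wm$plate, wm$well, sep = "/")
  miss <- setdiff(key, names(wells))
  if (length(miss)) stop("missing event data for wells: ",
                         paste(miss, collapse = ", "))
  if (!is.null(spill)) {
    wells <- lapply(wells, apply_compensation, spill = spill)
  }

  is_ctrl <- wm$antigen == "CONTROL"
  # viability threshold from the unstained control(s)
  via_keys <- key[is_ctrl & wm$fluorochrome == "NONE"]
  if (!length(via_keys)) {
    stop("fatal: no unstained (fluorochrome NONE) control well for the ",
         "viability gate")
  }
  via_ctrl <- do.call(rbind, lapply(wells[via_keys], unclass))
  via_thr <- fmo_threshold(event_table(via_ctrl), config$viability_channel,
                           config$viability_fmo_percentile)

  # one positivity threshold per fluorochrome from its FMO control's viable
  # singlet events
  fl_used <- unique(wm$fluorochrome[!is_ctrl])
  pos_thr <- numeric(0)
  for (fl in fl_used) {
    ck <- key[is_ctrl & wm$fluorochrome == fl]
    if (!length(ck)) {
      stop("fatal: no FMO control well for fluorochrome ", fl)
    }
    ch <- fluorochrome_channel(fl)
    ctrl <- do.call(rbind, lapply(wells[ck], unclass))
    ctrl <- event_table(ctrl)
    g <- gate_events(ctrl, config, via_thr)
    pos_thr[[ch]] <- fmo_threshold(event_table(ctrl[g$masks$analysis, ,
                                                    drop = FALSE]),
                                   ch, config$positivity_fmo_percentile)
  }

  rows <- which(!is_ctrl)
  out <- data.frame(plate = wm$plate[rows], well = wm$well[rows],
                    antigen = wm$antigen[rows],
                    channel = fluorochrome_channel(wm$fluorochrome[rows]),
                    total = NA_integer_, viable = NA_integer_,
                    analysis = NA_integer_,
                    viability_threshold = via_thr,
                    positivity_threshold = NA_real_,
                    percent_positive = NA_real_, qc_pass = NA,
                    stringsAsFactors = FALSE)
  for (j in seq_along(rows)) {
    i <- rows[j]
    ev <- wells[[key[i]]]
    ch <- out$channel[j]
    g <- gate_events(ev, config, via_thr, channel = ch,
                     threshold = pos_thr[[ch]])
    out$total[j] <- g$counts[["total"]]
    out$viable[j] <- g$counts[["viable"]]
    out$analysis[j] <- g$counts[["analysis"]]
    out$positivity_threshold[j] <- pos_thr[[ch]]
    out$qc_pass[j] <- g$qc_pass
    out$percent_positive[j] <- if (g$qc_pass) {
      percent_positive(ev, g, ch, pos_thr[[ch]])
    } else NA_real_
  }
  attr(out, "sample_id") <- attr(wells[[key[rows[1]]]], "metadata")$sample_id
  out
}
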