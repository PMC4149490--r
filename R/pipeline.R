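# Workflow orchestration: a single config object drives
# simulate -> gate -> screen -> cluster, with per-output seed/config
# provenance. The numbered drivers under analysis/ are thin narratives
# over these functions.

#' Pipeline configuration
#'
#' @param map A [plate_map] (default: the packaged 24-antibody demo panel).
#' @param out_dir Output directory.
#' @param seed Master integer seed; every downstream seed derives from it.
#' @param populations List of [population_spec]s for the screened sample.
#' @param treatments List of [treatment_effect]s (screened against the
#'   untreated run).
#' @param noise A [technical_noise] model.
#' @param gate A [gate_config].
#' @param criteria A [screen_criteria].
#' @param cluster_k Cluster count for the profile dendrogram cut.
#' @param format `"fcs"` (FCS 3.0 well files) or `"csv"`.
#' @param sample_id Sample identifier.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(map = demo_plate_map(), out_dir, seed = 1L,
                            populations = demo_populations(),
                            treatments = list(demo_digestion_treatment()),
                            noise = technical_noise(),
                            gate = gate_config(),
                            criteria = screen_criteria(),
                            cluster_k = 2L,
                            format = c("fcs", "csv"),
                            sample_id = "POOL1") {
  structure(list(map = map, out_dir = out_dir, seed = as.integer(seed),
                 populations = populations, treatments = treatments,
                 noise = noise, gate = gate, criteria = criteria,
                 cluster_k = cluster_k, format = match.arg(format),
                 sample_id = sample_id),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `plate_map` (CSV path), `out_dir`, `seed`, `sample_id`,
#' `format`, `cluster_k`, `noise` (fields of [technical_noise()] except the
#' spillover, which stays at the default), `gate` (fields of
#' [gate_config()]), `criteria` (fields of [screen_criteria()]), and
#' `treatments` (list of label -> antigen -> `{factor:}` or `{set:}`).
#' Omitted keys keep the demo defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$plate_map)) args$map <- load_plate_map(y$plate_map)
  for (k in c("out_dir", "seed", "sample_id", "format", "cluster_k")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$noise)) args$noise <- do.call(technical_noise, y$noise)
  if (!is.null(y$gate)) args$gate <- do.call(gate_config, y$gate)
  if (!is.null(y$criteria)) args$criteria <- do.call(screen_criteria, y$criteria)
  if (!is.null(y$treatments)) {
    args$treatments <- lapply(names(y$treatments), function(lbl) {
      treatment_effect(lbl, y$treatments[[lbl]])
    })
  }
  do.call(pipeline_config, args)
}

# stable FNV-1a hash of the deparsed config (minus the volatile output
# path), for output provenance
.config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.condition_seed <- function(config, condition) {
  well_seed(config$seed, config$sample_id, condition)
}

#' Simulate the configured screen to disk
#'
#' Simulates one plate set per condition (untreated plus each treatment),
#' writes every well as FCS 3.0 (or gzipped CSV) under
#' `out_dir/events/<condition>/`, and a JSON manifest recording seeds,
#' planted positive fractions and the config hash — the ground truth that
#' downstream oracle checks read.
#'
#' @param config A [pipeline_config].
#' @return Manifest path, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ev_dir <- file.path(config$out_dir, "events")
  conditions <- c(list(untreated = NULL),
                  stats::setNames(config$treatments,
                                  vapply(config$treatments, `[[`, "", "label")))
  manifest <- list(seed = config$seed, sample_id = config$sample_id,
                   config_hash = .config_hash(config),
                   format = config$format, conditions = list())
  for (cond in names(conditions)) {
    dir.create(file.path(ev_dir, cond), recursive = TRUE, showWarnings = FALSE)
    cseed <- .condition_seed(config, cond)
    pops <- apply_treatment(config$populations, conditions[[cond]])
    wells <- simulate_screen_plate(config$map, config$populations,
                                   config$noise,
                                   treatment = conditions[[cond]],
                                   seed = cseed,
                                   sample_id = config$sample_id)
    files <- character(0)
    for (key in names(wells)) {
      fn <- paste0(gsub("/", "_", key), if (config$format == "fcs") ".fcs"
                                        else ".csv.gz")
      path <- file.path(ev_dir, cond, fn)
      if (config$format == "fcs") {
        write_fcs(wells[[key]], path)
      } else {
        write_events_csv(wells[[key]], path)
      }
      files[key] <- file.path("events", cond, fn)
    }
    manifest$conditions[[cond]] <- list(
      seed = cseed,
      files = as.list(files),
      planted_positive_fraction = lapply(pops, function(p) {
        list(name = p$name, abundance = p$abundance,
             positive_fraction = as.list(p$positive_fraction))
      }))
  }
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Write events as gzipped CSV with a JSON metadata sidecar
#'
#' Tabular fallback to FCS: header row of channel names, one row per event.
#'
#' @param events An `event_table`.
#' @param path Output path (`.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  con <- gzfile(path, "wb")
  utils::write.csv(as.data.frame(unclass(events)), con, row.names = FALSE)
  close(con)
  md <- attr(events, "metadata")
  md$truth <- NULL
  jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read events written by [write_events_csv()]
#'
#' @param path Path to a `.csv.gz` events file.
#' @return An `event_table`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(gzfile(path), check.names = FALSE)
  md <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list()
  event_table(as.matrix(df), metadata = md)
}

#' Gate, screen and cluster a simulated run
#'
#' Reads the manifest written by [run_simulate()], gates every condition's
#' plate set (compensating with the configured spillover), assembles the
#' percent-positive matrix, screens each treatment against the untreated
#' run with the dual lability criteria, and exports the matrix, screen
#' results, category summary, QC report and (for >= 2 conditions) the
#' Pearson-distance complete-linkage dendrogram.
#'
#' @param config The [pipeline_config] used for [run_simulate()].
#' @return Named list of output file paths, invisibly.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mpath <- file.path(config$out_dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest at ", mpath,
                                "; run run_simulate() first")
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  read1 <- if (identical(manifest$format, "fcs")) read_fcs else read_events_csv

  summaries <- list()
  for (cond in names(manifest$conditions)) {
    files <- manifest$conditions[[cond]]$files
    wells <- lapply(files, function(f) read1(file.path(config$out_dir, f)))
    names(wells) <- names(files)
    summaries[[cond]] <- gate_plate(wells, config$map, config$gate,
                                    spill = config$noise$spillover)
  }
  mat <- assemble_matrix(summaries, config$map)

  out <- list()
  prov <- sprintf("# seed=%d config=%s", config$seed, .config_hash(config))
  write_prov_csv <- function(df, path) {
    con <- file(path, "w")
    writeLines(prov, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  out$matrix <- write_prov_csv(
    data.frame(condition = rownames(mat), as.data.frame(unclass(mat)),
               check.names = FALSE), file.path(config$out_dir, "percent_positive.csv"))
  qc <- do.call(rbind, lapply(names(summaries), function(cond) {
    cbind(condition = cond, summaries[[cond]])
  }))
  out$qc <- write_prov_csv(qc, file.path(config$out_dir, "gate_summary.csv"))

  results <- do.call(rbind, lapply(names(manifest$conditions)[-1], function(tr) {
    screen_treatment(mat["untreated", ], mat[tr, ], config$criteria,
                     treatment = tr)
  }))
  if (!is.null(results)) {
    out$screen <- write_prov_csv(results,
                                 file.path(config$out_dir, "screen_results.csv"))
    summ <- screen_summary(results)
    summ$per_treatment <- as.data.frame(summ$per_treatment)
    summ$seed <- config$seed
    summ$config_hash <- .config_hash(config)
    out$summary <- file.path(config$out_dir, "screen_summary.json")
    jsonlite::write_json(summ, out$summary, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (nrow(mat) >= 2L) {
    cmat <- knn_impute(mat)
    tree <- hcluster(pearson_distance(cmat))
    out$dendrogram <- file.path(config$out_dir, "conditions.nwk")
    export_dendrogram(tree, out$dendrogram,
                      order_path = file.path(config$out_dir,
                                             "condition_order.csv"))
  }
  invisible(out)
}
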