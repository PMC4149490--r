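# Independent oracles and small fixture builders, kept deliberately
# separate from the package's own code paths.

# --- naive complete-linkage agglomeration: recompute every inter-cluster
# distance from the original matrix at every step -----------------------
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- max(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- exhaustive k-NN imputation oracle ---------------------------------
brute_knn_impute <- function(m, k) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      if (!is.na(m[i, cc])) next
      cand <- setdiff(which(!is.na(m[, cc])), i)
      d <- sapply(cand, function(j) {
        sh <- !is.na(m[i, ]) & !is.na(m[j, ])
        sqrt(mean((m[i, sh] - m[j, sh])^2))
      })
      nb <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
      out[i, cc] <- mean(m[nb, cc])
    }
  }
  out
}

# --- Spearman rho via the rank-difference formula (tie-free inputs) ----
spearman_d2 <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}

# --- minimal independent FCS reader: byte-level, shares nothing with the
# package implementation ------------------------------------------------
independent_fcs_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 6, useBytes = TRUE)
  stopifnot(magic == "FCS3.0")
  readChar(con, 4, useBytes = TRUE)
  offs <- sapply(1:6, function(i) as.integer(trimws(readChar(con, 8, useBytes = TRUE))))
  seek(con, offs[1])
  txt <- readChar(con, offs[2] - offs[1] + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(2 * (length(parts) %/% 2))]
  kv <- setNames(parts[c(FALSE, TRUE)], parts[c(TRUE, FALSE)])
  p <- as.integer(kv["$PAR"]); n <- as.integer(kv["$TOT"])
  stopifnot(kv["$DATATYPE"] == "F", kv["$MODE"] == "L")
  seek(con, offs[3])
  vals <- readBin(con, "numeric", n * p, size = 4,
                  endian = if (kv["$BYTEORD"] == "1,2,3,4") "little" else "big")
  matrix(vals, nrow = n, byrow = TRUE,
         dimnames = list(NULL, unname(kv[sprintf("$P%dN", seq_len(p))])))
}

# replace the first occurrence of an ASCII byte pattern in a raw vector
replace_bytes <- function(raw, pattern, replacement) {
  pat <- charToRaw(pattern)
  rep <- charToRaw(replacement)
  stopifnot(length(pat) == length(rep))
  hits <- which(raw == pat[1])
  for (h in hits) {
    if (h + length(pat) - 1L <= length(raw) &&
        all(raw[h:(h + length(pat) - 1L)] == pat)) {
      raw[h:(h + length(rep) - 1L)] <- rep
      return(raw)
    }
  }
  stop("pattern not found")
}

# --- fixture builders ---------------------------------------------------
single_pop <- function(pf, name = "pop", stain = list(), auto = list()) {
  list(population_spec(name, 1, pf, stain_intensity = stain,
                       autofluorescence = auto))
}

quiet_noise <- function(events = 10000L, ...) {
  # no jitter, no dead cells or doublets, identity spillover: isolates the
  # staining model
  technical_noise(events_per_well = events, dead_fraction = 0,
                  doublet_fraction = 0,
                  spillover = spillover_matrix(c("PE-A", "FITC-A", "APC-A")),
                  intensity_jitter_sd = 0, ...)
}

# a tiny 2-plate map with two antibodies per plate
tiny_map_df <- function() {
  data.frame(
    plate = c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2"),
    well = c("A1", "A2", "C1", "C4", "A1", "A2", "C1", "C4"),
    antigen = c("CD45", "EpCAM", "CONTROL", "CONTROL",
                "CD90", "CD24", "CONTROL", "CONTROL"),
    fluorochrome = c("PE", "APC", "PE", "NONE", "FITC", "APC", "FITC", "NONE"),
    clone = NA_character_,
    stringsAsFactors = FALSE)
}

# gate an already-simulated replicate plate of the demo sample into one
# percent-positive profile row
demo_profile_row <- function(seed, noise = technical_noise(),
                             map = demo_plate_map(),
                             pops = demo_populations(),
                             treatment = NULL, gate = gate_config()) {
  wells <- simulate_screen_plate(map, pops, noise, treatment = treatment,
                                 seed = seed)
  g <- gate_plate(wells, map, gate, spill = noise$spillover)
  assemble_matrix(list(run = g), map)[1, ]
}
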