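# Minimal FCS 3.0 list-mode I/O: single data set, float32 data
# ($DATATYPE/F, $MODE/L), little-endian by default. Channel names are
# carried in $PnN; well/plate/sample metadata in custom keywords.

.FCS_DELIM <- "/"

#' Write an event table as an FCS 3.0 file
#'
#' List-mode, 32-bit float data. Channel names go to the `$PnN` keywords;
#' `plate`, `well`, `sample_id` and `seed` metadata, when present, are
#' stored as custom TEXT keywords and restored by [read_fcs()].
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  ch <- colnames(events)
  if (any(grepl(.FCS_DELIM, ch, fixed = TRUE))) {
    stop("channel names must not contain the TEXT delimiter '", .FCS_DELIM, "'")
  }
  n <- nrow(events); p <- ncol(events)
  md <- attr(events, "metadata")

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@BD@", "$ENDDATA", "@ED@",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", i), ch[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(events[, i], 1)),
                                        scientific = FALSE))
  }
  for (key in c("plate", "well", "sample_id", "seed")) {
    if (!is.null(md[[key]]) && !is.na(md[[key]])) {
      kw <- c(kw, paste0("HTFC_", toupper(key)), as.character(md[[key]]))
    }
  }

  d <- .FCS_DELIM
  text <- paste0(d, paste(kw, collapse = d), d)
  # placeholders are fixed 8-wide so TEXT length is stable when filled in
  text <- sub("@BD@", "@BDxxxxx", text, fixed = TRUE)
  text <- sub("@ED@", "@EDxxxxx", text, fixed = TRUE)
  text_start <- 58L
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  text <- sub("@BDxxxxx", sprintf("%08d", data_start), text, fixed = TRUE)
  text <- sub("@EDxxxxx", sprintf("%08d", data_end), text, fixed = TRUE)

  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end,
                 if (data_end <= 99999999L) data_start else 0L,
                 if (data_end <= 99999999L) data_end else 0L,
                 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(unclass(events))), con, size = 4L, endian = "little")
  invisible(path)
}

.fcs_text_keywords <- function(raw, text_start, text_end) {
  txt <- rawToChar(raw[(text_start + 1L):(text_end + 1L)])
  d <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  parts <- strsplit(body, d, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L && parts[length(parts)] == "") {
    parts <- parts[-length(parts)]
  }
  if (length(parts) %% 2L != 0L) stop("FCS format error: unpaired TEXT keyword")
  kw <- parts[seq(2L, length(parts), by = 2L)]
  names(kw) <- parts[seq(1L, length(parts), by = 2L)]
  kw
}

#' Read an FCS 3.0 file into an event table
#'
#' Supports the subset written by [write_fcs()] plus integer/float
#' list-mode variants with either byte order.
#'
#' @param path Path to an FCS file.
#' @return An `event_table` with channel names from `$PnN`.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 58L) stop("FCS format error: truncated header (offset 0)")
  if (rawToChar(raw[1:6]) != "FCS3.0") {
    stop("FCS format error: bad magic '", rawToChar(raw[1:6]), "' (offset 0)")
  }
  off <- function(i) {
    s <- rawToChar(raw[(11L + 8L * (i - 1L)):(10L + 8L * i)])
    as.integer(trimws(s))
  }
  text_start <- off(1); text_end <- off(2)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start ||
      text_end + 1L > length(raw)) {
    stop("FCS format error: invalid TEXT offsets (offset 10)")
  }
  kw <- .fcs_text_keywords(raw, text_start, text_end)
  need <- c("$DATATYPE", "$MODE", "$BYTEORD", "$PAR", "$TOT")
  miss <- setdiff(need, names(kw))
  if (length(miss)) {
    stop("FCS format error: missing required TEXT keyword ",
         paste(miss, collapse = ", "))
  }
  if (kw[["$MODE"]] != "L") stop("unsupported $MODE: ", kw[["$MODE"]])
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "D", "I")) stop("unsupported $DATATYPE: ", dtype)
  endian <- if (kw[["$BYTEORD"]] %in% c("1,2,3,4", "1,2")) "little" else "big"
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])

  data_start <- off(3); data_end <- off(4)
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  sz <- if (dtype == "D") 8L else 4L
  expect <- sz * n * p
  if (data_start + expect - 1L > length(raw)) {
    stop("FCS format error: truncated DATA segment (offset ", data_start, ")")
  }
  what <- if (dtype == "I") "integer" else "numeric"
  vals <- readBin(raw[(data_start + 1L):(data_start + expect)],
                  what, n = n * p, size = sz, endian = endian,
                  signed = TRUE)
  ch <- vapply(seq_len(p), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) stop("FCS format error: missing $P", i, "N")
    nm
  }, "")
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE,
              dimnames = list(NULL, ch))
  md <- list()
  for (key in c("plate", "well", "sample_id", "seed")) {
    v <- kw[[paste0("HTFC_", toupper(key))]]
    if (!is.null(v)) md[[key]] <- if (key == "seed") as.integer(v) else v
  }
  event_table(m, metadata = md)
}
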