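# Recording and network I/O. Two recording formats are supported: a
# delimited text dialect (comma-separated; row 1 = channel labels, then
# one row of samples per channel) and a minimal EDF (European Data
# Format) profile with one data record per trial and 16-bit samples.

.validateMontageLabels <- function(labels) {
  unknown <- setdiff(labels, .MONTAGE_LABELS)
  if (length(unknown))
    stop("channel label(s) not in the 60-channel montage: ",
         paste(unknown, collapse = ", "))
}

#' Write a recording to disk
#'
#' @param rec a [Recording-class].
#' @param path output file.
#' @param format `"csv"` (delimited text) or `"edf"`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(is(rec, "Recording"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(rec@labels, collapse = ","), con)
    write.table(format(rec@data, digits = 10, trim = TRUE,
                       scientific = TRUE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  } else {
    .writeEdf(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads a trial written by [writeRecording()] (or any file in the same
#' dialect). Channel order is preserved as stored; labels must belong to
#' the 60-channel montage. Delimited input carries no sampling rate, so
#' `fs` is required for CSV.
#'
#' @param path input file.
#' @param format `"csv"` or `"edf"`; inferred from the extension by
#'   default.
#' @param fs sampling rate in Hz (required for CSV input).
#' @param stageBounds stage boundaries in seconds for the returned
#'   recording.
#' @return a [Recording-class].
#' @export
readRecording <- function(path, format = NULL, fs = NULL,
                          stageBounds = c(0, 3, 4, 8, 10)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "csv"
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    if (is.null(fs))
      stop("delimited input carries no sampling rate; supply 'fs'")
    lines <- readLines(path)
    labels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    .validateMontageLabels(labels)
    data <- do.call(rbind, lapply(lines[-1], function(l)
      as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
    if (nrow(data) != length(labels))
      stop(sprintf("header lists %d channels but file has %d data rows",
                   length(labels), nrow(data)))
    new("Recording", data = data, labels = labels, fs = fs,
        stageBounds = stageBounds, history = "read(csv)")
  } else {
    .readEdf(path, stageBounds = stageBounds)
  }
}

# --- minimal EDF profile -------------------------------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal) followed by one
# data record of little-endian int16 samples, signal by signal. Physical
# scaling is per channel from the data range.

.edfField <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

.writeEdf <- function(rec, path) {
  data <- rec@data
  n <- nrow(data)
  nSamp <- ncol(data)
  duration <- nSamp / rec@fs
  physMin <- apply(data, 1, min)
  physMax <- apply(data, 1, max)
  flat <- physMax - physMin <= 0
  physMax[flat] <- physMin[flat] + 1
  dig <- t(vapply(seq_len(n), function(i) {
    round((data[i, ] - physMin[i]) / (physMax[i] - physMin[i]) *
            65535 - 32768)
  }, numeric(nSamp)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfField("0", 8),
    .edfField(sprintf("subject %s task %s trial %s", rec@subject,
                      rec@task, rec@trial), 80),
    .edfField("bfncir synthetic motor imagery", 80),
    .edfField("01.01.00", 8), .edfField("00.00.00", 8),
    .edfField(256 + 256 * n, 8), .edfField("", 44),
    .edfField(1, 8), .edfField(duration, 8), .edfField(n, 4),
    paste(.edfField(rec@labels, 16), collapse = ""),
    paste(rep(.edfField("", 80), n), collapse = ""),
    paste(rep(.edfField("uV", 8), n), collapse = ""),
    paste(.edfField(signif(physMin, 6), 8), collapse = ""),
    paste(.edfField(signif(physMax, 6), 8), collapse = ""),
    paste(rep(.edfField(-32768, 8), n), collapse = ""),
    paste(rep(.edfField(32767, 8), n), collapse = ""),
    paste(rep(.edfField("", 80), n), collapse = ""),
    paste(rep(.edfField(nSamp, 8), n), collapse = ""),
    paste(rep(.edfField("", 32), n), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # one data record: all samples of signal 1, then signal 2, ...
  writeBin(as.integer(as.vector(t(dig))), con, size = 2,
           endian = "little")
}

.readEdf <- function(path, stageBounds = c(0, 3, 4, 8, 10)) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)
  patient <- trimws(readChar(con, 80, useBytes = TRUE))
  readChar(con, 80 + 8 + 8, useBytes = TRUE)
  readChar(con, 8, useBytes = TRUE)              # header bytes
  readChar(con, 44, useBytes = TRUE)
  nRec <- as.integer(readChar(con, 8, useBytes = TRUE))
  duration <- as.numeric(readChar(con, 8, useBytes = TRUE))
  n <- as.integer(readChar(con, 4, useBytes = TRUE))
  rdFields <- function(width) {
    vapply(seq_len(n),
           function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
  }
  labels <- rdFields(16)
  rdFields(80)                                   # transducer
  rdFields(8)                                    # physical dimension
  physMin <- as.numeric(rdFields(8))
  physMax <- as.numeric(rdFields(8))
  digMin <- as.numeric(rdFields(8))
  digMax <- as.numeric(rdFields(8))
  rdFields(80)                                   # prefiltering
  nSamp <- as.integer(rdFields(8))
  rdFields(32)
  .validateMontageLabels(labels)
  data <- matrix(0, n, nSamp[1])
  for (rec_i in seq_len(nRec)) {
    for (i in seq_len(n)) {
      raw <- readBin(con, integer(), n = nSamp[i], size = 2,
                     endian = "little")
      data[i, ] <- physMin[i] + (raw - digMin[i]) /
        (digMax[i] - digMin[i]) * (physMax[i] - physMin[i])
    }
  }
  meta <- regmatches(patient,
                     regexec("subject (\\S+) task (\\S+) trial (\\S+)",
                             patient))[[1]]
  new("Recording", data = data, labels = labels,
      fs = nSamp[1] / duration, stageBounds = stageBounds,
      subject = if (length(meta)) meta[2] else NA_character_,
      task = if (length(meta)) meta[3] else NA_character_,
      trial = if (length(meta)) as.integer(meta[4]) else NA_integer_,
      history = "read(edf)")
}

# --- network export ------------------------------------------------------

#' Export a network as a weighted edge list
#'
#' CSV with columns `node_i`, `node_j`, `r_ij`, one row per surviving
#' edge (i before j in node order).
#'
#' @param G a [BfnGraph-class].
#' @param path output CSV path.
#' @return the edge-list data.frame, invisibly.
#' @export
writeEdgeList <- function(G, path) {
  stopifnot(is(G, "BfnGraph"))
  idx <- which(upper.tri(G@adjacency) & G@adjacency == 1, arr.ind = TRUE)
  el <- data.frame(node_i = G@labels[idx[, 1]],
                   node_j = G@labels[idx[, 2]],
                   r_ij = G@weights[idx])
  write.csv(el, path, row.names = FALSE)
  invisible(el)
}

#' Export a network as GraphML
#'
#' @param G a [BfnGraph-class].
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(G, path) {
  stopifnot(is(G, "BfnGraph"))
  g <- igraph::graph_from_adjacency_matrix(
    G@weights, mode = "undirected", weighted = TRUE)
  igraph::V(g)$name <- G@labels
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a correlation (or any square) matrix as delimited text
#'
#' @param R a [CorrelationMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCorrelation <- function(R, path) {
  stopifnot(is(R, "CorrelationMatrix"))
  write.csv(corValues(R), path)
  invisible(path)
}
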