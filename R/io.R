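#' Read and write tracks as CSV
#'
#' Tracks are serialized as CSV with header `t_s,x_mm,y_mm` and an
#' optional `heading_rad` column. Units are fixed by the format (mm, s,
#' radians) and validated on load.
#'
#' @param path file path.
#' @return `readTrack` returns a [Track-class].
#' @export
readTrack <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("t_s", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("malformed track header: need columns ", paste(need, collapse = ","),
         " (line 1)")
  Track(d$t_s, d$x_mm, d$y_mm,
        heading = if ("heading_rad" %in% names(d)) d$heading_rad else numeric())
}

#' @rdname readTrack
#' @param track a [Track-class].
#' @export
writeTrack <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trace matrices as delimited text
#'
#' Rows are ROIs, columns time points; the sampling rate (and optional
#' ROI coordinates) live in a JSON sidecar `<path>.json`.
#'
#' @param path file path of the delimited matrix.
#' @return `readTraceMatrix` returns a [TraceSet-class].
#' @export
readTraceMatrix <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(side$rate_hz)) stop("sidecar must state rate_hz")
  coords <- if (!is.null(side$coords)) as.data.frame(side$coords) else NULL
  dimnames(m) <- NULL
  TraceSet(m, rateHz = side$rate_hz, coords = coords)
}

#' @rdname readTraceMatrix
#' @param traces a [TraceSet-class].
#' @export
writeTraceMatrix <- function(traces, path) {
  utils::write.table(traceMatrix(traces), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- list(rate_hz = traceRate(traces))
  cd <- SummarizedExperiment::rowData(traces)
  if (ncol(cd)) side$coords <- as.data.frame(cd)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write stimulus schedules as CSV
#'
#' Columns: `onset_s,duration_s,label,freq_hz` plus any extras.
#'
#' @param path file path.
#' @return `readStimulusSchedule` returns a [StimulusSchedule-class].
#' @export
readStimulusSchedule <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label", "freq_hz")
  if (!all(need %in% names(d)))
    stop("malformed schedule header: need ", paste(need, collapse = ","),
         " (line 1)")
  StimulusSchedule(d)
}

#' @rdname readStimulusSchedule
#' @param schedule a [StimulusSchedule-class].
#' @export
writeStimulusSchedule <- function(schedule, path) {
  write.csv(scheduleTable(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal NRRD volume input/output
#'
#' Reads and writes detached-free NRRD files with raw encoding and
#' little-endian doubles or floats, carrying the mandatory voxel
#' spacings. This covers the volumes the package exchanges (density
#' fields, channel volumes, masks); exotic NRRD features are out of
#' scope.
#'
#' @param path file path.
#' @return `readNRRD` returns a list with `data` (3-D array) and
#'   `spacing` (numeric, per-axis spacing).
#' @export
readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop("malformed NRRD header: bad magic (line 1)")
  fields <- list()
  lineNo <- 1
  repeat {
    ln <- readLines(con, n = 1)
    lineNo <- lineNo + 1
    if (!length(ln) || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed NRRD header at line ", lineNo)
    fields[[trimws(kv[1])]] <- trimws(sub("^=?\\s*", "", kv[2]))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  enc <- fields$encoding
  if (is.null(enc) || enc != "raw") stop("only raw encoding is supported")
  what <- switch(type, double = "double", float = "double",
                 stop("unsupported NRRD type: ", type))
  size <- switch(type, double = 8L, float = 4L)
  endian <- if (!is.null(fields$endian) && fields$endian == "big")
    "big" else "little"
  vals <- readBin(con, what, n = prod(sizes), size = size, endian = endian)
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else rep(1, length(sizes))
  list(data = array(vals, sizes), spacing = spacing)
}

#' @rdname readNRRD
#' @param data numeric array.
#' @param spacing per-axis voxel spacing.
#' @param type `"double"` (lossless) or `"float"`.
#' @export
writeNRRD <- function(data, path, spacing = rep(1, length(dim(data))),
                      type = c("double", "float")) {
  type <- match.arg(type)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           paste0("dimension: ", length(dim(data))),
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(spacing, collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con)
  writeBin(as.numeric(data), con, size = if (type == "double") 8L else 4L,
           endian = "little")
  invisible(path)
}

#' Multi-page TIFF volume input/output with JSON sidecar
#'
#' Volumes are stored as 32-bit TIFF stacks (one page per z plane).
#' Because the TIFF writer stores values in \[0, 1\], intensities are
#' affinely mapped to that range; the scale, offset and voxel spacing
#' are recorded in a `<path>.json` sidecar and undone on read. The
#' format quantizes values to 32 bits (about 2e-10 of the intensity
#' range per conversion); NRRD is the lossless dialect.
#'
#' @param path file path of the TIFF stack.
#' @return `readVolumeTIFF` returns a list with `data` and `spacing`.
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(unlist(lapply(pages, function(p) as.numeric(t(p)))),
               c(dim(pages[[1]])[2], dim(pages[[1]])[1], length(pages)))
  arr <- arr * side$scale + side$offset
  list(data = arr, spacing = as.numeric(side$spacing))
}

#' @rdname readVolumeTIFF
#' @param data numeric 3-D array (x, y, z).
#' @param spacing per-axis voxel spacing.
#' @export
writeVolumeTIFF <- function(data, path, spacing = c(1, 1, 1)) {
  rng <- range(data)
  offset <- rng[1]
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (data - offset) / scale
  pages <- lapply(seq_len(dim(data)[3]), function(k) t(norm[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(scale = scale, offset = offset,
                            spacing = spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert between supported file dialects
#'
#' Lossless conversion of numeric payloads between the package's file
#' dialects. Tracks and schedules round-trip through CSV; volumes
#' convert between NRRD (double precision, lossless) and float TIFF
#' (single precision).
#'
#' @param input,output file paths.
#' @param from,to dialects: `track_csv`, `schedule_csv`, `trace_matrix`,
#'   `nrrd`, `tiff`.
#' @return `output`, invisibly.
#' @export
convertFile <- function(input, output, from, to) {
  dialects <- c("track_csv", "schedule_csv", "trace_matrix", "nrrd", "tiff")
  if (!from %in% dialects || !to %in% dialects)
    stop("unknown dialect; supported: ", paste(dialects, collapse = ", "))
  volGroup <- c("nrrd", "tiff")
  if (from %in% volGroup != to %in% volGroup ||
      (!from %in% volGroup && from != to))
    stop("cannot convert between dialects ", from, " and ", to)
  if (from == "track_csv") return(writeTrack(readTrack(input), output))
  if (from == "schedule_csv")
    return(writeStimulusSchedule(readStimulusSchedule(input), output))
  if (from == "trace_matrix")
    return(writeTraceMatrix(readTraceMatrix(input), output))
  vol <- if (from == "nrrd") readNRRD(input) else readVolumeTIFF(input)
  if (to == "nrrd") writeNRRD(vol$data, output, spacing = vol$spacing)
  else writeVolumeTIFF(vol$data, output, spacing = vol$spacing)
  invisible(output)
}
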