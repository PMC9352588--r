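#' TraceSet: ROI fluorescence traces with acquisition metadata
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment]
#' holding one `fluo` assay (rows = ROIs, columns = time points at a
#' stated uniform rate) plus optional ROI anatomical coordinates in
#' `rowData` and the sampling rate in `metadata`. Traces are raw
#' fluorescence (non-negative); dF/F is computed per stimulus epoch by
#' [epochDFF()].
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  if (!"fluo" %in% SummarizedExperiment::assayNames(object))
    return("TraceSet needs a 'fluo' assay")
  r <- S4Vectors::metadata(object)$rate_hz
  if (is.null(r) || r <= 0)
    return("metadata must carry a positive rate_hz")
  if (min(SummarizedExperiment::assay(object, "fluo")) < 0)
    return("raw fluorescence must be non-negative")
  TRUE
})

#' Construct a TraceSet
#'
#' @param fluo numeric matrix, ROI x time raw fluorescence.
#' @param rateHz sampling rate in volumes (frames) per second.
#' @param coords optional data.frame of ROI coordinates (x_um, y_um,
#'   z_um), one row per ROI.
#' @return A [TraceSet-class] object.
#' @examples
#' ts <- TraceSet(matrix(100 + rnorm(200), 2, 100), rateHz = 1)
#' traceRate(ts)
#' @export
TraceSet <- function(fluo, rateHz, coords = NULL) {
  fluo <- as.matrix(fluo)
  if (is.null(rownames(fluo))) rownames(fluo) <- paste0("roi", seq_len(nrow(fluo)))
  rd <- if (is.null(coords)) NULL else S4Vectors::DataFrame(coords)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluo = fluo),
    rowData = rd,
    metadata = list(rate_hz = rateHz))
  new("TraceSet", se)
}

#' @describeIn TraceSet The raw fluorescence matrix.
#' @param object a `TraceSet`.
#' @export
traceMatrix <- function(object)
  SummarizedExperiment::assay(object, "fluo")

#' @describeIn TraceSet Sampling rate (volumes per second).
#' @export
traceRate <- function(object) S4Vectors::metadata(object)$rate_hz

#' Downsample a TraceSet by block averaging
#'
#' Consecutive blocks of `factor` time points are replaced by their mean,
#' mirroring the fivefold downsampling of 5 volumes/s acquisitions to
#' one volume per second. A trailing partial block is dropped.
#'
#' @param object a [TraceSet-class].
#' @param factor integer downsampling factor.
#' @return A [TraceSet-class] at `rateHz/factor`.
#' @export
downsampleTraces <- function(object, factor = 5L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  f <- traceMatrix(object)
  nb <- ncol(f) %/% factor
  if (nb < 1) stop("trace shorter than one downsampling block")
  idx <- seq_len(nb * factor)
  grp <- rep(seq_len(nb), each = factor)
  out <- t(apply(f[, idx, drop = FALSE], 1, function(r) tapply(r, grp, mean)))
  cd <- SummarizedExperiment::rowData(object)
  TraceSet(out, rateHz = traceRate(object) / factor,
           coords = if (ncol(cd)) as.data.frame(cd) else NULL)
}

#' StimulusSchedule: stimulus presentation timing and labels
#'
#' One row per presentation: onset (s), duration (s, 22.6 s for standard
#' dot stimuli) and a stimulus label, plus the parameters needed
#' downstream (at least the bout frequency in Hz). Presentations must not
#' overlap and each onset must leave at least the baseline window
#' (5 s) clear after the previous presentation ends.
#'
#' @slot table data.frame with columns onset_s, duration_s, label,
#'   freq_hz and optionally size_mm, direction, kind.
#' @export
setClass("StimulusSchedule", representation(table = "data.frame"))

setValidity("StimulusSchedule", function(object) {
  tb <- object@table
  need <- c("onset_s", "duration_s", "label", "freq_hz")
  if (!all(need %in% names(tb)))
    return(paste("schedule needs columns:", paste(need, collapse = ", ")))
  if (is.unsorted(tb$onset_s, strictly = TRUE))
    return("onsets must be strictly increasing")
  if (nrow(tb) > 1) {
    gap <- tb$onset_s[-1] - (tb$onset_s + tb$duration_s)[-nrow(tb)]
    if (any(gap < 5 - 1e-9))
      return("presentations must be separated by at least the 5 s baseline window")
  }
  if (tb$onset_s[1] < 5 - 1e-9)
    return("first onset must leave a 5 s baseline window")
  TRUE
})

#' Construct a StimulusSchedule
#' @param table data.frame with columns onset_s, duration_s, label,
#'   freq_hz (and optional extras).
#' @return A [StimulusSchedule-class].
#' @export
StimulusSchedule <- function(table) new("StimulusSchedule", table = table)

#' @describeIn StimulusSchedule The schedule table.
#' @param object a `StimulusSchedule`.
#' @export
scheduleTable <- function(object) object@table

setMethod("show", "StimulusSchedule", function(object) {
  tb <- object@table
  cat(sprintf("StimulusSchedule: %d presentations of %d stimuli over %.1f s\n",
              nrow(tb), length(unique(tb$label)),
              max(tb$onset_s + tb$duration_s)))
})

#' Build a frequency-tuning stimulus schedule
#'
#' Presentations of the standard dot stimulus at the five bout
#' frequencies (0.75, 1.5, 3, 6, 60 Hz; 60 Hz is continuous at the
#' display rate), each 22.6 s long and followed by a 20 s break, repeated
#' `nReps` times in a fixed interleaved order.
#'
#' @param freqs bout frequencies, Hz.
#' @param nReps presentations per frequency.
#' @param duration presentation length, s.
#' @param gap break after each presentation, s.
#' @param lead time before the first onset, s.
#' @return A [StimulusSchedule-class].
#' @export
makeFrequencySchedule <- function(freqs = c(0.75, 1.5, 3, 6, 60),
                                  nReps = 4, duration = 22.6, gap = 20,
                                  lead = 10) {
  f <- rep(freqs, nReps)
  onset <- lead + (seq_along(f) - 1) * (duration + gap)
  StimulusSchedule(data.frame(
    onset_s = onset, duration_s = duration,
    label = sprintf("dot_%ghz", f), freq_hz = f,
    stringsAsFactors = FALSE))
}
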