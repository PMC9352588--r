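#' Epoch fluorescence traces into per-presentation dF/F
#'
#' Splits each ROI trace into stimulus episodes and computes
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean fluorescence over the
#' 5 s immediately before stimulus onset. ROI-presentations whose
#' baseline falls below `floorFrac` of the ROI's median fluorescence are
#' flagged invalid (NA) rather than producing unbounded dF/F.
#'
#' @param traces a [TraceSet-class].
#' @param schedule a [StimulusSchedule-class]; all presentation windows
#'   (including baselines) must lie inside the recording.
#' @param baselineS baseline window before onset, s (default 5).
#' @param floorFrac baseline floor as a fraction of the ROI median.
#' @return An object of class `EpochedDFF`: a list with elements `dff`
#'   (list of ROI x time matrices, one per presentation), `label`,
#'   `freq_hz`, and `rate_hz`.
#' @export
epochDFF <- function(traces, schedule, baselineS = 5, floorFrac = 0.01) {
  stopifnot(is(traces, "TraceSet"), is(schedule, "StimulusSchedule"))
  f <- traceMatrix(traces)
  rate <- traceRate(traces)
  tb <- scheduleTable(schedule)
  nb <- round(baselineS * rate)
  if (nb < 1) stop("baseline window shorter than one sample")
  dff <- vector("list", nrow(tb))
  roiMed <- apply(f, 1, median)
  for (k in seq_len(nrow(tb))) {
    i0 <- round(tb$onset_s[k] * rate) + 1L
    ns <- round(tb$duration_s[k] * rate)
    if (i0 - nb < 1 || i0 + ns - 1 > ncol(f))
      stop("presentation ", k, " (with its baseline) lies outside the recording")
    f0 <- rowMeans(f[, (i0 - nb):(i0 - 1L), drop = FALSE])
    bad <- f0 < floorFrac * roiMed
    m <- (f[, i0:(i0 + ns - 1L), drop = FALSE] - f0) / f0
    m[bad, ] <- NA_real_
    dff[[k]] <- m
  }
  structure(list(dff = dff, label = as.character(tb$label),
                 freq_hz = tb$freq_hz, rate_hz = rate),
            class = "EpochedDFF")
}

#' Mean dF/F response per ROI and stimulus
#'
#' Averages epoched dF/F across the presentations of each stimulus
#' first, then over the stimulus window in time, yielding one value per
#' ROI-stimulus pair. Presentations of unequal length are truncated to
#' the shortest before averaging. Stimuli without presentations are
#' simply absent from the table.
#'
#' @param epoched an `EpochedDFF` from [epochDFF()].
#' @return A [ResponseTable-class].
#' @export
meanResponses <- function(epoched) {
  stopifnot(inherits(epoched, "EpochedDFF"))
  labs <- unique(epoched$label)
  vals <- sapply(labs, function(l) {
    idx <- which(epoched$label == l)
    len <- min(vapply(epoched$dff[idx], ncol, integer(1)))
    m <- Reduce(`+`, lapply(epoched$dff[idx],
                            function(x) x[, seq_len(len), drop = FALSE]))
    rowMeans(m / length(idx))
  })
  vals <- matrix(vals, ncol = length(labs),
                 dimnames = list(rownames(epoched$dff[[1]]), labs))
  info <- data.frame(label = labs,
                     freq_hz = epoched$freq_hz[match(labs, epoched$label)],
                     stringsAsFactors = FALSE)
  ResponseTable(vals, info)
}

#' Responsiveness filter by per-stimulus percentile
#'
#' For each stimulus, the given percentile of its responses across ROIs
#' defines a cutoff; ROIs whose response strictly exceeds the cutoff for
#' at least one stimulus are retained. The percentile is configurable:
#' 95 for dense volumetric recordings, 90 or 50 for sparser data.
#'
#' @param table a [ResponseTable-class] with at least 20 ROIs.
#' @param percentile percentile in \[0, 100).
#' @return Integer indices of the retained ROIs.
#' @export
responsiveFilter <- function(table, percentile = 95) {
  stopifnot(is(table, "ResponseTable"))
  v <- responseValues(table)
  if (nrow(v) < 20)
    stop("percentile filter needs at least 20 ROIs")
  if (percentile <= 0) return(seq_len(nrow(v)))  # no threshold
  cut <- apply(v, 2, quantile, probs = percentile / 100, na.rm = TRUE)
  keep <- rowSums(sweep(v, 2, cut, `>`), na.rm = TRUE) > 0
  which(keep)
}

#' Bout preference index and BPN classification
#'
#' Splits stimuli into bout-like (0.75-3 Hz) and continuous (6-60 Hz)
#' categories regardless of size or direction, and computes, per ROI,
#'
#' \deqn{BPI = \frac{\bar R_{bout} - \bar R_{cont}}
#'                  {\bar R_{bout} + \bar R_{cont}}}
#'
#' where each category response is the mean over that category's mean
#' dF/F values. ROIs with `BPI > threshold` (default 0.5, a threefold
#' higher bout response) are flagged as bout preference neurons (BPNs).
#' A zero denominator yields NA with reason `"zero_denominator"`;
#' negative mean responses are admitted, and a BPI outside \[-1, 1\] is
#' kept but flagged `"outside_unit"`.
#'
#' @param table a [ResponseTable-class].
#' @param boutHz frequencies of the bout-like category, Hz.
#' @param contHz frequencies of the continuous category, Hz.
#' @param threshold BPN threshold on BPI.
#' @return data.frame with columns roi, bout_mean, cont_mean, bpi, bpn,
#'   flag.
#' @examples
#' rt <- ResponseTable(cbind(3, 1),
#'                     data.frame(label = c("b", "c"), freq_hz = c(1.5, 60)))
#' boutPreferenceIndex(rt)$bpi  # 0.5
#' @export
boutPreferenceIndex <- function(table, boutHz = c(0.75, 1.5, 3),
                                contHz = c(6, 60), threshold = 0.5) {
  stopifnot(is(table, "ResponseTable"))
  info <- stimInfo(table)
  v <- responseValues(table)
  bi <- which(info$freq_hz %in% boutHz)
  ci <- which(info$freq_hz %in% contHz)
  if (!length(bi) || !length(ci))
    stop("both stimulus categories must be present in the table")
  b <- rowMeans(v[, bi, drop = FALSE])
  cc <- rowMeans(v[, ci, drop = FALSE])
  den <- b + cc
  bpi <- ifelse(den == 0, NA_real_, (b - cc) / den)
  flag <- rep("", nrow(v))
  flag[den == 0] <- "zero_denominator"
  flag[!is.na(bpi) & abs(bpi) > 1] <- "outside_unit"
  data.frame(roi = if (is.null(rownames(v))) seq_len(nrow(v)) else rownames(v),
             bout_mean = b, cont_mean = cc, bpi = bpi,
             bpn = !is.na(bpi) & bpi > threshold, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tuning-peak location by quadratic spline interpolation
#'
#' Interpolates mean responses over a stimulus parameter with a
#' one-dimensional degree-2 (quadratic) spline through the support
#' points and returns the location of the interpolant's maximum over the
#' support interval (boundaries allowed). For bout-frequency tuning, the
#' supports span 0.75-60 Hz, so the interpolation runs on a log2
#' frequency axis by default (`logAxis = TRUE` in [frequencyTuningPeak()]).
#'
#' @param x stimulus parameter values (>= 3, distinct).
#' @param y mean responses at `x`.
#' @return The `x` location of the interpolant maximum.
#' @examples
#' tuningPeak(1:5, -(1:5 - 2.3)^2)  # 2.3
#' @export
tuningPeak <- function(x, y) {
  if (length(x) < 3) stop("at least 3 support points required")
  if (anyDuplicated(x)) stop("duplicate x values are invalid")
  o <- order(x)
  x <- as.numeric(x[o]); y <- as.numeric(y[o])
  n <- length(x)
  knots <- c(rep(x[1], 3),
             if (n > 3) (x[2:(n - 2)] + x[3:(n - 1)]) / 2,
             rep(x[n], 3))
  B <- splines::splineDesign(knots, x, ord = 3)
  co <- solve(B, y)
  f <- function(g) drop(splines::splineDesign(knots, g, ord = 3) %*% co)
  grid <- seq(x[1], x[n], length.out = 2001)
  fg <- f(grid)
  i <- which.max(fg)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  if (lo == hi) return(grid[i])
  opt <- optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  if (opt$objective >= fg[i]) opt$maximum else grid[i]
}

#' @describeIn tuningPeak Peak of a frequency tuning curve, interpolated
#'   on a log2 frequency axis and returned in Hz.
#' @param freqsHz stimulus bout frequencies, Hz.
#' @param responses mean dF/F responses at `freqsHz`.
#' @export
frequencyTuningPeak <- function(freqsHz, responses) {
  2^tuningPeak(log2(freqsHz), responses)
}
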