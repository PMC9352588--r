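#' @import methods
#' @importFrom stats approx convolve dist dnorm hclust mad median optimize
#'   quantile rnorm runif sd setNames t.test uniroot var rexp
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

#' Track: a time-stamped 2-D trajectory
#'
#' Uniformly sampled position of one animal or one stimulus dot, in dish
#' coordinates (millimetres, dish centre at the origin) with time in
#' seconds. An optional heading (radians, world frame, atan2 convention)
#' may be carried; when absent it is derived from frame-to-frame
#' displacement where needed.
#'
#' @slot t numeric, strictly increasing uniform time grid (s).
#' @slot x,y numeric, coordinates (mm).
#' @slot heading numeric, optional heading (rad); length 0 or length(t).
#' @export
setClass("Track", representation(t = "numeric", x = "numeric",
                                 y = "numeric", heading = "numeric"))

setValidity("Track", function(object) {
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n)
    return("t, x and y must have equal length")
  if (!all(is.finite(object@t)) || !all(is.finite(object@x)) ||
      !all(is.finite(object@y)))
    return("coordinates and times must be finite")
  if (n >= 2) {
    dt <- diff(object@t)
    if (any(dt <= 0)) return("time grid must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * stats::median(dt))
      return("time grid must be uniform")
  }
  if (length(object@heading) != 0 && length(object@heading) != n)
    return("heading must be empty or match the number of samples")
  TRUE
})

#' Construct a Track
#'
#' @param t time grid in seconds (uniform, strictly increasing).
#' @param x,y coordinates in mm.
#' @param heading optional heading in radians.
#' @return A [Track-class] object.
#' @examples
#' tr <- Track(t = seq(0, 1, by = 1/30), x = rnorm(31), y = rnorm(31))
#' nSamples(tr)
#' @export
Track <- function(t, x, y, heading = numeric()) {
  new("Track", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      heading = as.numeric(heading))
}

#' @describeIn Track Number of samples.
#' @param object,x a `Track`.
#' @export
nSamples <- function(object) length(object@t)

#' @describeIn Track Sampling interval (s).
#' @export
sampleInterval <- function(object) {
  if (nSamples(object) < 2) stop("track too short to define a sampling interval")
  stats::median(diff(object@t))
}

#' @describeIn Track Coerce to data.frame with columns t_s, x_mm, y_mm
#'   (and heading_rad when present).
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "Track", function(x, ...) {
  d <- data.frame(t_s = x@t, x_mm = x@x, y_mm = x@y)
  if (length(x@heading)) d$heading_rad <- x@heading
  d
})

setMethod("show", "Track", function(object) {
  n <- nSamples(object)
  cat("Track with", n, "samples")
  if (n >= 2) cat(sprintf(" (%.1f s at %.1f Hz)", diff(range(object@t)),
                          1 / sampleInterval(object)))
  cat(if (length(object@heading)) ", with heading\n" else "\n")
})

#' StimulusSpec: parametric description of a virtual-conspecific stimulus
#'
#' Captures the dot stimuli used for behaviour and imaging: a dot moving
#' along a circular, trefoil or naturalistic path in discrete bout-like
#' jumps or continuously, plus looming/grating/whole-field control
#' records. A bout frequency equal to the display frame rate encodes
#' continuous motion.
#'
#' @slot kind one of circular_dot, trefoil_dot, naturalistic_dot,
#'   looming, grating, wholefield.
#' @slot dotDiameter dot diameter (mm).
#' @slot avgSpeed average speed along the path (mm/s).
#' @slot boutFreq bout frequency (Hz); equal to `frameRate` means continuous.
#' @slot profile instant_jump, gaussian or continuous.
#' @slot peakAccel peak acceleration of the Gaussian bout profile (m/s^2).
#' @slot radius path radius (mm); for trefoil paths the scale.
#' @slot frameRate display update rate (Hz); 30 on the behaviour rig, 60
#'   on the imaging rig.
#' @slot duration stimulus duration (s).
#' @slot direction cw or ccw.
#' @slot startPhase starting phase on the path (rad).
#' @export
setClass("StimulusSpec", representation(
  kind = "character", dotDiameter = "numeric", avgSpeed = "numeric",
  boutFreq = "numeric", profile = "character", peakAccel = "numeric",
  radius = "numeric", frameRate = "numeric", duration = "numeric",
  direction = "character", startPhase = "numeric"))

setValidity("StimulusSpec", function(object) {
  kinds <- c("circular_dot", "trefoil_dot", "naturalistic_dot", "looming",
             "grating", "wholefield")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (!object@profile %in% c("instant_jump", "gaussian", "continuous"))
    return("profile must be instant_jump, gaussian or continuous")
  if (object@avgSpeed < 0) return("avgSpeed must be >= 0")
  if (object@boutFreq > object@frameRate + 1e-9)
    return("boutFreq cannot exceed the display frame rate")
  if (!object@direction %in% c("cw", "ccw"))
    return("direction must be cw or ccw")
  if (object@radius <= 0) return("radius must be positive")
  TRUE
})

#' Construct a StimulusSpec
#'
#' Defaults correspond to the standard imaging-rig dot: 4 mm dot at
#' 5 mm/s on an 18 mm circle, 22.6 s presentation, 60 Hz display.
#'
#' @param kind stimulus kind (see [StimulusSpec-class]).
#' @param dotDiameter dot diameter, mm.
#' @param avgSpeed average speed, mm/s.
#' @param boutFreq bout frequency, Hz (equal to `frameRate` encodes
#'   continuous motion).
#' @param profile speed profile within a bout.
#' @param peakAccel peak acceleration for the gaussian profile, m/s^2.
#' @param radius path radius (or trefoil scale), mm.
#' @param frameRate display update rate, Hz.
#' @param duration stimulus duration, s.
#' @param direction cw or ccw.
#' @param startPhase starting phase, rad.
#' @return A [StimulusSpec-class] object.
#' @examples
#' stimulusSpec(boutFreq = 1.5)
#' @export
stimulusSpec <- function(kind = "circular_dot", dotDiameter = 4,
                         avgSpeed = 5, boutFreq = 60,
                         profile = c("instant_jump", "gaussian",
                                     "continuous"),
                         peakAccel = 0, radius = 18, frameRate = 60,
                         duration = 22.6, direction = "ccw",
                         startPhase = 0) {
  profile <- match.arg(profile)
  if (boutFreq >= frameRate) profile <- "continuous"
  new("StimulusSpec", kind = kind, dotDiameter = dotDiameter,
      avgSpeed = avgSpeed, boutFreq = boutFreq, profile = profile,
      peakAccel = peakAccel, radius = radius, frameRate = frameRate,
      duration = duration, direction = direction, startPhase = startPhase)
}

setMethod("show", "StimulusSpec", function(object) {
  cat(sprintf("StimulusSpec: %s, %.3g mm dot, %.3g mm/s, %.3g Hz (%s), r = %.3g mm, %.4g s\n",
              object@kind, object@dotDiameter, object@avgSpeed,
              object@boutFreq, object@profile, object@radius,
              object@duration))
})

#' NeighborMap: egocentric neighbour-density histogram
#'
#' Binned 2-D histogram of partner positions in the focal animal's
#' reference frame (focal at the centre, heading up along +y). Row index
#' runs along egocentric x (rightward), column index along egocentric y.
#'
#' @slot counts numeric matrix of bin counts (or probabilities when
#'   normalized).
#' @slot binSize bin size, mm.
#' @slot extent full map side length, mm.
#' @slot normalized logical; TRUE when counts sum to 1.
#' @slot nSamples number of samples retained in the map.
#' @slot nClipped number of samples outside the extent (discarded).
#' @export
setClass("NeighborMap", representation(
  counts = "matrix", binSize = "numeric", extent = "numeric",
  normalized = "logical", nSamples = "numeric", nClipped = "numeric"))

setValidity("NeighborMap", function(object) {
  tot <- sum(object@counts)
  if (object@normalized) {
    if (object@nSamples > 0 && abs(tot - 1) > 1e-8)
      return("normalized map must sum to 1")
  } else if (abs(tot - object@nSamples) > 1e-8) {
    return("count sum must equal the number of retained samples")
  }
  TRUE
})

setMethod("show", "NeighborMap", function(object) {
  cat(sprintf("NeighborMap: %g x %g mm at %g mm bins, %d samples (%d clipped)%s\n",
              object@extent, object@extent, object@binSize,
              as.integer(object@nSamples), as.integer(object@nClipped),
              if (object@normalized) ", normalized" else ""))
})

#' @describeIn NeighborMap Bin-centre coordinates (mm) along one axis.
#' @param object a `NeighborMap`.
#' @export
binCenters <- function(object) {
  nb <- nrow(object@counts)
  (seq_len(nb) - 0.5) * object@binSize - object@extent / 2
}

#' AttractionResult: time-shift-null attraction statistics
#'
#' @slot iadReal per-chunk mean inter-animal (or animal-dot) distance, mm.
#' @slot iadShifted per-chunk mean distance over time-shifted null
#'   trajectories, mm.
#' @slot attraction per-chunk attraction, (IADs - IADr)/IADs.
#' @slot chunkSeconds chunk length, s.
#' @export
setClass("AttractionResult", representation(
  iadReal = "numeric", iadShifted = "numeric", attraction = "numeric",
  chunkSeconds = "numeric"))

setMethod("show", "AttractionResult", function(object) {
  cat(sprintf("AttractionResult: %d chunks of %g s, mean attraction %.3f\n",
              length(object@attraction), object@chunkSeconds,
              mean(object@attraction)))
})

#' @describeIn AttractionResult Per-animal attraction value: the mean of
#'   the per-chunk attraction scores.
#' @param object an `AttractionResult`.
#' @export
meanAttraction <- function(object) mean(object@attraction)

#' RepulsionResult: central density-deficit score of a neighbour map
#'
#' @slot scan averaged radial line scan: data.frame with columns r_mm and
#'   density.
#' @slot rPeak radius of maximum neighbour density, mm.
#' @slot score repulsion score (area above the averaged scan left of the
#'   peak, divided by the full 29 mm scan length).
#' @slot smoothed the Gaussian-smoothed map the scans were read from.
#' @export
setClass("RepulsionResult", representation(
  scan = "data.frame", rPeak = "numeric", score = "numeric",
  smoothed = "matrix"))

setMethod("show", "RepulsionResult", function(object) {
  cat(sprintf("RepulsionResult: r_peak = %.2f mm, repulsion score = %.4g\n",
              object@rPeak, object@score))
})

#' ResponseTable: per-ROI mean dF/F responses per stimulus
#'
#' One row per ROI, one column per stimulus; the substrate of the bout
#' preference index. Column metadata carries the stimulus parameters.
#'
#' @slot values numeric matrix, ROI x stimulus mean dF/F.
#' @slot stimInfo data.frame with one row per column of `values`; must
#'   contain at least `label` and `freq_hz`.
#' @export
setClass("ResponseTable", representation(values = "matrix",
                                         stimInfo = "data.frame"))

setValidity("ResponseTable", function(object) {
  if (ncol(object@values) != nrow(object@stimInfo))
    return("stimInfo must have one row per stimulus column")
  if (!all(c("label", "freq_hz") %in% names(object@stimInfo)))
    return("stimInfo needs columns label and freq_hz")
  TRUE
})

#' Construct a ResponseTable
#' @param values ROI x stimulus matrix of mean dF/F values.
#' @param stimInfo data.frame of per-stimulus metadata (label, freq_hz, ...).
#' @return A [ResponseTable-class].
#' @export
ResponseTable <- function(values, stimInfo) {
  values <- as.matrix(values)
  colnames(values) <- as.character(stimInfo$label)
  new("ResponseTable", values = values, stimInfo = stimInfo)
}

#' @describeIn ResponseTable The ROI x stimulus value matrix.
#' @param object a `ResponseTable`.
#' @export
responseValues <- function(object) object@values

#' @describeIn ResponseTable Per-stimulus metadata.
#' @export
stimInfo <- function(object) object@stimInfo

setMethod("show", "ResponseTable", function(object) {
  cat(sprintf("ResponseTable: %d ROIs x %d stimuli (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(utils::head(object@stimInfo$label, 5), collapse = ", ")))
})

#' @describeIn ResponseTable Subset ROIs (rows) and/or stimuli (columns).
#' @param x a `ResponseTable`.
#' @param i,j row/column indices.
#' @param drop ignored.
#' @export
setMethod("[", "ResponseTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  s <- x@stimInfo
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) { v <- v[, j, drop = FALSE]; s <- s[j, , drop = FALSE] }
  new("ResponseTable", values = v, stimInfo = s)
})

#' DensityField: voxelized cell-density estimate
#'
#' A kernel-density estimate of cell coordinates evaluated on a regular
#' voxel grid in reference-brain space, masked to the brain and scaled so
#' that the density integrates to the total cell count. Density values
#' are per cubic micrometre.
#'
#' @slot values 3-D numeric array, density per um^3.
#' @slot spacing voxel spacing, um (length 3).
#' @slot origin coordinate of the centre of voxel (1,1,1), um.
#' @slot mask logical array, TRUE inside the brain.
#' @slot nPoints number of cells the field integrates to.
#' @export
setClass("DensityField", representation(
  values = "array", spacing = "numeric", origin = "numeric",
  mask = "array", nPoints = "numeric"))

setValidity("DensityField", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("mask and values must share a grid")
  if (any(object@values[!object@mask] != 0))
    return("density must be zero outside the brain mask")
  TRUE
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField: %s voxels at %s um, %g cells\n",
              paste(dim(object@values), collapse = " x "),
              paste(object@spacing, collapse = " x "), object@nPoints))
})

#' @describeIn DensityField Voxel volume in um^3.
#' @param object a `DensityField`.
#' @export
voxelVolume <- function(object) prod(object@spacing)

#' VolumePair: a registered two-channel volume for one animal
#'
#' Activity (c-fos HCR) and reference (elavl3 HCR) channels on the same
#' voxel grid, with the animal's stimulus condition.
#'
#' @slot activity,reference 3-D numeric arrays, same dimensions.
#' @slot animal animal identifier.
#' @slot condition condition label (e.g. no-stimulus, continuous,
#'   bout-like, conspecific).
#' @export
setClass("VolumePair", representation(
  activity = "array", reference = "array", animal = "character",
  condition = "character"))

setValidity("VolumePair", function(object) {
  if (!identical(dim(object@activity), dim(object@reference)))
    return("activity and reference must have identical dimensions")
  if (min(object@activity) < 0 || min(object@reference) < 0)
    return("intensities must be non-negative")
  TRUE
})

setMethod("show", "VolumePair", function(object) {
  cat(sprintf("VolumePair '%s' (%s): %s voxels\n", object@animal,
              object@condition, paste(dim(object@activity), collapse = " x ")))
})

#' EffectMatrix: cluster x condition effect sizes with test results
#'
#' Cohen's d of bulk normalized activity in each cluster for each
#' stimulus condition against the no-stimulus baseline, with two-tailed
#' t-test p values and Bonferroni-corrected significance tiers
#' (alpha/3 within each cluster). Negative d means a signal below the
#' baseline condition.
#'
#' @slot d numeric matrix, cluster x condition Cohen's d.
#' @slot p numeric matrix of two-tailed p values.
#' @slot tier character matrix of significance marks ("", "*", "**",
#'   "***" at p < 0.05/3, 0.01/3, 0.001/3).
#' @slot baseline baseline condition label.
#' @slot nPerGroup named integer vector of group sizes.
#' @export
setClass("EffectMatrix", representation(
  d = "matrix", p = "matrix", tier = "matrix", baseline = "character",
  nPerGroup = "integer"))

setMethod("show", "EffectMatrix", function(object) {
  cat(sprintf("EffectMatrix: %d clusters x %d conditions vs '%s'\n",
              nrow(object@d), ncol(object@d), object@baseline))
})

#' @describeIn EffectMatrix Cohen's d matrix.
#' @param object an `EffectMatrix`.
#' @export
effectSizes <- function(object) object@d

#' @describeIn EffectMatrix p-value matrix.
#' @export
pValues <- function(object) object@p

#' @describeIn EffectMatrix significance-tier matrix.
#' @export
significanceTiers <- function(object) object@tier
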