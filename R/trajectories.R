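#' Generate a dot moving on a circular path
#'
#' Positions of a dot on a circle of the spec's radius, sampled at the
#' display frame rate. With the `continuous` profile the dot advances
#' every frame; with `instant_jump` it advances one arc step of
#' `avgSpeed / boutFreq` at every bout boundary and holds position in
#' between. The time-averaged speed along the arc equals the configured
#' average speed, so one revolution takes `2*pi*r/v` seconds
#' independently of the bout frequency (22.6 s at 5 mm/s and r = 18 mm).
#'
#' @param spec a [StimulusSpec-class] with `kind = "circular_dot"`.
#' @return A [Track-class]; heading holds the path tangent.
#' @examples
#' tr <- makeCircularDotSeries(stimulusSpec(boutFreq = 1.5, duration = 22.6))
#' @export
makeCircularDotSeries <- function(spec) {
  stopifnot(is(spec, "StimulusSpec"))
  if (spec@kind != "circular_dot") stop("spec kind must be circular_dot")
  n <- floor(spec@duration * spec@frameRate)
  if (spec@profile == "instant_jump" && spec@duration < 1 / spec@boutFreq)
    stop("duration shorter than one bout update: empty series")
  if (n < 1) stop("duration shorter than one display frame: empty series")
  t <- (seq_len(n) - 1) / spec@frameRate
  s <- if (spec@direction == "cw") -1 else 1
  phi <- if (spec@profile == "continuous") {
    spec@startPhase + s * (spec@avgSpeed / spec@radius) * t
  } else {
    # arc advance of v/f once per bout period
    k <- floor(t * spec@boutFreq + 1e-9)
    spec@startPhase + s * (spec@avgSpeed / (spec@radius * spec@boutFreq)) * k
  }
  Track(t, spec@radius * cos(phi), spec@radius * sin(phi),
        heading = phi + s * pi / 2)
}

#' Gaussian speed profile of bout-like motion
#'
#' Models each bout as a Gaussian speed pulse repeated at the bout
#' frequency, with the pulse width set so that the maximum absolute
#' acceleration of the profile equals `peakAccelMS2` and the amplitude
#' normalized so that the mean speed over the period equals
#' `avgSpeedMmS`. Pulses are periodically wrapped, so very low peak
#' accelerations smoothly degenerate towards constant-speed motion, and
#' `peakAccelMS2 = 0` returns exactly constant speed.
#'
#' If the required pulse is narrower than one display frame the width is
#' clipped to one frame interval with a warning: the requested peak
#' acceleration is not realizable at that frame rate.
#'
#' @param peakAccelMS2 requested peak acceleration, m/s^2 (>= 0).
#' @param avgSpeedMmS average speed over each bout period, mm/s.
#' @param boutFreqHz bout frequency, Hz.
#' @param frameRateHz sampling rate of the returned series, Hz.
#' @param durationS length of the returned series, s (default one bout
#'   period).
#' @return data.frame with columns t_s and speed_mm_s; the realized pulse
#'   width (s) is attached as attribute `sigma_s`.
#' @examples
#' p <- gaussianBoutProfile(12, 5, 1.5, 1000)
#' mean(p$speed_mm_s)  # 5
#' @export
gaussianBoutProfile <- function(peakAccelMS2, avgSpeedMmS = 5,
                                boutFreqHz = 1.5, frameRateHz = 60,
                                durationS = 1 / boutFreqHz) {
  if (peakAccelMS2 < 0) stop("peak acceleration must be non-negative")
  stopifnot(avgSpeedMmS > 0, boutFreqHz > 0, frameRateHz > 0)
  T <- 1 / boutFreqHz
  dt <- 1 / frameRateHz
  n <- max(1L, round(durationS * frameRateHz))
  t <- (seq_len(n) - 1) * dt
  if (peakAccelMS2 == 0) {
    out <- data.frame(t_s = t, speed_mm_s = rep(avgSpeedMmS, n))
    attr(out, "sigma_s") <- Inf
    return(out)
  }
  aMm <- peakAccelMS2 * 1000  # mm/s^2
  profileAt <- function(tt, sigma) {
    # wrapped sum of Gaussian pulses centred at T/2 + k*T
    K <- ceiling(6 * sigma / T) + 1
    A <- avgSpeedMmS * T / (sigma * sqrt(2 * pi))
    v <- 0
    for (k in -K:K) v <- v + A * exp(-((tt - T / 2 - k * T)^2) / (2 * sigma^2))
    v
  }
  maxAccel <- function(sigma) {
    tt <- seq(0, T, length.out = 4001)
    v <- profileAt(tt, sigma)
    max(abs(diff(v))) / (tt[2] - tt[1])
  }
  # peak acceleration decreases monotonically with pulse width
  lo <- T * 1e-4
  hi <- 10 * T
  if (maxAccel(lo) < aMm) {
    sigma <- lo
  } else {
    sigma <- uniroot(function(ls) maxAccel(exp(ls)) - aMm,
                     lower = log(lo), upper = log(hi), tol = 1e-12)$root
    sigma <- exp(sigma)
  }
  if (sigma < dt) {
    warning("requested peak acceleration not achievable at this frame rate; ",
            "pulse width clipped to one frame interval")
    sigma <- dt
  }
  v <- profileAt(t %% T, sigma)
  v <- v * avgSpeedMmS / mean(v)  # exact mean-speed normalization
  out <- data.frame(t_s = t, speed_mm_s = v)
  attr(out, "sigma_s") <- sigma
  out
}

# trefoil curve (planar three-lobed rose-like closed curve), unit scale
.trefoilXY <- function(u, scaleMm) {
  cbind(x = scaleMm * (sin(u) + 2 * sin(2 * u)) / 3,
        y = scaleMm * (cos(u) - 2 * cos(2 * u)) / 3)
}

# dense arc-length table for the trefoil, one full circuit
.trefoilArcTable <- function(scaleMm, nDense = 20000L) {
  u <- seq(0, 2 * pi, length.out = nDense + 1L)
  p <- .trefoilXY(u, scaleMm)
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  list(u = u, p = p, s = c(0, cumsum(seg)), L = sum(seg))
}

#' Generate a dot moving on a synthetic trefoil path
#'
#' Arc-length-uniform traversal of a smooth, closed, three-lobed curve
#' `(x, y) = s * (sin t + 2 sin 2t, cos t - 2 cos 2t) / 3` whose extreme
#' radius equals `scaleMm`. With the continuous profile the dot advances
#' an equal arc every display frame; with `instant_jump` it advances in
#' discrete jumps at the bout frequency, each jump covering a straight-
#' line displacement of `avgSpeed / boutFreq`, so the realized mean
#' frame-to-frame speed equals the configured average speed.
#'
#' @param avgSpeedMmS average speed, mm/s.
#' @param boutFreqHz bout frequency, Hz (used by `instant_jump`).
#' @param scaleMm maximum path radius, mm.
#' @param durationS duration, s.
#' @param frameRateHz display frame rate, Hz.
#' @param profile `"instant_jump"` or `"continuous"`.
#' @return A [Track-class].
#' @export
makeTrefoilSeries <- function(avgSpeedMmS = 5, boutFreqHz = 1.5,
                              scaleMm = 18, durationS = 60,
                              frameRateHz = 60,
                              profile = c("instant_jump", "continuous")) {
  profile <- match.arg(profile)
  stopifnot(avgSpeedMmS > 0, scaleMm > 0, durationS > 0)
  tab <- .trefoilArcTable(scaleMm)
  posAtArc <- function(s) {
    s <- s %% tab$L
    u <- approx(tab$s, tab$u, xout = s, rule = 2)$y
    .trefoilXY(u, scaleMm)
  }
  n <- floor(durationS * frameRateHz)
  t <- (seq_len(n) - 1) / frameRateHz
  if (profile == "continuous") {
    p <- posAtArc(avgSpeedMmS * t)
    return(Track(t, p[, "x"], p[, "y"]))
  }
  # instant jumps: step forward along the curve until the straight-line
  # displacement equals the per-bout distance v/f
  d <- avgSpeedMmS / boutFreqHz
  nBouts <- floor(durationS * boutFreqHz) + 1L
  arcPos <- numeric(nBouts)
  arcPos[1] <- 0
  for (b in seq_len(nBouts - 1L)) {
    p0 <- posAtArc(arcPos[b])
    chord <- function(ds) sqrt(sum((posAtArc(arcPos[b] + ds) - p0)^2)) - d
    # a chord is never longer than its arc, so the root lies in [d, 2d]
    hi <- d
    while (chord(hi) < 0) hi <- hi * 1.5
    arcPos[b + 1] <- arcPos[b] + uniroot(chord, lower = d * 0.99, upper = hi,
                                         tol = 1e-10)$root
  }
  k <- floor(t * boutFreqHz + 1e-9) + 1L
  p <- posAtArc(arcPos[pmin(k, nBouts)])
  Track(t, p[, "x"], p[, "y"])
}

#' Smooth a trajectory with a normalized Hamming window
#'
#' Convolves each coordinate with a unit-sum Hamming window in `valid`
#' mode (no edge padding), the smoothing applied to recorded conspecific
#' trajectories before replaying them as naturalistic dot stimuli. The
#' output has `n - windowLen + 1` samples; heading, if present, is
#' dropped (recompute it from displacement).
#'
#' @param track a [Track-class] with more than `windowLen` samples.
#' @param windowLen Hamming window length (default 20).
#' @return A smoothed [Track-class].
#' @export
smoothTrajectory <- function(track, windowLen = 20L) {
  stopifnot(is(track, "Track"))
  n <- nSamples(track)
  if (n <= windowLen) stop("track must be longer than the smoothing window")
  w <- as.numeric(signal::hamming(windowLen))
  w <- w / sum(w)
  xs <- convolve(track@x, rev(w), type = "filter")
  ys <- convolve(track@y, rev(w), type = "filter")
  # centre of each window
  i0 <- (windowLen + 1) / 2
  ts <- track@t[1] + (i0 - 1 + seq_along(xs) - 1) * sampleInterval(track)
  Track(ts, xs, ys)
}

#' Angular-size time course of a looming disc
#'
#' Monotone expansion of the subtended angle from `startDeg` to `endDeg`
#' over `expandMs` (0.6 deg to 110 deg in 83 ms for the imaging-rig
#' loom; the behavioural variant expands within 500 ms). The disc centre
#' offset (5 mm to the left or right of the animal in the behavioural
#' assay) is carried as metadata.
#'
#' @param startDeg initial angular size, deg.
#' @param endDeg final angular size, deg (>= `startDeg`).
#' @param expandMs expansion time, ms.
#' @param offsetMm lateral offset of the disc centre, mm (sign = side).
#' @param sampleRateHz sampling rate of the series, Hz.
#' @param holdMs time the final size is held after expansion, ms.
#' @return data.frame with columns t_ms and angle_deg; `offset_mm`
#'   attached as an attribute.
#' @examples
#' lo <- makeLoomingSeries(0.6, 110, 83)
#' @export
makeLoomingSeries <- function(startDeg = 0.6, endDeg = 110, expandMs = 83,
                              offsetMm = 5, sampleRateHz = 1000,
                              holdMs = 0) {
  if (endDeg < startDeg) stop("final size must not be smaller than initial size")
  tMs <- seq(0, expandMs + holdMs, by = 1000 / sampleRateHz)
  ang <- if (expandMs > 0) {
    startDeg + (endDeg - startDeg) * pmin(tMs / expandMs, 1)
  } else rep(endDeg, length(tMs))
  if (startDeg == endDeg) ang <- rep(startDeg, length(tMs))
  out <- data.frame(t_ms = tMs, angle_deg = ang)
  attr(out, "offset_mm") <- offsetMm
  out
}
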