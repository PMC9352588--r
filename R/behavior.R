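.checkAligned <- function(focal, neighbor) {
  if (nSamples(focal) != nSamples(neighbor) ||
      max(abs(focal@t - neighbor@t)) > 1e-6)
    stop("tracks are not time-aligned on the same grid")
}

.pairDistance <- function(focal, neighbor)
  sqrt((focal@x - neighbor@x)^2 + (focal@y - neighbor@y)^2)

.chunkIndex <- function(n, framesPerChunk) {
  nChunks <- n %/% framesPerChunk
  if (nChunks < 1) stop("tracks shorter than one chunk")
  lapply(seq_len(nChunks), function(k)
    ((k - 1) * framesPerChunk + 1):(k * framesPerChunk))
}

#' Real inter-animal distance per chunk (IADr)
#'
#' Mean Euclidean distance between a focal animal and its neighbour (or
#' a virtual dot) in non-overlapping 5 min chunks; a trailing partial
#' chunk is dropped.
#'
#' @param focal,neighbor time-aligned [Track-class] objects.
#' @param chunkS chunk length, s (default 300).
#' @return Numeric vector of per-chunk mean distances, mm.
#' @export
chunkedIAD <- function(focal, neighbor, chunkS = 300) {
  .checkAligned(focal, neighbor)
  d <- .pairDistance(focal, neighbor)
  fpc <- round(chunkS / sampleInterval(focal))
  vapply(.chunkIndex(length(d), fpc), function(i) mean(d[i]), numeric(1))
}

#' Time-shift-null inter-animal distance per chunk (IADs)
#'
#' For each chunk the neighbour trajectory is cyclically time-shifted
#' within the chunk `nShifts` times (shifts evenly spaced at
#' `k * chunk / (nShifts + 1)`, k = 1..nShifts, so the smallest shift is
#' about 27 s for a 5 min chunk) and the mean distance is recomputed;
#' the per-chunk IADs is the mean over shifts. This breaks the temporal
#' correlation between the trajectories while preserving each animal's
#' spatial occupancy, giving the null distance against which attraction
#' is measured.
#'
#' @inheritParams chunkedIAD
#' @param nShifts number of cyclic time shifts (default 10).
#' @return Numeric vector of per-chunk shifted mean distances, mm.
#' @export
shiftedIAD <- function(focal, neighbor, chunkS = 300, nShifts = 10) {
  .checkAligned(focal, neighbor)
  fpc <- round(chunkS / sampleInterval(focal))
  if (fpc < nShifts + 1) stop("chunk shorter than the minimum usable shift")
  fx <- focal@x; fy <- focal@y; nx <- neighbor@x; ny <- neighbor@y
  shifts <- round(seq_len(nShifts) * fpc / (nShifts + 1))
  vapply(.chunkIndex(length(fx), fpc), function(i) {
    mean(vapply(shifts, function(s) {
      j <- i[((seq_along(i) - 1 + s) %% length(i)) + 1]
      mean(sqrt((fx[i] - nx[j])^2 + (fy[i] - ny[j])^2))
    }, numeric(1)))
  }, numeric(1))
}

#' Attraction score from real and shifted distances
#'
#' `(IADs - IADr) / IADs` per chunk: 1 for perfect following, 0 when the
#' real distance is no smaller than the time-shift null, negative for
#' avoidance.
#'
#' @param iadReal per-chunk real mean distances (IADr), mm.
#' @param iadShifted per-chunk shifted mean distances (IADs), mm.
#' @return Per-chunk attraction values.
#' @examples
#' attractionScore(20, 25)  # 0.2
#' @export
attractionScore <- function(iadReal, iadShifted) {
  if (any(iadShifted == 0))
    stop("IADs is zero (permanently coincident trajectories): attraction undefined")
  (iadShifted - iadReal) / iadShifted
}

#' Full attraction analysis of a dyad
#'
#' Convenience wrapper running [chunkedIAD()], [shiftedIAD()] and
#' [attractionScore()] on a pair of aligned tracks.
#'
#' @inheritParams shiftedIAD
#' @return An [AttractionResult-class]; the per-animal attraction value
#'   is [meanAttraction()] (mean over chunks).
#' @export
attractionAnalysis <- function(focal, neighbor, chunkS = 300, nShifts = 10) {
  r <- chunkedIAD(focal, neighbor, chunkS)
  s <- shiftedIAD(focal, neighbor, chunkS, nShifts)
  new("AttractionResult", iadReal = r, iadShifted = s,
      attraction = attractionScore(r, s), chunkSeconds = chunkS)
}

#' Egocentric neighbour-density map
#'
#' Transforms the neighbour position time series into the focal animal's
#' reference frame (focal at the centre, heading up along +y) and
#' accumulates a binned 2-D histogram over a square map of side
#' `extentMm`. When the focal track has no heading channel, heading is
#' derived from frame-to-frame displacement; samples in which the focal
#' animal moved less than `minStepMm` are skipped because their heading
#' is undefined. Samples falling outside the map extent are discarded
#' but counted in the clipped tally.
#'
#' @inheritParams chunkedIAD
#' @param extentMm side length of the square map, mm (default 60).
#' @param binMm bin size, mm (default 1, fine enough to resolve the 3 mm
#'   smoothing kernel used by [repulsionScore()]).
#' @param normalize divide counts by their sum.
#' @param minStepMm displacement below which a derived heading is
#'   considered undefined, mm per frame.
#' @return A [NeighborMap-class].
#' @export
neighborDensityMap <- function(focal, neighbor, extentMm = 60, binMm = 1,
                               normalize = FALSE, minStepMm = 0.1) {
  .checkAligned(focal, neighbor)
  n <- nSamples(focal)
  if (length(focal@heading)) {
    th <- focal@heading
    keep <- rep(TRUE, n)
  } else {
    dx <- diff(focal@x); dy <- diff(focal@y)
    th <- c(atan2(dy, dx), NA_real_)
    keep <- c(sqrt(dx^2 + dy^2) >= minStepMm, FALSE)
  }
  rx <- neighbor@x - focal@x
  ry <- neighbor@y - focal@y
  # egocentric frame: +y = forward (heading), +x = rightward
  # snap numerical dust so samples on exact bin boundaries (e.g. a
  # neighbour dead ahead) bin deterministically across headings
  egoY <- round(rx * cos(th) + ry * sin(th), 9)
  egoX <- round(rx * sin(th) - ry * cos(th), 9)
  egoX <- egoX[keep]; egoY <- egoY[keep]
  nb <- round(extentMm / binMm)
  half <- extentMm / 2
  ix <- floor((egoX + half) / binMm) + 1L
  iy <- floor((egoY + half) / binMm) + 1L
  inside <- ix >= 1L & ix <= nb & iy >= 1L & iy <= nb
  counts <- matrix(0, nb, nb)
  if (any(inside)) {
    tab <- table(factor(ix[inside], levels = seq_len(nb)),
                 factor(iy[inside], levels = seq_len(nb)))
    counts <- matrix(as.numeric(tab), nb, nb)
  }
  nIn <- sum(inside)
  if (normalize && nIn > 0) counts <- counts / nIn
  new("NeighborMap", counts = counts, binSize = binMm, extent = extentMm,
      normalized = normalize, nSamples = as.numeric(nIn),
      nClipped = as.numeric(sum(!inside)))
}

# bilinear interpolation of a matrix indexed by bin-centre coordinates
.bilinear <- function(m, centers, px, py) {
  bin <- centers[2] - centers[1]
  gx <- (px - centers[1]) / bin + 1
  gy <- (py - centers[1]) / bin + 1
  nb <- nrow(m)
  x0 <- pmin(pmax(floor(gx), 1), nb - 1); y0 <- pmin(pmax(floor(gy), 1), nb - 1)
  fx <- pmin(pmax(gx - x0, 0), 1); fy <- pmin(pmax(gy - y0, 0), 1)
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Repulsion score of a neighbour-density map
#'
#' Quantifies the central density deficit ("reduction in attraction at
#' the centre") of a neighbour map. The map is Gaussian-smoothed
#' (sigma = 3 mm), 24 equally spaced radial line scans of 5 mm width
#' (five parallel rays spanning the width, bilinear interpolation) are
#' taken from the centre out to 29 mm and averaged; the repulsion score
#' is the area between the scan's peak level and the scan at radii
#' smaller than the density peak, divided by the full 29 mm scan length.
#' A map whose density is maximal at the centre scores 0.
#'
#' @param map a [NeighborMap-class] with extent of at least 58 mm.
#' @param sigmaMm Gaussian smoothing sigma, mm.
#' @param nScans number of radial scans.
#' @param scanWidthMm width of each scan, mm.
#' @param maxRadiusMm scan length, mm.
#' @param drMm radial sampling step, mm.
#' @return A [RepulsionResult-class].
#' @export
repulsionScore <- function(map, sigmaMm = 3, nScans = 24,
                           scanWidthMm = 5, maxRadiusMm = 29, drMm = 0.25) {
  stopifnot(is(map, "NeighborMap"))
  if (map@extent < 2 * maxRadiusMm)
    stop("map extent must cover the full scan length")
  if (sum(map@counts) == 0) stop("empty map: no neighbour density")
  sigmaPx <- sigmaMm / map@binSize
  bw <- 2L * ceiling(3 * sigmaPx) + 1L
  brush <- EBImage::makeBrush(bw, shape = "gaussian", sigma = sigmaPx)
  sm <- EBImage::filter2(map@counts, brush, boundary = "replicate")
  sm <- matrix(pmax(as.numeric(sm), 0), nrow(map@counts), ncol(map@counts))
  centers <- binCenters(map)
  r <- seq(0, maxRadiusMm, by = drMm)
  offs <- seq(-scanWidthMm / 2, scanWidthMm / 2, length.out = 5)
  angles <- (seq_len(nScans) - 1) * 2 * pi / nScans
  acc <- numeric(length(r))
  for (a in angles) {
    ca <- cos(a); sa <- sin(a)
    for (o in offs) {
      px <- r * ca - o * sa
      py <- r * sa + o * ca
      acc <- acc + .bilinear(sm, centers, px, py)
    }
  }
  scan <- acc / (nScans * length(offs))
  iPeak <- which.max(scan)
  rPeak <- r[iPeak]
  score <- if (iPeak == 1) 0 else
    sum(scan[iPeak] - scan[seq_len(iPeak - 1)]) * drMm / maxRadiusMm
  new("RepulsionResult", scan = data.frame(r_mm = r, density = scan),
      rPeak = rPeak, score = score, smoothed = sm)
}

#' Detect swim bouts from a velocity time series
#'
#' Peak detection on the frame-to-frame speed: samples above a
#' noise-adaptive threshold (median + 3 MAD of the speed series) are
#' grouped into contiguous supra-threshold spans, each span counting as
#' one bout whose duration is the span length and whose time is the
#' speed peak within the span.
#'
#' @param track a [Track-class] sampled at 10 Hz or faster.
#' @return data.frame with columns t_s (peak time), duration_s and
#'   peak_speed_mm_s; zero rows when no bouts are found.
#' @export
detectBouts <- function(track) {
  stopifnot(is(track, "Track"))
  dt <- sampleInterval(track)
  if (dt > 0.1) stop("bout detection needs sampling at 10 Hz or faster")
  sp <- sqrt(diff(track@x)^2 + diff(track@y)^2) / dt
  thr <- median(sp) + 3 * mad(sp)
  above <- sp > thr
  if (!any(above))
    return(data.frame(t_s = numeric(), duration_s = numeric(),
                      peak_speed_mm_s = numeric()))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  t0 <- track@t[-length(track@t)]
  out <- lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    j <- i[which.max(sp[i])]
    data.frame(t_s = t0[j], duration_s = length(i) * dt,
               peak_speed_mm_s = sp[j])
  })
  do.call(rbind, out)
}

#' Looming escape fraction
#'
#' A trial counts as an escape when the animal moves more than twice as
#' far in the 1 s immediately after loom onset as in the 1.3 s before
#' it. Trials whose pre or post window is truncated by the recording
#' edges are excluded.
#'
#' @param track a [Track-class].
#' @param loomTimesS loom onset times, s.
#' @param postS post-loom window, s.
#' @param preS pre-loom window, s.
#' @return list with `fraction` (escapes / valid trials), `nTrials`
#'   (valid trials) and `escaped` (logical per valid trial).
#' @export
escapeFraction <- function(track, loomTimesS, postS = 1, preS = 1.3) {
  stopifnot(is(track, "Track"))
  step <- sqrt(diff(track@x)^2 + diff(track@y)^2)
  tStep <- track@t[-length(track@t)]  # step assigned to its start time
  pathLen <- function(a, b) sum(step[tStep >= a & tStep < b])
  t0 <- track@t[1]; t1 <- track@t[length(track@t)]
  res <- logical(0)
  for (tl in loomTimesS) {
    if (tl - preS < t0 || tl + postS > t1) next  # truncated window: excluded
    pre <- pathLen(tl - preS, tl)
    post <- pathLen(tl, tl + postS)
    res <- c(res, post > 2 * pre)
  }
  if (!length(res)) stop("no loom trial with complete pre/post windows")
  list(fraction = mean(res), nTrials = length(res), escaped = res)
}
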