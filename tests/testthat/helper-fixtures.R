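# shared fixtures and independent mini-oracles

# straight-line track at constant velocity
lineTrack <- function(durationS = 60, fps = 30, v = c(1, 0),
                      start = c(0, 0), headingFromV = FALSE) {
  t <- seq(0, durationS, by = 1 / fps)
  h <- if (headingFromV) rep(atan2(v[2], v[1]), length(t)) else numeric()
  Track(t, start[1] + v[1] * t, start[2] + v[2] * t, heading = h)
}

# track resting at a point
stillTrack <- function(durationS = 60, fps = 30, at = c(0, 0)) {
  t <- seq(0, durationS, by = 1 / fps)
  Track(t, rep(at[1], length(t)), rep(at[2], length(t)))
}

# rigid rotation + translation of a track (world-frame transform)
transformTrack <- function(tr, angle = 0, shift = c(0, 0)) {
  x <- tr@x * cos(angle) - tr@y * sin(angle) + shift[1]
  y <- tr@x * sin(angle) + tr@y * cos(angle) + shift[2]
  h <- if (length(tr@heading)) tr@heading + angle else numeric()
  Track(tr@t, x, y, heading = h)
}

# brute-force mean distance per chunk (independent of chunkedIAD)
loopIAD <- function(f, n, chunkS = 300) {
  dt <- median(diff(f@t))
  fpc <- round(chunkS / dt)
  nc <- length(f@t) %/% fpc
  out <- numeric(nc)
  for (k in seq_len(nc)) {
    s <- 0
    for (i in ((k - 1) * fpc + 1):(k * fpc))
      s <- s + sqrt((f@x[i] - n@x[i])^2 + (f@y[i] - n@y[i])^2)
    out[k] <- s / fpc
  }
  out
}

# independent Gaussian smoothing + azimuthal-average repulsion oracle
oracleRepulsion <- function(counts, binMm, extentMm, sigmaMm = 3,
                            maxR = 29, dr = 0.25) {
  nb <- nrow(counts)
  half <- ceiling(3 * sigmaMm / binMm)
  k1 <- dnorm(-half:half, sd = sigmaMm / binMm)
  k1 <- k1 / sum(k1)
  padConv <- function(m) {
    # separable convolution with edge replication, row then column
    m2 <- t(apply(m, 1, function(v) {
      vp <- c(rep(v[1], half), v, rep(v[nb], half))
      as.numeric(stats::filter(vp, k1, sides = 2))[(half + 1):(half + nb)]
    }))
    apply(m2, 2, function(v) {
      vp <- c(rep(v[1], half), v, rep(v[nb], half))
      as.numeric(stats::filter(vp, k1, sides = 2))[(half + 1):(half + nb)]
    })
  }
  sm <- padConv(counts)
  centers <- (seq_len(nb) - 0.5) * binMm - extentMm / 2
  r <- seq(0, maxR, by = dr)
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  scan <- vapply(r, function(rr) {
    px <- rr * cos(ang); py <- rr * sin(ang)
    ix <- round((px - centers[1]) / binMm) + 1
    iy <- round((py - centers[1]) / binMm) + 1
    ix <- pmin(pmax(ix, 1), nb); iy <- pmin(pmax(iy, 1), nb)
    mean(sm[cbind(ix, iy)])
  }, numeric(1))
  ip <- which.max(scan)
  list(rPeak = r[ip],
       score = if (ip == 1) 0 else
         sum(scan[ip] - scan[seq_len(ip - 1)]) * dr / maxR)
}

# small deterministic response table
toyResponseTable <- function(values, freqs) {
  ResponseTable(values,
                data.frame(label = sprintf("s%g", freqs), freq_hz = freqs))
}
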