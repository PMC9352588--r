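#' Angular size of a dot at a viewing distance
#'
#' Full subtended visual angle of a disc of the given diameter seen from
#' the path radius, `2 * atan((d/2) / r)` in degrees. A 4 mm dot on the
#' 18 mm circle subtends 12.7 deg.
#'
#' @param diameterMm dot diameter, mm (>= 0).
#' @param distanceMm viewing distance, mm (> 0).
#' @return Angular size in degrees.
#' @examples
#' angularSize(4, 18)   # 12.7
#' angularSize(8, 18)   # 25.1
#' @export
angularSize <- function(diameterMm, distanceMm) {
  if (any(distanceMm <= 0)) stop("viewing distance must be positive")
  if (any(diameterMm < 0)) stop("diameter must be non-negative")
  2 * atan((diameterMm / 2) / distanceMm) * 180 / pi
}

#' Angular speed of a dot on a circular path
#'
#' Arc-length conversion of a linear speed on a circle of the given
#' radius: `(v / r) * 180 / pi` degrees per second. 5 mm/s at 18 mm
#' radius is 15.9 deg/s.
#'
#' @param speedMmS linear speed along the path, mm/s.
#' @param radiusMm path radius, mm (> 0).
#' @return Angular speed, deg/s.
#' @examples
#' angularSpeed(5, 18)    # 15.9
#' angularSpeed(150, 18)  # 477.5
#' @export
angularSpeed <- function(speedMmS, radiusMm) {
  if (any(radiusMm <= 0)) stop("radius must be positive")
  (speedMmS / radiusMm) * 180 / pi
}

#' Angular acceleration of a dot on a circular path
#'
#' Arc-length conversion of a linear acceleration (m/s^2) at the given
#' path radius (mm): `(a * 1000 / r) * 180 / pi` deg/s^2. 12 m/s^2 at
#' 18 mm radius is 38.2e3 deg/s^2.
#'
#' @param accelMS2 linear acceleration, m/s^2.
#' @param radiusMm path radius, mm (> 0).
#' @return Angular acceleration, deg/s^2.
#' @export
angularAcceleration <- function(accelMS2, radiusMm) {
  if (any(radiusMm <= 0)) stop("radius must be positive")
  (accelMS2 * 1000 / radiusMm) * 180 / pi
}

#' Position-update interval of a bout-like stimulus
#'
#' Milliseconds between discrete position updates at a given bout
#' frequency, floored to an integer (1.5 Hz updates once every 666 ms).
#'
#' @param boutFreqHz bout frequency, Hz (> 0).
#' @return Integer update interval, ms.
#' @examples
#' boutUpdateIntervalMs(1.5)  # 666
#' @export
boutUpdateIntervalMs <- function(boutFreqHz) {
  if (any(boutFreqHz <= 0)) stop("bout frequency must be positive")
  as.integer(floor(1000 / boutFreqHz))
}

#' Acceleration of an instantaneous bout jump
#'
#' A bout-like dot advancing in discrete jumps covers `v / f` mm per
#' bout, executed within a single display frame, so the acceleration is
#' `d / dt^2` with `dt = 1/frameRate`, returned in m/s^2. At 5 mm/s,
#' 1.5 Hz and a 60 Hz display this is 12 m/s^2.
#'
#' @param avgSpeedMmS average speed, mm/s.
#' @param boutFreqHz bout frequency, Hz.
#' @param frameRateHz display update rate, Hz.
#' @return Acceleration, m/s^2.
#' @examples
#' boutJumpAcceleration(5, 1.5, 60)  # 12
#' @export
boutJumpAcceleration <- function(avgSpeedMmS, boutFreqHz, frameRateHz) {
  if (any(avgSpeedMmS <= 0) || any(boutFreqHz <= 0) || any(frameRateHz <= 0))
    stop("speed, bout frequency and frame rate must be positive")
  dMm <- avgSpeedMmS / boutFreqHz
  dt <- 1 / frameRateHz
  (dMm / 1000) / dt^2
}
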