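# dot trajectory generators: circular, gaussian-bout, trefoil, smoothing, looming

test_that("circular dot series has the documented revolution geometry", {
  # continuous motion: one full round in 2*pi*r/v seconds (22.6 s)
  tr <- makeCircularDotSeries(stimulusSpec(duration = 30))
  phi <- atan2(tr@y, tr@x)
  unwrapped <- cumsum(c(phi[1], atan2(sin(diff(phi)), cos(diff(phi)))))
  tRev <- tr@t[which(unwrapped - unwrapped[1] >= 2 * pi)[1]]
  expect_equal(round(tRev, 1), 22.6)
  expect_equal(tRev, 2 * pi * 18 / 5, tolerance = 2e-3)

  # instant jumps: arc length v/f per jump, floor(duration * f) updates
  sp <- stimulusSpec(boutFreq = 1.5, duration = 22.6)
  tj <- makeCircularDotSeries(sp)
  expect_true(all(abs(sqrt(tj@x^2 + tj@y^2) - 18) < 1e-9))
  moves <- which(abs(diff(tj@x)) + abs(diff(tj@y)) > 0)
  expect_equal(length(moves), floor(22.6 * 1.5))
  arc <- 18 * abs(atan2(sin(diff(atan2(tj@y, tj@x))[moves]),
                        cos(diff(atan2(tj@y, tj@x))[moves])))
  expect_equal(arc, rep(5 / 1.5, length(moves)), tolerance = 1e-9)

  # whole-period displacement bookkeeping: mean arc speed is exact
  i20 <- which(abs(tj@t - 20 / 1.5) < 1e-9)  # 20 bout periods in
  dphi <- diff(atan2(tj@y, tj@x))[seq_len(i20 - 1)]
  arcTot <- 18 * sum(abs(atan2(sin(dphi), cos(dphi))))
  expect_equal(arcTot / tj@t[i20], 5, tolerance = 1e-9)

  # direction flag and degenerate duration
  cw <- makeCircularDotSeries(stimulusSpec(duration = 5, direction = "cw"))
  ccw <- makeCircularDotSeries(stimulusSpec(duration = 5, direction = "ccw"))
  expect_equal(cw@x, ccw@x, tolerance = 1e-12)
  expect_equal(cw@y, -ccw@y, tolerance = 1e-12)
  expect_error(makeCircularDotSeries(stimulusSpec(boutFreq = 1.5,
                                                  duration = 0.5)),
               "empty series")
})

test_that("gaussian bout profile hits the requested mean speed and peak acceleration", {
  # zero peak acceleration degenerates to constant speed
  p0 <- gaussianBoutProfile(0, 5, 1.5, 60)
  expect_equal(unique(p0$speed_mm_s), 5)

  # normalization: mean speed within 0.1% for all printed accelerations
  for (a in c(0.02, 0.5, 2, 12)) {
    p <- gaussianBoutProfile(a, 5, 1.5, 2000)
    expect_equal(mean(p$speed_mm_s), 5, tolerance = 1e-3)
  }

  # dense-grid finite-difference acceleration within 2% of the request
  p12 <- gaussianBoutProfile(12, 5, 1.5, 10000)
  aHat <- max(abs(diff(p12$speed_mm_s))) * 10000 / 1000  # m/s^2
  expect_equal(aHat, 12, tolerance = 0.02)
  p05 <- gaussianBoutProfile(0.5, 5, 1.5, 10000)
  expect_equal(max(abs(diff(p05$speed_mm_s))) * 10, 0.5, tolerance = 0.02)

  # unachievable at a coarse display rate: clipped with a warning
  expect_warning(gaussianBoutProfile(12, 5, 1.5, 60), "clipped")
})

test_that("trefoil series is closed, bounded by its scale and speed-calibrated", {
  tf <- makeTrefoilSeries(5, 1.5, 18, durationS = 120, profile = "continuous")
  # extreme radius equals the scale
  expect_lt(max(sqrt(tf@x^2 + tf@y^2)), 18 + 1e-6)
  expect_gt(max(sqrt(tf@x^2 + tf@y^2)), 17.5)
  # closed path: the dot comes back to its start once per circuit
  d0 <- sqrt((tf@x - tf@x[1])^2 + (tf@y - tf@y[1])^2)
  expect_lt(min(d0[tf@t > 10]), 5 / 60 * 2)  # within two frame steps
  # continuous mean frame-to-frame speed within 0.5%
  step <- sqrt(diff(tf@x)^2 + diff(tf@y)^2)
  expect_equal(sum(step) / (length(step) / 60), 5, tolerance = 5e-3)

  # instant jumps: every jump displaces exactly v/f; speed over whole
  # bout periods is exact
  tj <- makeTrefoilSeries(5, 1.5, 18, durationS = 20)
  stepj <- sqrt(diff(tj@x)^2 + diff(tj@y)^2)
  jumps <- stepj[stepj > 0]
  expect_equal(jumps, rep(5 / 1.5, length(jumps)), tolerance = 1e-6)
  iEnd <- which(abs(tj@t - 28 / 1.5) < 1e-9)
  expect_equal(sum(stepj[seq_len(iEnd - 1)]) / tj@t[iEnd], 5,
               tolerance = 1e-6)
})

test_that("trajectory smoothing is a valid-mode unit-sum Hamming convolution", {
  # constant track: values unchanged, length n - windowLen + 1
  st <- stillTrack(durationS = 99 / 30, at = c(3, -2))  # 100 samples
  sm <- smoothTrajectory(st)
  expect_identical(nSamples(sm), 81L)
  expect_equal(sm@x, rep(3, 81))
  expect_equal(sm@y, rep(-2, 81))

  # direct convolution oracle on a noisy track + variance reduction
  set.seed(5)
  t <- seq(0, 9.99, by = 1 / 30)
  x <- sin(t) + rnorm(length(t), 0, 0.5)
  y <- cos(t) + rnorm(length(t), 0, 0.5)
  tr <- Track(t, x, y)
  sm2 <- smoothTrajectory(tr, windowLen = 20)
  w <- as.numeric(signal::hamming(20)); w <- w / sum(w)
  manual <- vapply(seq_len(length(x) - 19),
                   function(i) sum(x[i:(i + 19)] * w), numeric(1))
  expect_equal(sm2@x, manual, tolerance = 1e-12)
  expect_lt(var(sm2@x - sin(sm2@t)), var(x - sin(t)))
  expect_error(smoothTrajectory(stillTrack(0.5), 20), "longer")
})

test_that("looming series ramps monotonically between the stated sizes", {
  lo <- makeLoomingSeries(0.6, 110, 83)
  expect_equal(lo$angle_deg[1], 0.6)
  expect_equal(lo$angle_deg[which.min(abs(lo$t_ms - 83))], 110)
  expect_true(all(diff(lo$angle_deg) >= 0))
  # behavioural variant: 500 ms expansion, 5 mm offset
  lo5 <- makeLoomingSeries(0.6, 110, 500, offsetMm = -5)
  expect_equal(attr(lo5, "offset_mm"), -5)
  expect_equal(lo5$angle_deg[nrow(lo5)], 110)
  # degenerate constant disc
  cc <- makeLoomingSeries(10, 10, 100)
  expect_equal(unique(cc$angle_deg), 10)
  expect_error(makeLoomingSeries(110, 0.6, 83), "smaller")
})
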