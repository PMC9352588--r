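# dF/F epoching, response tables, BPI and tuning peaks

test_that("epoched dF/F uses the 5 s pre-onset baseline", {
  sch <- StimulusSchedule(data.frame(onset_s = 10, duration_s = 20,
                                     label = "a", freq_hz = 1.5))
  # constant trace: dF/F identically zero
  tsConst <- TraceSet(matrix(100, 1, 60), rateHz = 1)
  ep <- epochDFF(tsConst, sch)
  expect_equal(unique(as.numeric(ep$dff[[1]])), 0)

  # baseline 100, plateau 200 during the stimulus: dF/F = 1
  f <- matrix(100, 1, 60); f[1, 11:30] <- 200
  ep2 <- epochDFF(TraceSet(f, rateHz = 1), sch)
  expect_equal(unique(as.numeric(ep2$dff[[1]])), 1)

  # a near-zero baseline is flagged invalid rather than exploding
  f3 <- rbind(f, c(rep(0.001, 10), rep(100, 50)))
  ep3 <- epochDFF(TraceSet(f3, rateHz = 1), sch)
  expect_true(all(is.na(ep3$dff[[1]][2, ])))
  expect_false(anyNA(ep3$dff[[1]][1, ]))

  # a presentation whose window leaves the recording is an error
  schBad <- StimulusSchedule(data.frame(onset_s = 50, duration_s = 20,
                                        label = "a", freq_hz = 1.5))
  expect_error(epochDFF(TraceSet(matrix(100, 1, 60), 1), schBad), "outside")
})

test_that("noise-free synthetic responses match the closed-form kernel solution", {
  sch <- makeFrequencySchedule(nReps = 1)
  prm <- neuronSimParams(nNeurons = 4, selectiveFrac = 0.5,
                         responderFrac = 0.5, noiseSd = 0)
  sim <- genTraces(prm, sch, seed = 2)
  # first presentation: no prior response, baseline exactly at baselineF;
  # the discrete exponential kernel has the closed form g * (1 - (1-a)^k)
  ep <- epochDFF(sim$traces, sch)
  g <- prm$amplitude *
    exp(-(log2(scheduleTable(sch)$freq_hz[1]) -
            log2(sim$truth$centre_hz[1]))^2 / 2)
  a <- (1 / prm$rateHz) / prm$tauS
  k5 <- function(j) mean(g * (1 - (1 - a)^(((j - 1) * 5 + 1):((j - 1) * 5 + 5))))
  expected <- vapply(seq_len(22), k5, numeric(1))
  expect_equal(as.numeric(ep$dff[[1]][1, 1:22]), expected, tolerance = 1e-6)
})

test_that("mean responses average presentations first, then time", {
  # two presentations a and b give the time mean of (a+b)/2
  mk <- function(vals) matrix(vals, 2, 4, byrow = TRUE)
  ep <- structure(list(dff = list(mk(c(1, 2, 3, 4)), mk(c(3, 2, 1, 0))),
                       label = c("s", "s"), freq_hz = c(1.5, 1.5),
                       rate_hz = 1), class = "EpochedDFF")
  rt <- meanResponses(ep)
  expect_equal(as.numeric(responseValues(rt)), rep(mean(c(2, 2, 2, 2)), 2))

  # random epoched tensor against brute-force nested loops
  set.seed(11)
  labs <- rep(c("x", "y"), each = 3)
  dff <- lapply(1:6, function(i) matrix(rnorm(5 * 7), 5, 7))
  epR <- structure(list(dff = dff, label = labs,
                        freq_hz = rep(c(1.5, 60), each = 3), rate_hz = 1),
                   class = "EpochedDFF")
  rtR <- meanResponses(epR)
  for (roi in 1:5) for (li in 1:2) {
    idx <- which(labs == c("x", "y")[li])
    acc <- 0
    for (tt in 1:7) {
      s <- 0
      for (p in idx) s <- s + dff[[p]][roi, tt]
      acc <- acc + s / length(idx)
    }
    expect_equal(unname(responseValues(rtR)[roi, li]), acc / 7,
                 tolerance = 1e-12)
  }
})

test_that("the percentile responsiveness filter follows its tie and boundary rules", {
  vals <- matrix(seq_len(100), 100, 1)  # distinct values, one stimulus
  rt <- toyResponseTable(vals, 1.5)
  expect_identical(responsiveFilter(rt, 95), 96:100)  # exactly 5 retained
  expect_identical(responsiveFilter(rt, 0), 1:100)    # no threshold
  rtTie <- toyResponseTable(matrix(1, 50, 1), 1.5)
  expect_length(responsiveFilter(rtTie, 95), 0)       # strict inequality
  expect_error(responsiveFilter(toyResponseTable(matrix(1, 5, 1), 1.5)),
               "20 ROIs")
})

test_that("the bout preference index implements the normalized category contrast", {
  rt <- toyResponseTable(rbind(c(3, 3, 3, 1, 1),    # 3:1 ratio -> 0.5
                               c(2, 2, 2, 2, 2),    # equal -> 0
                               c(1, 1, 1, 0, 0),    # no continuous -> 1
                               c(0, 0, 0, 0, 0),    # zero denominator
                               c(1, 1, 1, -2, -2)), # negative mean allowed
                         c(0.75, 1.5, 3, 6, 60))
  b <- boutPreferenceIndex(rt)
  expect_identical(b$bpi[1], 0.5)
  expect_identical(b$bpi[2], 0)
  expect_identical(b$bpi[3], 1)
  expect_true(is.na(b$bpi[4]))
  expect_identical(b$flag[4], "zero_denominator")
  expect_identical(b$flag[5], "outside_unit")
  expect_identical(b$bpn, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # antisymmetry under category swap, invariance under rescaling
  set.seed(3)
  v <- matrix(abs(rnorm(40, 1)), 8, 5)
  rtR <- toyResponseTable(v, c(0.75, 1.5, 3, 6, 60))
  bF <- boutPreferenceIndex(rtR)
  bS <- boutPreferenceIndex(rtR, boutHz = c(6, 60), contHz = c(0.75, 1.5, 3))
  expect_equal(bS$bpi, -bF$bpi)
  bC <- boutPreferenceIndex(toyResponseTable(3.7 * v, c(0.75, 1.5, 3, 6, 60)))
  expect_equal(bC$bpi, bF$bpi)
})

test_that("the quadratic-spline tuning peak locates maxima exactly where expected", {
  # exact parabola: vertex recovered to 1e-6
  x <- c(0.5, 1, 2, 4, 8)
  y <- -(x - 2.3)^2 + 10
  expect_equal(tuningPeak(x, y), 2.3, tolerance = 1e-6)
  # strictly increasing responses peak at the right boundary
  expect_equal(tuningPeak(1:5, c(1, 2, 4, 8, 16)), 5, tolerance = 1e-6)
  # symmetric tent peaks at its middle support point
  expect_equal(tuningPeak(1:5, c(0, 1, 2, 1, 0)), 3, tolerance = 1e-6)
  expect_error(tuningPeak(c(1, 1, 2), c(0, 1, 0)), "duplicate")
  expect_error(tuningPeak(c(1, 2), c(0, 1)), "3 support")

  # log-axis frequency peak on the standard five-frequency grid
  f <- c(0.75, 1.5, 3, 6, 60)
  resp <- exp(-(log2(f) - log2(1.2))^2 / 2)
  expect_equal(frequencyTuningPeak(f, resp), 1.2, tolerance = 0.05)
})

test_that("a non-selective population has mean BPI near zero", {
  sim <- genTraces(neuronSimParams(nNeurons = 60, selectiveFrac = 0,
                                   responderFrac = 1), seed = 13)
  rt <- meanResponses(epochDFF(sim$traces, makeFrequencySchedule()))
  b <- boutPreferenceIndex(rt)
  sem <- sd(b$bpi) / sqrt(length(b$bpi))
  expect_lt(abs(mean(b$bpi)), 2 * sem + 0.02)
})
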