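# kernel density mapping of cell coordinates and region assignment

test_that("the KDE conserves mass and respects the hemisphere split", {
  mask <- array(TRUE, c(40, 30, 20))
  pts <- genCellPoints(rbind(c(60, 60, 40), c(140, 70, 40)),
                       c(80, 20), sigmaUm = 15, seed = 3)
  f <- fitDensity(pts, mask, bandwidthUm = 10, spacingUm = 4,
                  midlineUm = 100)
  # mass conservation: |sum * voxel volume - N| < 1e-6 N
  expect_equal(sum(f@values) * voxelVolume(f), 100, tolerance = 1e-6)
  # global argmax falls inside the 80% cluster
  am <- which(f@values == max(f@values), arr.ind = TRUE)
  amUm <- (am - 1) * 4
  expect_lt(sqrt(sum((amUm - c(60, 60, 40))^2)), 20)

  # points confined to the left hemisphere leave the right at zero
  ptsL <- pts[pts$x_um <= 100, ]
  fL <- fitDensity(ptsL, mask, 10, 4, midlineUm = 100)
  xc <- (seq_len(40) - 1) * 4
  expect_equal(max(fL@values[xc > 100, , ]), 0)
  expect_gt(max(fL@values[xc <= 100, , ]), 0)

  # all points at one in-mask location: total mass N, argmax there
  one <- data.frame(x_um = rep(48, 7), y_um = rep(48, 7), z_um = rep(36, 7))
  f1 <- fitDensity(one, mask, 10, 4)
  expect_equal(sum(f1@values) * voxelVolume(f1), 7, tolerance = 1e-6)
  am1 <- (which(f1@values == max(f1@values), arr.ind = TRUE) - 1) * 4
  expect_equal(as.numeric(am1), c(48, 48, 36))

  expect_warning(f0 <- fitDensity(one[0, ], mask, 10, 4), "empty")
  expect_equal(max(f0@values), 0)
})

test_that("the KDE is equivariant under rigid translation", {
  mask <- array(TRUE, c(30, 30, 15))
  pts <- genCellPoints(rbind(c(40, 40, 20)), 40, sigmaUm = 10, seed = 8)
  f0 <- fitDensity(pts, mask, 10, 4)
  shifted <- pts
  shifted$x_um <- shifted$x_um + 16
  shifted$y_um <- shifted$y_um + 8
  f1 <- fitDensity(shifted, mask, 10, 4, originUm = c(16, 8, 0))
  expect_equal(f1@values, f0@values, tolerance = 1e-9)
})

test_that("density contours binarize, project and nest correctly", {
  mask <- array(TRUE, c(30, 30, 15))
  pts <- genCellPoints(rbind(c(60, 60, 30)), 200, sigmaUm = 12, seed = 4)
  f <- fitDensity(pts, mask, 10, 4)
  ct <- densityContours(f)
  # a single spherical cluster: one closed contour per passing threshold
  lens <- vapply(ct, length, numeric(1))
  expect_true(all(lens[lens > 0] == 1))
  # nesting: higher-threshold contour lies inside the lower one
  passing <- which(lens == 1)
  if (length(passing) >= 2) {
    lo <- ct[[passing[1]]][[1]]
    hi <- ct[[passing[length(passing)]]][[1]]
    expect_gte(min(hi$x_um), min(lo$x_um))
    expect_lte(max(hi$x_um), max(lo$x_um))
    expect_gte(min(hi$y_um), min(lo$y_um))
    expect_lte(max(hi$y_um), max(lo$y_um))
  }
  # thresholds above the maximum produce no contours; empty fields too
  expect_length(densityContours(f, 1e6)[[1]], 0)
  fEmpty <- suppressWarnings(fitDensity(pts[0, ], mask, 10, 4))
  expect_length(densityContours(fEmpty, 0.1)[[1]], 0)
})

test_that("region fractions partition all cells, including unassigned", {
  lab <- array(0L, c(50, 40, 25))
  lab[1:18, , ] <- 1L   # 36% band
  lab[19:27, , ] <- 2L  # 18% band
  set.seed(6)
  mkpts <- function(n, xr) data.frame(x_um = runif(n, xr[1], xr[2]),
                                      y_um = runif(n, 2, 150),
                                      z_um = runif(n, 2, 90))
  pts <- rbind(mkpts(36, c(2, 68)), mkpts(18, c(74, 104)),
               mkpts(46, c(110, 190)))
  fr <- regionFractions(pts, lab, c("TeO", "DT"), spacingUm = 4)
  expect_equal(as.numeric(fr), c(0.36, 0.18, 0.46))
  expect_equal(sum(fr), 1)

  allIn <- mkpts(20, c(2, 68))
  frAll <- regionFractions(allIn, lab, c("TeO", "DT"), spacingUm = 4)
  expect_equal(as.numeric(frAll), c(1, 0, 0))
  outside <- data.frame(x_um = rep(1e4, 5), y_um = 0, z_um = 0)
  frOut <- regionFractions(outside, lab, c("TeO", "DT"), spacingUm = 4)
  expect_equal(as.numeric(frOut["unassigned"]), 1)
})
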