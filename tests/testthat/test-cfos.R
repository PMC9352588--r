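# two-channel normalization, bulk cluster signal, effect sizes, clustering

blockMasks <- function(dims = c(12, 10, 8)) {
  mk <- function(xr) { m <- array(FALSE, dims); m[xr, 1:5, ] <- TRUE; m }
  list(A = mk(1:4), B = mk(5:8), C = mk(9:12))
}

test_that("activity normalization cancels shared intensity structure", {
  dims <- c(12, 10, 8)
  ref <- array(runif(prod(dims), 50, 150), dims)
  p <- new("VolumePair", activity = ref, reference = ref,
           animal = "a1", condition = "no-stimulus")
  expect_equal(unique(as.numeric(normalizeActivity(p))), 1)

  # multiplying both channels by a positive scalar field changes nothing
  fieldScale <- array(runif(prod(dims), 0.5, 2), dims)
  act <- array(runif(prod(dims), 10, 90), dims)
  p1 <- new("VolumePair", activity = act, reference = ref,
            animal = "a", condition = "bout-like")
  p2 <- new("VolumePair", activity = act * fieldScale,
            reference = ref * fieldScale, animal = "a",
            condition = "bout-like")
  m <- blockMasks(dims)
  expect_equal(bulkClusterSignal(normalizeActivity(p2), m),
               bulkClusterSignal(normalizeActivity(p1), m),
               tolerance = 1e-12)

  # reference-zero voxels are masked, not divided
  refz <- ref; refz[1:3, 1, 1] <- 0
  pz <- new("VolumePair", activity = act, reference = refz,
            animal = "z", condition = "bout-like")
  nv <- normalizeActivity(pz)
  expect_true(all(is.na(nv[1:3, 1, 1])))
  expect_error(normalizeActivity(new("VolumePair",
    activity = act, reference = array(0, dims), animal = "e",
    condition = "bout-like")), "all zero")

  # synthetic depth attenuation applied to both channels cancels out
  vols <- genCfosVolumes(blockMasks(), matrix(0, 3, 1,
                           dimnames = list(c("A", "B", "C"), "bout-like")),
                         nPerGroup = 2, animalSd = 0, voxelNoiseSd = 0,
                         seed = 2)
  flat <- normalizeActivity(vols[[1]])
  expect_lt(diff(range(apply(flat, 3, mean, na.rm = TRUE))), 1e-6)
})

test_that("bulk cluster signal equals the brute-force masked mean", {
  dims <- c(12, 10, 8)
  m <- blockMasks(dims)
  vol <- array(0, dims)
  vol[m$A] <- 3.5; vol[m$B] <- 1.25; vol[m$C] <- -2
  expect_equal(bulkClusterSignal(vol, m),
               c(A = 3.5, B = 1.25, C = -2))

  set.seed(7)
  volR <- array(rnorm(prod(dims)), dims)
  got <- bulkClusterSignal(volR, m)
  for (k in names(m)) {
    acc <- 0; cnt <- 0
    for (i in seq_along(volR)) if (m[[k]][i]) { acc <- acc + volR[i]; cnt <- cnt + 1 }
    expect_equal(unname(got[k]), acc / cnt, tolerance = 1e-12)
  }
  allNA <- volR; allNA[m$A] <- NA
  expect_warning(gotNA <- bulkClusterSignal(allNA, m), "A")
  expect_true(is.na(gotNA["A"]))
})

test_that("Cohen's d and the Bonferroni tiers follow their definitions", {
  expect_equal(cohensD(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_true(is.na(cohensD(c(1, 1), c(1, 1))))
  x <- rnorm(8); y <- rnorm(8, 1)
  expect_equal(cohensD(x, y), -cohensD(y, x))

  bulk <- rbind(matrix(c(0, 1, 2), 3, 2), matrix(c(1, 2, 3), 3, 2))
  colnames(bulk) <- c("c1", "c2")
  em <- conditionEffects(bulk, rep(c("no-stimulus", "bout-like"), each = 3))
  expect_equal(unname(effectSizes(em)[, "bout-like"]), c(1, 1))

  # identical groups: d = 0, p = 1
  same <- rbind(matrix(1:4, 4, 1), matrix(1:4, 4, 1))
  emS <- conditionEffects(same, rep(c("no-stimulus", "continuous"), each = 4))
  expect_equal(unname(effectSizes(emS)[1, 1]), 0)
  expect_equal(unname(pValues(emS)[1, 1]), 1)

  # a condition below baseline yields negative d; the Bonferroni family
  # is the per-cluster set of stimulus-vs-baseline comparisons (alpha/3)
  set.seed(1)
  mkGrp <- function(shift) matrix(rnorm(24, 10) + shift, 8, 3)
  b3 <- rbind(mkGrp(0), mkGrp(-5), mkGrp(0.1), mkGrp(0))
  conds <- rep(c("no-stimulus", "bout-like", "continuous", "conspecific"),
               each = 8)
  em3 <- conditionEffects(b3, conds)
  expect_lt(unname(effectSizes(em3)[1, "bout-like"]), 0)
  expect_identical(unname(significanceTiers(em3)[1, "bout-like"]), "***")
  p1 <- pValues(em3)[1, "continuous"]
  expect_identical(unname(significanceTiers(em3)[1, "continuous"]),
                   if (p1 < 0.001 / 3) "***" else if (p1 < 0.01 / 3) "**"
                   else if (p1 < 0.05 / 3) "*" else "")
  expect_error(conditionEffects(b3, rep("bout-like", 32)), "baseline")
})

test_that("effect dendrograms merge identical rows first and split blocks last", {
  rows <- rbind(a = c(1, 1, 1), b = c(1, 1, 1),
                x = c(-4, -4, -4), y = c(-4.2, -4, -4))
  dn <- effectDendrogram(rows)
  hc <- dn$hclust
  expect_equal(hc$height[1], 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("a", "b"))
  # top split separates the two blocks
  topGroups <- cutree(hc, 2)
  expect_identical(unname(topGroups[c("a", "b")]), c(1L, 1L))
  expect_identical(unname(topGroups[c("x", "y")]), c(2L, 2L))
  expect_match(dn$newick, "^\\(")

  # single complete row: trivial tree; NA rows are dropped with report
  one <- effectDendrogram(rbind(solo = c(1, 2)))
  expect_identical(one$labels, "solo")
  withNA <- rbind(a = c(1, NA), b = c(0, 1), c = c(2, 1))
  dnNA <- effectDendrogram(withNA)
  expect_identical(dnNA$dropped, "a")
  expect_identical(sort(dnNA$hclust$labels), c("b", "c"))
})

test_that("planted effect sizes are recovered from synthetic volumes", {
  m <- blockMasks()
  eff <- matrix(c(1.5, 0, -1), 3, 1,
                dimnames = list(names(m), "bout-like"))
  vols <- genCfosVolumes(m, eff, nPerGroup = 8, seed = 5)
  bulk <- t(vapply(vols, function(p)
    bulkClusterSignal(normalizeActivity(p), m), numeric(3)))
  conds <- vapply(vols, function(p) p@condition, character(1))
  em <- conditionEffects(bulk, conds)
  dHat <- effectSizes(em)[, "bout-like"]
  expect_gt(dHat["A"], 0)
  expect_lt(dHat["C"], 0)
  expect_true(all(abs(dHat - eff[, 1]) < 0.8))
})
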