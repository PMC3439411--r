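test_that("generated stress records follow the exponential law exactly", {
  m <- TissueModel(0.02e6, 8)
  curve <- genStressStrain(m, 50, noiseSD = 0, seed = 3)
  lam <- stretchLevels(curve)
  expect_equal(stressValues(curve), 0.02e6 * (exp(8 * (lam - 1)) - 1),
               tolerance = 1e-10)
  # direct evaluation at lambda = 1.3: 0.02 MPa * (e^2.4 - 1)
  expect_equal(0.02e6 * (exp(8 * 0.3) - 1), 0.2005e6, tolerance = 1e-3)
  expect_equal(stressValues(curve)[1], 0)  # lambda = 1 anchor

  null <- genStressStrain(TissueModel(0, 5), 200, noiseSD = 100, seed = 4)
  expect_lt(abs(mean(stressValues(null))), 3 * 100 / sqrt(200))
  expect_error(genStressStrain(m, 2, 0, 1), ">= 3")
  expect_error(genStressStrain(m, 10, -1, 1), ">= 0")
  expect_identical(stressValues(genStressStrain(m, 20, 50, seed = 9)),
                   stressValues(genStressStrain(m, 20, 50, seed = 9)))
})

test_that("two-post equilibrium matches an independent bisection solve", {
  g <- PostGeometry()
  k <- postBendingStiffness(g)
  m <- TissueModel(0.02e6, 8)
  d <- seq(0, 250e-6, by = 50e-6)
  rec <- simulateTwoPostTest(g, m, d)
  for (i in seq_along(d)) {
    vOracle <- bisectTwoPost(k, m, g@baseSeparation, d[i])
    expect_lt(abs(rec$deflection_m[i] - vOracle), 1e-9)
  }
  # force balance residual at every step
  Ftis <- 0.02e6 * (exp(8 * (rec$stretch - 1)) - 1) * m@width * m@thickness
  expect_lt(max(abs(k * rec$deflection_m - Ftis)), 1e-9)
  expect_true(all(diff(rec$stretch) >= 0))
})

test_that("two-post limits: free posts and rigid posts", {
  g <- PostGeometry()
  d <- c(0, 100e-6, 250e-6)
  free <- simulateTwoPostTest(g, TissueModel(0, 8), d)
  expect_equal(free$deflection_m, rep(0, 3))
  expect_equal(free$stretch, (g@baseSeparation + 2 * d) / g@baseSeparation)

  rigid <- simulateTwoPostTest(
    PostGeometry(elasticModulus = 1e16), TissueModel(0.02e6, 8), d)
  expect_lt(max(abs(rigid$stretch -
                      (g@baseSeparation + 2 * d) / g@baseSeparation)), 1e-6)
  expect_error(simulateTwoPostTest(g, TissueModel(0.02e6, 8), c(2e-4, 1e-4)),
               "nondecreasing")
})

test_that("fiber scenes are seed-reproducible and honor the affine map", {
  spec <- FiberFieldSpec(seed = 11)
  a <- genFiberImage(spec, 1.25)
  b <- genFiberImage(spec, 1.25)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(groundTruth(a), groundTruth(b))
  # at lambda = 1 the affine map is the identity whatever nu is
  expect_identical(sceneImage(genFiberImage(spec, 1, nu = 0.3)),
                   sceneImage(genFiberImage(spec, 1, nu = 2)))
  expect_error(genFiberImage(spec, 0.9), ">= 1")
})

test_that("fiber orientation ground truth concentrates with kappa", {
  # strongly concentrated fields are dominated by near-axis length
  sc50 <- genFiberImage(FiberFieldSpec(orientationConcentration = 50,
                                       seed = 2), 1)
  expect_gte(analyticAlignmentIndex(sc50), 0.6)
  # axial circular mean approaches the loading axis as kappa grows
  axialMean <- function(sc) {
    seg <- groundTruth(sc)
    ang <- seg$angleDeg * pi / 90  # doubled angles
    m <- atan2(sum(seg$lengthPx * sin(ang)), sum(seg$lengthPx * cos(ang)))
    abs(m * 90 / pi)
  }
  dev <- vapply(c(5, 200), function(k) {
    mean(vapply(1:4, function(s)
      axialMean(genFiberImage(FiberFieldSpec(orientationConcentration = k,
                                             seed = s), 1)), numeric(1)))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 2)
})

test_that("cell masks hit their target circularity and stay labeled", {
  circles <- CellFieldSpec(nCells = 15, imageSize = 384, baseCI = 1,
                           ciSlope = 0, noiseSD = 0, seed = 5)
  sc <- genCellMasks(circles, 1)
  cis <- vapply(segmentCells(sc), circularity, numeric(1))
  expect_true(all(cis >= 0.98 & cis <= 1))

  flat <- CellFieldSpec(nCells = 15, imageSize = 384, baseCI = 0.8,
                        ciSlope = 0, noiseSD = 0, seed = 6)
  ciPerLam <- vapply(c(1, 1.3, 1.6), function(l)
    mean(vapply(segmentCells(genCellMasks(flat, l)), circularity,
                numeric(1))), numeric(1))
  expect_lt(diff(range(ciPerLam)), 0.02)

  # labels are stable across stretch for a fixed seed
  t1 <- groundTruth(genCellMasks(flat, 1))
  t2 <- groundTruth(genCellMasks(flat, 1.5))
  expect_identical(t1$cellId, t2$cellId)
  expect_equal(t1$phiDeg, t2$phiDeg)

  bad <- CellFieldSpec(baseCI = 0.3, ciSlope = -0.6, seed = 1)
  expect_error(genCellMasks(bad, 1.6), "outside")
})

test_that("noiseless mechanical round trip recovers the tissue model", {
  g <- PostGeometry()
  m <- TissueModel(0.025e6, 7)
  rec <- simulateTwoPostTest(g, m, seq(0, 320e-6, length.out = 15))
  fit <- fitFung(curveFromRecord(rec, g, width = m@width,
                                 thickness = m@thickness))
  expect_equal(coef(fit)[["alpha"]], 0.025e6, tolerance = 0.01)
  expect_equal(coef(fit)[["beta"]], 7, tolerance = 0.01)
})

test_that("synthetic slides honor requested fractions and degenerate cases", {
  expect_error(genHistologySlide(c(collagen = 0.7, gag = 0.4), 96, 1),
               "sum")
  empty <- genHistologySlide(c(collagen = 0, gag = 0), 96, seed = 1)
  cf <- areaFractions(splitConstituents(empty, stainProfile("movat")),
                      empty@leafletMask)
  expect_true(all(fractions(cf) < 0.02))

  even <- genHistologySlide(c(collagen = 0.5, gag = 0.5), 192, seed = 2)
  cfe <- areaFractions(splitConstituents(even, stainProfile("movat")),
                       even@leafletMask)
  expect_equal(collagenGagRatio(cfe), 1.0, tolerance = 0.03)
})
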