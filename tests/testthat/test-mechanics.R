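test_that("cantilever stiffness follows Euler-Bernoulli tip loading", {
  g <- PostGeometry(diameter = 2e-3, length = 6e-3, elasticModulus = 1e6)
  expect_equal(postBendingStiffness(g), 10.908, tolerance = 1e-3)
  # linear in E, cubic in L, quartic in d
  g2 <- PostGeometry(diameter = 2e-3, length = 6e-3, elasticModulus = 2e6)
  expect_identical(postBendingStiffness(g2), 2 * postBendingStiffness(g))
  g3 <- PostGeometry(diameter = 2e-3, length = 60e-3, elasticModulus = 1e6)
  expect_equal(postBendingStiffness(g3), postBendingStiffness(g) / 1000)
  g4 <- PostGeometry(diameter = 4e-3, length = 6e-3, elasticModulus = 1e6)
  expect_equal(postBendingStiffness(g4), 16 * postBendingStiffness(g))
  expect_error(PostGeometry(diameter = -1), "> 0")
})

test_that("force, stretch and stress conversions are exact and linear", {
  k <- postBendingStiffness(PostGeometry())
  expect_identical(forceFromDeflection(0, k), 0)
  expect_equal(forceFromDeflection(100e-6, k), 1.0908e-3, tolerance = 1e-4)
  v <- c(1e-6, 5e-6, 2e-4)
  expect_identical(forceFromDeflection(2 * v, k),
                   2 * forceFromDeflection(v, k))

  lam <- stretchFromSeparation(800e-6, 500e-6)
  expect_equal(as.numeric(lam), 1.6)
  expect_false(attr(lam, "compression"))
  lam0 <- stretchFromSeparation(0, 500e-6)
  expect_equal(as.numeric(lam0), 0)
  expect_true(attr(lam0, "compression"))

  expect_identical(nominalStress(0, 1e-3, 40e-6), 0)
  expect_equal(nominalStress(1e-3, 1e-3, 40e-6), 25e3)
  expect_equal(nominalStress(1e-3, 1e-3, 20e-6),
               2 * nominalStress(1e-3, 1e-3, 40e-6))
})

test_that("exponential-law fit recovers noiseless parameters to 0.1%", {
  lam <- seq(1, 1.6, length.out = 15)
  for (par in list(c(0.02e6, 8), c(5e3, 12), c(0.1e6, 3))) {
    curve <- StressStrainCurve(lam, par[1] * (exp(par[2] * (lam - 1)) - 1))
    fit <- fitFung(curve)
    expect_equal(coef(fit)[["alpha"]], par[1], tolerance = 1e-3)
    expect_equal(coef(fit)[["beta"]], par[2], tolerance = 1e-3)
    expect_gt(rSquared(fit), 0.9999)
  }
})

test_that("degenerate stress records are rejected with data-quality errors", {
  lam <- seq(1, 1.6, length.out = 10)
  expect_error(fitFung(StressStrainCurve(lam, rep(0, 10))), "equal")
  # monotone-decreasing stress is not a tensile record
  expect_error(fitFung(StressStrainCurve(lam, seq(1e4, 0, length.out = 10))),
               "decreas")
  expect_error(StressStrainCurve(c(1, 1.2), c(0, 1)), "3 points")
  expect_error(StressStrainCurve(c(1, 1.2, 1.1), c(0, 1, 2)), "increasing")
})

test_that("fit agrees with a brute-force lattice search on random curves", {
  set.seed(42)
  lam <- seq(1, 1.6, length.out = 12)
  for (i in 1:10) {
    a <- exp(runif(1, log(5e3), log(1e5)))
    b <- runif(1, 3, 12)
    sig <- a * (exp(b * (lam - 1)) - 1)
    fit <- fitFung(StressStrainCurve(lam, sig))
    gs <- gridSearchFung(lam - 1, sig, alphaRange = a * c(0.5, 2),
                         betaRange = b + c(-2, 2))
    expect_lt(abs(log(coef(fit)[["alpha"]]) - log(gs$alpha)), gs$dAlpha)
    expect_lt(abs(coef(fit)[["beta"]] - gs$beta), gs$dBeta)
  }
})

test_that("tangent modulus follows alpha * beta * exp(beta * eps)", {
  curve <- genStressStrain(TissueModel(0.02e6, 8), 20, 0, seed = 1)
  fit <- fitFung(curve)
  expect_equal(effectiveModulus(fit, 0), coef(fit)[["alpha"]] *
                 coef(fit)[["beta"]])
  expect_equal(effectiveModulus(fit, 0.3), 1.764e6, tolerance = 1e-3)
  eref <- seq(0, 0.6, by = 0.1)
  expect_true(all(diff(effectiveModulus(fit, eref)) > 0))
  expect_error(effectiveModulus(fit, -0.1), ">= 0")
})

test_that("stress output scales exactly with inverse cross-section area", {
  g <- PostGeometry()
  rec <- simulateTwoPostTest(g, TissueModel(0.02e6, 8),
                             seq(0, 200e-6, by = 50e-6))
  c1 <- curveFromRecord(rec, g, width = 1e-3, thickness = 40e-6)
  c2 <- curveFromRecord(rec, g, width = 2e-3, thickness = 40e-6)
  expect_equal(stressValues(c1), 2 * stressValues(c2))
})
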