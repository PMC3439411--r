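test_that("constituent masks agree with the painted ground truth", {
  sl <- genHistologySlide(c(collagen = 0.45, gag = 0.25), 224, seed = 31)
  masks <- splitConstituents(sl, stainProfile("movat"))
  truth <- groundTruth(sl)
  for (nm in names(masks)) {
    agree <- mean((masks[[nm]] == truth[[nm]])[sl@leafletMask])
    expect_gte(agree, 0.98)
  }
})

test_that("pure and blank slides split into trivial masks", {
  white <- array(1, c(96, 96, 3))
  masks <- splitConstituents(white, stainProfile("movat"))
  expect_true(all(!masks$collagen) && all(!masks$gag))

  pure <- genHistologySlide(c(collagen = 1), 128, seed = 1)
  m <- splitConstituents(pure, stainProfile("movat"))
  inLeaf <- sl <- pure@leafletMask
  expect_gte(sum(m$collagen & inLeaf) / sum(inLeaf), 0.97)
  expect_lte(sum(m$gag & inLeaf) / sum(inLeaf), 0.02)
})

test_that("area fractions are leaflet-normalized with a guarded ratio", {
  sl <- genHistologySlide(c(collagen = 0.6, gag = 0.2), 224, seed = 32)
  cf <- areaFractions(splitConstituents(sl, stainProfile("movat")),
                      sl@leafletMask)
  expect_equal(collagenGagRatio(cf), 3.0, tolerance = 0.05 / 3)
  # ratio always equals the ratio of the recovered fractions
  expect_equal(collagenGagRatio(cf),
               fractions(cf)[["collagen"]] / fractions(cf)[["gag"]],
               tolerance = 1e-12)

  noGag <- genHistologySlide(c(collagen = 0.5, gag = 0), 128, seed = 33)
  cf0 <- areaFractions(splitConstituents(noGag, stainProfile("movat")),
                       noGag@leafletMask)
  expect_false(cf0@ratioDefined)
  expect_true(is.na(collagenGagRatio(cf0)))
  expect_error(areaFractions(list(collagen = matrix(TRUE, 4, 4)),
                             matrix(FALSE, 4, 4)), "empty")
})

test_that("fraction recovery stays within 0.02 across random slides", {
  set.seed(34)
  maxErr <- 0
  for (s in 1:15) {
    f <- c(collagen = runif(1, 0.1, 0.55), gag = runif(1, 0.05, 0.35))
    sl <- genHistologySlide(f, 160, seed = 1000 + s)
    cf <- areaFractions(splitConstituents(sl, stainProfile("movat")),
                        sl@leafletMask)
    maxErr <- max(maxErr, abs(fractions(cf) - f))
  }
  expect_lt(maxErr, 0.02)
})

test_that("Otsu is robust against a known-optimal fixed threshold", {
  # 5% color noise; the constituent colors put the optimal cut midway
  prof <- stainProfile("movat")
  fixed <- prof
  fixed@rules$collagen$threshold <- 0.4
  fixed@rules$gag$threshold <- 0.27
  for (s in 1:5) {
    sl <- genHistologySlide(c(collagen = 0.4, gag = 0.25), 160,
                            seed = 40 + s, colorNoise = 0.05)
    fOtsu <- fractions(areaFractions(splitConstituents(sl, prof),
                                     sl@leafletMask))
    fFix <- fractions(areaFractions(splitConstituents(sl, fixed),
                                    sl@leafletMask))
    expect_lt(max(abs(fOtsu - fFix)), 0.03)
  }
})

test_that("stain profiles cover trichrome and VVG rule spaces", {
  cols <- valvemech:::defaultConstituentColors()
  slt <- genHistologySlide(c(connective_tissue = 0.5), 160, seed = 50)
  mt <- splitConstituents(slt, stainProfile("trichrome"))
  frt <- areaFractions(mt, slt@leafletMask)
  expect_equal(fractions(frt)[["connective_tissue"]], 0.5,
               tolerance = 0.02)

  slv <- genHistologySlide(c(elastin = 0.3), 160, seed = 51)
  mv <- splitConstituents(slv, stainProfile("vvg"))
  frv <- areaFractions(mv, slv@leafletMask)
  expect_equal(fractions(frv)[["elastin"]], 0.3, tolerance = 0.02)
})

test_that("stain profile YAML round-trips and rejects unknown rules", {
  p <- stainProfile("movat")
  f <- tempfile(fileext = ".yaml")
  writeStainProfile(p, f)
  q <- readStainProfile(f)
  expect_identical(q@stainName, p@stainName)
  expect_identical(names(q@rules), names(p@rules))
  bad <- p
  expect_error({bad@rules$collagen$space <- "hsl"; validObject(bad)},
               "channel space")
})

test_that("reference normalization rescales the reference mean to 1", {
  v <- c(0.31, 0.29, 0.33, 0.14, 0.16, 0.15)
  g <- rep(c("wt", "mut"), each = 3)
  rel <- normalizeToReference(v, g, "wt")
  expect_identical(mean(rel[g == "wt"]), 1)
  expect_equal(mean(rel[g == "mut"]),
               mean(v[g == "mut"]) / mean(v[g == "wt"]))
  half <- normalizeToReference(c(2, 2, 1, 1), c("r", "r", "t", "t"), "r")
  expect_equal(mean(half[3:4]), 0.5)
  expect_error(normalizeToReference(c(0, 0, 1), c("r", "r", "t"), "r"),
               "zero")
  # seeded cohorts around 0.30 vs 0.15 recover a relative mean near 0.5
  set.seed(60)
  ref <- rnorm(6, 0.30, 0.03); tst <- rnorm(6, 0.15, 0.03)
  rel2 <- normalizeToReference(c(ref, tst), rep(c("r", "t"), each = 6), "r")
  expect_equal(mean(rel2[7:12]), 0.5, tolerance = 0.2)
  expect_lt(abs(mean(rel2[7:12]) - 0.5), 0.1)
})
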