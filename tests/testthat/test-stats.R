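test_that("linear trend is exact on affine data and sane on noise", {
  tr <- linearTrend(1:7, 3 - 0.3 * (1:7))
  expect_equal(tr$slope, -0.3, tolerance = 1e-12)
  expect_equal(tr$intercept, 3, tolerance = 1e-12)
  expect_equal(tr$rSquared, 1, tolerance = 1e-12)
  expect_equal(linearTrend(1:5, rep(2, 5))$slope, 0, tolerance = 1e-12)
  set.seed(70)
  x <- seq(0, 1, length.out = 100)
  tr2 <- linearTrend(x, x + rnorm(100, 0, 0.1))
  expect_lt(abs(tr2$slope - 1), 0.05)
  expect_error(linearTrend(rep(1, 5), 1:5), "equal")
})

test_that("Student's t matches the closed-form pooled statistic", {
  r <- twoSampleT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(testStatistic(r), -sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(testStatistic(r), -1.2247, tolerance = 1e-4)
  expect_equal(r@df, 4)

  same <- twoSampleT(c(5, 6, 7), c(5, 6, 7))
  expect_equal(testStatistic(same), 0)
  expect_equal(pValue(same), 1)
  ident <- twoSampleT(c(2, 2, 2), c(2, 2))
  expect_equal(pValue(ident), 1)
  expect_error(twoSampleT(c(1, 1, 1), c(2, 2, 2)), "zero pooled variance")
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})

test_that("t-test power on well-separated seeded samples", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    pValue(twoSampleT(rnorm(6, 0, 1), rnorm(6, 2, 1))) < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("ANOVA F and p match the hand-computed reference", {
  set.seed(80)
  for (i in 1:20) {
    ng <- sample(2:5, 1)
    n <- sample(3:8, ng, replace = TRUE)
    g <- rep(letters[1:ng], n)
    v <- rnorm(sum(n), mean = rep(runif(ng, 0, 3), n))
    res <- oneWayAnovaTukey(v, g)
    # independent textbook computation of the F statistic
    gm <- mean(v)
    ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
    ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
    dfb <- ng - 1; dfw <- sum(n) - ng
    Fref <- (ssb / dfb) / (ssw / dfw)
    pref <- pf(Fref, dfb, dfw, lower.tail = FALSE)
    expect_lt(abs(testStatistic(res) - Fref), 1e-8)
    expect_lt(abs(pValue(res) - pref), 1e-8)
  }
})

test_that("Tukey letters separate exactly the significant pairs", {
  # three identical groups share a single letter
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  resEq <- oneWayAnovaTukey(v, g)
  expect_equal(pValue(resEq), 1, tolerance = 1e-12)
  expect_length(unique(letterDisplay(resEq)), 1)

  # one clearly shifted group earns its own letter; oracle is the
  # studentized-range computation done by hand on the same values
  set.seed(81)
  vals <- c(rnorm(6, 0, 1), rnorm(6, 0, 1), rnorm(6, 10, 1))
  grp <- rep(c("g1", "g2", "g3"), each = 6)
  res <- oneWayAnovaTukey(vals, grp)
  ld <- letterDisplay(res)
  expect_false(grepl(ld[["g3"]], ld[["g1"]], fixed = TRUE))
  expect_identical(ld[["g1"]], ld[["g2"]])
  mse <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2))) / 15
  qstat <- abs(mean(vals[13:18]) - mean(vals[1:6])) / sqrt(mse / 6)
  pHand <- ptukey(qstat, 3, 15, lower.tail = FALSE)
  pPkg <- res@pairs$pAdj[res@pairs$group1 == "g3" &
                           res@pairs$group2 == "g1"]
  expect_lt(abs(pPkg - pHand), 1e-8)

  expect_error(oneWayAnovaTukey(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(oneWayAnovaTukey(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 values")
})

test_that("letter display is consistent with adjusted p on random tables", {
  set.seed(82)
  for (i in 1:12) {
    ng <- sample(3:5, 1)
    v <- rnorm(ng * 5, mean = rep(runif(ng, 0, 4), each = 5))
    g <- rep(paste0("g", 1:ng), each = 5)
    res <- oneWayAnovaTukey(v, g)
    ld <- letterDisplay(res)
    for (r in seq_len(nrow(res@pairs))) {
      shares <- any(strsplit(ld[[res@pairs$group1[r]]], "")[[1]] %in%
                      strsplit(ld[[res@pairs$group2[r]]], "")[[1]])
      expect_identical(shares, res@pairs$pAdj[r] >= res@alpha)
    }
  }
})
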