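test_that("circularity matches closed forms for canonical shapes", {
  sq <- CellOutline(rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3)))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(regularPolygon(360, 100)), 1, tolerance = 1e-3)
  expect_gte(1 + 1e-12, circularity(regularPolygon(360, 100)))
  sliver <- rbind(c(0, 0), c(100, 0), c(100, 1), c(0, 1))
  expect_equal(circularity(sliver), 4 * pi * 100 / 202^2, tolerance = 1e-12)
})

test_that("circularity rejects degenerate and self-intersecting polygons", {
  expect_error(circularity(rbind(c(0, 0), c(1, 1))), "3")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(circularity(bowtie), "self-intersecting")
  expect_error(circularity(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("circularity is invariant under similarity transforms", {
  set.seed(7)
  for (i in 1:20) {
    V <- regularPolygon(sample(5:40, 1), runif(1, 0.5, 20))
    V <- V + matrix(rnorm(nrow(V) * 2, 0, 0.02), ncol = 2)
    if (!valvemech:::isSimplePolygon(V)) next
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    W <- s * V %*% R + matrix(runif(2, -100, 100), nrow(V), 2, byrow = TRUE)
    expect_equal(circularity(V), circularity(W), tolerance = 1e-12)
  }
})

test_that("no simple polygon beats the isoperimetric bound", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(3:25, 1)
    # random convex polygon: points on a noisy circle, convex hull
    P <- cbind(runif(n, -1, 1), runif(n, -1, 1))
    H <- P[chull(P), , drop = FALSE]
    if (nrow(H) < 3) next
    expect_lte(circularity(H), 1 + 1e-9)
  }
})

test_that("segmentation counts disjoint cells and flags merges", {
  spec <- CellFieldSpec(nCells = 20, imageSize = 384, baseCI = 0.85,
                        ciSlope = -0.1, noiseSD = 0, seed = 8)
  expect_length(segmentCells(genCellMasks(spec, 1.2)), 20)
  expect_length(segmentCells(matrix(0, 128, 128)), 0)
  # two overlapping ellipses merge into one 8-connected component
  lab <- matrix(0L, 128, 128)
  lab <- valvemech:::paintEllipse(lab, 1L, 50, 64, 18, 10, 0)
  lab <- valvemech:::paintEllipse(lab, 2L, 70, 64, 18, 10, 0)
  expect_length(segmentCells((lab > 0) * 1), 1)
})

test_that("matching is identity on identical frames and gated by radius", {
  spec <- CellFieldSpec(nCells = 12, imageSize = 256, baseCI = 0.9,
                        ciSlope = -0.2, noiseSD = 0, seed = 9)
  fr <- segmentCells(genCellMasks(spec, 1))
  m <- matchCells(list(fr, fr))
  m2 <- m[m$frame == 2, ]
  expect_identical(m2$cellId, m[m$frame == 1, ]$cellId)
  expect_equal(nrow(m2), length(fr))
  # zero gate: every trajectory ends at frame 1
  frB <- segmentCells(genCellMasks(spec, 1.1), frame = 2)
  m0 <- matchCells(list(fr, frB), gatingRadius = 0)
  expect_equal(sum(m0$frame == 2), 0)
})

test_that("matching follows generator labels across stretch steps", {
  spec <- CellFieldSpec(nCells = 30, imageSize = 384, baseCI = 0.9,
                        ciSlope = -0.25, noiseSD = 0.01, seed = 10)
  lams <- seq(1, 1.6, by = 0.1)
  scenes <- lapply(lams, function(l) genCellMasks(spec, l))
  frames <- lapply(seq_along(lams), function(i)
    segmentCells(scenes[[i]], frame = i))
  m <- matchCells(frames)
  # map each matched observation to the nearest ground-truth cell id
  truthId <- function(i, x, y) {
    tt <- groundTruth(scenes[[i]])
    tt$cellId[which.min((tt$x - x)^2 + (tt$y - y)^2)]
  }
  m$truth <- mapply(truthId, m$frame, m$x, m$y)
  correct <- vapply(split(m, m$trackId), function(d)
    all(d$truth == d$truth[1]), logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("trajectory slope is exact on exact linear CI data", {
  lams <- seq(1, 1.6, by = 0.1)
  frames <- lapply(seq_along(lams), function(i) {
    ci <- 0.7 - 0.3 * (lams[i] - 1)  # rectangle CI is capped at pi/4
    list(CellOutline(rectangleForCI(ci) + 50, cellId = "1", frame = i))
  })
  tr <- ciTrajectory(frames, lams, gatingRadius = 100)
  expect_equal(trendSlope(tr), -0.3, tolerance = 1e-9)
  expect_equal(rSquared(tr), 1, tolerance = 1e-9)
  # constant CI gives slope 0
  frames0 <- lapply(seq_along(lams), function(i)
    list(CellOutline(rectangleForCI(0.6) + 50, cellId = "1", frame = i)))
  expect_equal(trendSlope(ciTrajectory(frames0, lams, gatingRadius = 100)),
               0, tolerance = 1e-12)
})

test_that("trajectory recovers the generating CI slope from rasters", {
  spec <- CellFieldSpec(nCells = 50, imageSize = 512, baseCI = 0.9,
                        ciSlope = -0.25, noiseSD = 0.01, seed = 12)
  lams <- seq(1, 1.6, by = 0.1)
  frames <- lapply(seq_along(lams), function(i)
    segmentCells(genCellMasks(spec, lams[i]), frame = i))
  tr <- ciTrajectory(frames, lams)
  expect_lt(abs(trendSlope(tr) - (-0.25)), 0.04)
})

test_that("fiducial tracking recovers translations to subpixel accuracy", {
  set.seed(21)
  base <- matrix(runif(180 * 180), 180, 180)
  base <- EBImage::imageData(EBImage::gblur(EBImage::Image(base), 1))
  dim(base) <- c(180, 180)
  ident <- trackFiducials(list(base, base), rbind(c(50, 50), c(120, 100)))
  for (t in ident)
    expect_equal(t@positions[2, ], t@positions[1, ], tolerance = 0.05)

  shifted <- rbind(matrix(0, 7, 180), base[1:173, ])  # +7 px in x
  tr <- trackFiducials(list(base, shifted), rbind(c(60, 60), c(100, 120)))
  for (t in tr) {
    expect_false(any(t@lost))
    expect_equal(t@positions[2, 1] - t@positions[1, 1], 7, tolerance = 0.25)
    expect_equal(t@positions[2, 2] - t@positions[1, 2], 0, tolerance = 0.25)
  }
  # displacement beyond the search window -> lost from that frame on
  far <- rbind(matrix(0, 60, 180), base[1:120, ])
  lostTr <- trackFiducials(list(base, far, far), rbind(c(80, 80)),
                           templateRadius = 12, searchRadius = 10)
  expect_true(all(lostTr[[1]]@lost[2:3]))
  expect_true(all(is.na(lostTr[[1]]@positions[2:3, ])))
  expect_error(trackFiducials(list(base, base), rbind(c(500, 50))),
               "outside")
})

test_that("local stretch projects marker-pair separations on the axis", {
  mk <- function(pos) new("MarkerTrack", markerId = "m",
                          positions = pos, lost = rep(FALSE, nrow(pos)),
                          searchWindow = 15)
  static <- list(mk(rbind(c(10, 10), c(10, 10), c(10, 10))),
                 mk(rbind(c(60, 10), c(60, 10), c(60, 10))))
  expect_equal(localStretch(static), c(1, 1, 1))
  # affine lambda = 1.4 about x = 0
  aff <- list(mk(rbind(c(10, 10), c(14, 10))), mk(rbind(c(60, 10), c(84, 10))))
  expect_equal(localStretch(aff)[2], 1.4, tolerance = 0.02)
  # pure transverse motion projects out
  trans <- list(mk(rbind(c(10, 10), c(10, 40))), mk(rbind(c(60, 10), c(60, 55))))
  expect_equal(localStretch(trans), c(1, 1))
  near <- list(mk(rbind(c(10, 10), c(11, 10))), mk(rbind(c(11, 10), c(12, 10))))
  expect_error(localStretch(near), "below 2 px")
})

test_that("external tracing CSV ingests into per-frame outlines", {
  d <- data.frame(cell_id = rep(c("a", "b"), each = 8),
                  frame = rep(rep(1:2, each = 4), 2),
                  vertex_index = rep(1:4, 4),
                  x_px = rep(c(0, 10, 10, 0), 4),
                  y_px = rep(c(0, 0, 5, 5), 4))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE)
  frames <- readCellTracings(f)
  expect_length(frames, 2)
  expect_length(frames[[1]], 2)
  expect_equal(circularity(frames[[1]][[1]]),
               4 * pi * 50 / 30^2, tolerance = 1e-12)
})
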