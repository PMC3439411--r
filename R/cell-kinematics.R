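# Shoelace signed area of an n x 2 vertex matrix.
shoelaceArea <- function(V) {
  x <- V[, 1]; y <- V[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygonPerimeter <- function(V) {
  d <- V - V[c(2:nrow(V), 1), ]
  sum(sqrt(rowSums(d^2)))
}

# TRUE if no two non-adjacent edges of the closed polygon intersect.
isSimplePolygon <- function(V) {
  n <- nrow(V)
  if (n < 3) return(FALSE)
  A <- V; B <- V[c(2:n, 1), ]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (!nrow(idx)) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- cross(A[i, 1], A[i, 2], B[i, 1], B[i, 2], A[j, 1], A[j, 2])
  d2 <- cross(A[i, 1], A[i, 2], B[i, 1], B[i, 2], B[j, 1], B[j, 2])
  d3 <- cross(A[j, 1], A[j, 2], B[j, 1], B[j, 2], A[i, 1], A[i, 2])
  d4 <- cross(A[j, 1], A[j, 2], B[j, 1], B[j, 2], B[i, 1], B[i, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Circularity index of a cell outline
#'
#' The circularity index \eqn{CI = 4\pi A / P^2} of a simple polygon, with
#' the area by the shoelace formula and the perimeter by summed edge
#' lengths. CI is 1 for a circle and tends to 0 for elongated shapes; for
#' any simple polygon CI < 1 (isoperimetric inequality). Scale- and
#' rotation-invariant.
#'
#' @param outline a [CellOutline-class], or an n x 2 vertex matrix.
#' @return CI in (0, 1].
#' @examples
#' circularity(CellOutline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
#' # square: pi / 4
#' @export
circularity <- function(outline) {
  V <- if (is(outline, "CellOutline")) outline@vertices else as.matrix(outline)
  stopIfNot(is.numeric(V) && ncol(V) == 2 && nrow(V) >= 3,
            "outline needs at least 3 planar vertices", "invalidPolygonError")
  stopIfNot(isSimplePolygon(V), "polygon is self-intersecting",
            "invalidPolygonError")
  A <- abs(shoelaceArea(V))
  P <- polygonPerimeter(V)
  stopIfNot(A > 0 && P > 0, "degenerate polygon", "invalidPolygonError")
  4 * pi * A / P^2
}

# Closed-chain moving-average smoothing of a boundary chain; the raw
# 8-connected pixel chain overestimates perimeter (staircase bias), which
# would bias CI low, so outlines are smoothed before measurement.
smoothChain <- function(V, window = 7L) {
  n <- nrow(V)
  if (n <= window || window < 3) return(V)
  pad <- (window - 1L) %/% 2L
  Vp <- rbind(V[(n - pad + 1):n, , drop = FALSE], V,
              V[1:pad, , drop = FALSE])
  xs <- stats::filter(Vp[, 1], rep(1 / window, window), sides = 2)
  ys <- stats::filter(Vp[, 2], rep(1 / window, window), sides = 2)
  out <- cbind(xs, ys)[(pad + 1):(pad + n), , drop = FALSE]
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Segment cells from a grayscale raster
#'
#' Global Otsu threshold, connected-component labeling, area filtering and
#' boundary polygonization (8-connected contour chain smoothed by a
#' closed-chain moving average, so the perimeter is measured on the
#' polygonized boundary rather than by pixel-edge counting). Touching cells
#' merge into one component; that is a documented limitation of
#' connectivity-based segmentation.
#'
#' @param image grayscale matrix in \[0,1\] (indexed `[x, y]`), or a
#'   [CellScene-class] (its binarized labels are used).
#' @param minArea,maxArea component area filter in pixels.
#' @param frame frame index attached to the outlines.
#' @param threshold `"otsu"` or a fixed value in \[0,1\].
#' @param smoothWindow boundary smoothing window (vertices).
#' @return list of [CellOutline-class]; empty list when nothing survives
#'   the filter.
#' @export
segmentCells <- function(image, minArea = 30, maxArea = Inf, frame = 1L,
                         threshold = "otsu", smoothWindow = 7L) {
  if (is(image, "CellScene")) image <- (image@labels > 0) * 1
  stopIfNot(is.matrix(image) && is.numeric(image),
            "image must be a numeric matrix", "invalidSpecError")
  if (diff(range(image)) == 0) return(list())
  th <- if (identical(threshold, "otsu"))
    EBImage::otsu(asImage(image), range = range(image)) else threshold
  bw <- (image > th) * 1
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= minArea & areas <= maxArea)
  if (!length(keep)) return(list())
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (k in keep) {
    V <- smoothChain(oc[[k]] + 1, window = smoothWindow)
    if (nrow(V) >= 3 && isSimplePolygon(V))
      out[[length(out) + 1]] <- CellOutline(V, cellId = as.character(k),
                                            frame = frame)
  }
  out
}

outlineCentroid <- function(outline) colMeans(outline@vertices)

#' Match cells across frames by nearest centroid
#'
#' Greedy nearest-centroid assignment between consecutive frames under a
#' gating radius: candidate pairs are sorted by centroid distance (ties by
#' lowest cell label) and assigned injectively. Cells unmatched in any
#' later frame are dropped from their trajectory from that frame onward;
#' cells first appearing after frame 1 do not start new trajectories.
#'
#' @param frames list (one element per frame) of lists of
#'   [CellOutline-class].
#' @param gatingRadius maximum centroid displacement in pixels.
#' @return data.frame with columns `trackId`, `frame`, `cellId`, `x`, `y`;
#'   one row per matched observation.
#' @export
matchCells <- function(frames, gatingRadius = 40) {
  stopIfNot(length(frames) >= 2, "need at least 2 frames",
            "insufficientDataError")
  cent <- lapply(frames, function(fr)
    if (length(fr)) t(vapply(fr, outlineCentroid, numeric(2)))
    else matrix(numeric(0), 0, 2))
  ids <- lapply(frames, function(fr)
    vapply(fr, function(o) o@cellId, character(1)))
  nTracks <- length(frames[[1]])
  if (!nTracks) return(data.frame(trackId = integer(0), frame = integer(0),
                                  cellId = character(0), x = numeric(0),
                                  y = numeric(0)))
  # track state: index of each track's cell in the current frame (NA = lost)
  cur <- seq_len(nTracks)
  rows <- data.frame(trackId = seq_len(nTracks), frame = 1L,
                     cellId = ids[[1]], x = cent[[1]][, 1],
                     y = cent[[1]][, 2])
  for (f in 2:length(frames)) {
    nxt <- rep(NA_integer_, nTracks)
    alive <- which(!is.na(cur))
    if (length(alive) && nrow(cent[[f]])) {
      prev <- cent[[f - 1]][cur[alive], , drop = FALSE]
      D <- outer(prev[, 1], cent[[f]][, 1], "-")^2 +
           outer(prev[, 2], cent[[f]][, 2], "-")^2
      D <- sqrt(D)
      cand <- which(D <= gatingRadius, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(D[cand], ids[[f]][cand[, 2]], cand[, 2], na.last = TRUE)
        cand <- cand[o, , drop = FALSE]
        usedA <- rep(FALSE, length(alive))
        usedB <- rep(FALSE, nrow(cent[[f]]))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE; usedB[j] <- TRUE
            nxt[alive[i]] <- j
          }
        }
      }
    }
    cur <- nxt
    got <- which(!is.na(cur))
    if (length(got))
      rows <- rbind(rows, data.frame(trackId = got, frame = f,
                                     cellId = ids[[f]][cur[got]],
                                     x = cent[[f]][cur[got], 1],
                                     y = cent[[f]][cur[got], 2]))
  }
  rows[order(rows$trackId, rows$frame), ]
}

#' Circularity-index trajectory across stretch levels
#'
#' Segments (or ingests) cell outlines per frame, matches cells across
#' frames, computes per-cell circularity, and fits the ordinary
#' least-squares trend of mean CI on stretch. The headline statistic is the
#' slope of the mean-CI curve; the per-cell CI table is kept for
#' inspection.
#'
#' @param frames list (one per stretch level) of lists of
#'   [CellOutline-class], e.g. from [segmentCells()].
#' @param stretch stretch ratio per frame, strictly increasing.
#' @param gatingRadius matching gate in pixels (see [matchCells()]).
#' @return a [CircularityTrajectory-class].
#' @examples
#' spec <- CellFieldSpec(nCells = 12, imageSize = 256, seed = 2)
#' lams <- c(1, 1.3, 1.6)
#' frames <- lapply(seq_along(lams), function(i)
#'   segmentCells(genCellMasks(spec, lams[i]), frame = i))
#' ciTrajectory(frames, lams)
#' @export
ciTrajectory <- function(frames, stretch, gatingRadius = 40) {
  stopIfNot(length(frames) == length(stretch) && length(frames) >= 2,
            "need >= 2 frames with matching stretch values",
            "insufficientDataError")
  matches <- matchCells(frames, gatingRadius = gatingRadius)
  stopIfNot(nrow(matches) > 0, "no matched cells across frames",
            "insufficientDataError")
  nT <- max(matches$trackId)
  nF <- length(frames)
  ci <- matrix(NA_real_, nT, nF)
  for (r in seq_len(nrow(matches))) {
    f <- matches$frame[r]
    o <- frames[[f]][[which(vapply(frames[[f]], function(x) x@cellId,
                                   character(1)) == matches$cellId[r])[1]]]
    ci[matches$trackId[r], f] <- circularity(o)
  }
  usable <- colSums(!is.na(ci)) >= 1
  stopIfNot(sum(usable) >= 2, "fewer than 2 frames with matched cells",
            "insufficientDataError")
  m <- colMeans(ci, na.rm = TRUE)
  tr <- linearTrend(stretch[usable], m[usable])
  new("CircularityTrajectory", stretch = as.numeric(stretch),
      meanCI = as.numeric(m), perCellCI = ci, slope = tr$slope,
      intercept = tr$intercept, rSquared = tr$rSquared)
}

#' Track virtual fiducial markers by normalized cross-correlation
#'
#' Frame-to-frame template matching: a square template around the marker's
#' last position is correlated against the next frame over a bounded search
#' window, the peak is refined to subpixel precision by parabolic
#' interpolation, and a marker is flagged lost (from that frame onward,
#' never interpolated) when the peak correlation falls below `corrFloor`.
#'
#' @param frames list of grayscale matrices (`[x, y]`), >= 2 frames.
#' @param seeds n x 2 matrix of initial (x, y) marker positions in frame 1.
#' @param templateRadius template half-size in pixels.
#' @param searchRadius search half-window in pixels.
#' @param corrFloor minimum acceptable peak correlation (default 0.5).
#' @return list of [MarkerTrack-class], one per seed.
#' @export
trackFiducials <- function(frames, seeds, templateRadius = 8,
                           searchRadius = 15, corrFloor = 0.5) {
  stopIfNot(length(frames) >= 2, "need at least 2 frames",
            "insufficientDataError")
  seeds <- matrix(as.numeric(seeds), ncol = 2)
  S1 <- nrow(frames[[1]]); S2 <- ncol(frames[[1]])
  stopIfNot(all(seeds[, 1] >= 1 & seeds[, 1] <= S1 &
                  seeds[, 2] >= 1 & seeds[, 2] <= S2),
            "seed point outside the first frame", "invalidSeedError")
  nF <- length(frames)
  ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(0)
    sum(a * b) / den
  }
  trackOne <- function(id, p0) {
    pos <- matrix(NA_real_, nF, 2)
    lost <- rep(FALSE, nF)
    pos[1, ] <- p0
    for (f in 2:nF) {
      if (lost[f - 1]) { lost[f] <- TRUE; next }
      c0 <- round(pos[f - 1, ])
      tr <- templateRadius
      if (c0[1] - tr < 1 || c0[1] + tr > S1 ||
          c0[2] - tr < 1 || c0[2] + tr > S2) {
        lost[f:nF] <- TRUE; break
      }
      tmpl <- frames[[f - 1]][(c0[1] - tr):(c0[1] + tr),
                              (c0[2] - tr):(c0[2] + tr)]
      offs <- -searchRadius:searchRadius
      cc <- matrix(-Inf, length(offs), length(offs))
      for (ix in seq_along(offs)) for (iy in seq_along(offs)) {
        x0 <- c0[1] + offs[ix]; y0 <- c0[2] + offs[iy]
        if (x0 - tr < 1 || x0 + tr > S1 || y0 - tr < 1 || y0 + tr > S2)
          next
        cc[ix, iy] <- ncc(tmpl, frames[[f]][(x0 - tr):(x0 + tr),
                                            (y0 - tr):(y0 + tr)])
      }
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (!is.finite(cc[pk[1], pk[2]]) || cc[pk[1], pk[2]] < corrFloor) {
        lost[f:nF] <- TRUE; break
      }
      sub <- c(0, 0)
      para <- function(l, c, r) {
        den <- l - 2 * c + r
        if (den >= 0) 0 else clamp(0.5 * (l - r) / den, -0.5, 0.5)
      }
      if (pk[1] > 1 && pk[1] < nrow(cc) &&
          is.finite(cc[pk[1] - 1, pk[2]]) && is.finite(cc[pk[1] + 1, pk[2]]))
        sub[1] <- para(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]],
                       cc[pk[1] + 1, pk[2]])
      if (pk[2] > 1 && pk[2] < ncol(cc) &&
          is.finite(cc[pk[1], pk[2] - 1]) && is.finite(cc[pk[1], pk[2] + 1]))
        sub[2] <- para(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]],
                       cc[pk[1], pk[2] + 1])
      pos[f, ] <- c0 + c(offs[pk[1]], offs[pk[2]]) + sub
    }
    new("MarkerTrack", markerId = as.character(id), positions = pos,
        lost = lost, searchWindow = searchRadius)
  }
  lapply(seq_len(nrow(seeds)), function(i) trackOne(i, seeds[i, ]))
}

#' Local stretch from fiducial marker pairs
#'
#' Per-frame local stretch: for every marker pair, the ratio of the current
#' to the initial pair separation projected on the loading axis, averaged
#' over pairs. Pairs whose initial projected separation is below 2 px are
#' rejected as unstable; purely transverse motion projects to zero change
#' and yields a local stretch of 1.
#'
#' @param tracks list of [MarkerTrack-class] (>= 2 markers).
#' @param axis loading-axis angle in degrees (default 0 = x).
#' @return numeric vector of local stretch per frame (NA where no pair
#'   survives).
#' @export
localStretch <- function(tracks, axis = 0) {
  stopIfNot(length(tracks) >= 2, "need at least 2 markers",
            "insufficientDataError")
  u <- c(cos(axis * pi / 180), sin(axis * pi / 180))
  nF <- nrow(tracks[[1]]@positions)
  prs <- utils::combn(length(tracks), 2)
  lamSum <- lamN <- numeric(nF)
  for (p in seq_len(ncol(prs))) {
    A <- tracks[[prs[1, p]]]@positions
    B <- tracks[[prs[2, p]]]@positions
    proj <- (A - B) %*% u
    stopIfNot(is.na(proj[1]) || abs(proj[1]) >= 2,
              "initial projected pair separation below 2 px",
              "unstablePairError")
    ok <- which(!is.na(proj) & !is.na(proj[1]))
    lamSum[ok] <- lamSum[ok] + abs(proj[ok]) / abs(proj[1])
    lamN[ok] <- lamN[ok] + 1
  }
  out <- lamSum / lamN
  out[lamN == 0] <- NA_real_
  out
}

#' Read external cell tracings from CSV
#'
#' Ingests manually traced outlines in the schema
#' `cell_id,frame,vertex_index,x_px,y_px`, the exchange format for
#' tracings made outside the package.
#'
#' @param path CSV path.
#' @return list (per frame, in ascending frame order) of lists of
#'   [CellOutline-class].
#' @export
readCellTracings <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "frame", "vertex_index", "x_px", "y_px")
  stopIfNot(all(need %in% names(d)), "CSV lacks tracing schema columns",
            "dataQualityError")
  fr <- sort(unique(d$frame))
  lapply(seq_along(fr), function(i) {
    di <- d[d$frame == fr[i], ]
    lapply(split(di, di$cell_id), function(dc) {
      dc <- dc[order(dc$vertex_index), ]
      CellOutline(cbind(dc$x_px, dc$y_px), cellId = as.character(dc$cell_id[1]),
                  frame = i)
    })
  })
}

#' Write a circularity trajectory to CSV
#'
#' Writes `frame,stretch,mean_ci,n_cells` rows plus one `fit` summary row
#' carrying the slope, intercept and r-squared.
#'
#' @param trajectory a [CircularityTrajectory-class].
#' @param path CSV path.
#' @return the table, invisibly.
#' @export
writeCITrajectory <- function(trajectory, path) {
  n <- colSums(!is.na(trajectory@perCellCI))
  tab <- data.frame(frame = seq_along(trajectory@stretch),
                    stretch = trajectory@stretch,
                    mean_ci = trajectory@meanCI, n_cells = n)
  utils::write.csv(tab, path, row.names = FALSE)
  cat(sprintf("fit,slope=%.6g,intercept=%.6g,r2=%.6g\n",
              trajectory@slope, trajectory@intercept, trajectory@rSquared),
      file = path, append = TRUE)
  invisible(tab)
}
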