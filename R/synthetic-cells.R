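# Circularity of an ellipse with unit semi-major axis and aspect e = b/a,
# using Ramanujan's perimeter approximation.
ellipseCI <- function(e) {
  P <- pi * (3 * (1 + e) - sqrt((3 + e) * (1 + 3 * e)))
  4 * pi * (pi * e) / P^2
}

# Aspect ratio b/a giving a target circularity.
aspectForCI <- function(ci) {
  stopIfNot(ci > 0 && ci <= 1, "target CI must lie in (0, 1]",
            "invalidSpecError")
  if (ci >= 1 - 1e-12) return(1)
  stats::uniroot(function(e) ellipseCI(e) - ci, c(1e-5, 1),
                 tol = 1e-12)$root
}

# Paint a rotated filled ellipse with the given label into an integer
# raster (matrix [x, y]); returns the raster.
paintEllipse <- function(lab, label, cx, cy, a, b, phi) {
  S1 <- nrow(lab); S2 <- ncol(lab)
  ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  xr <- max(1, floor(cx - ex - 1)):min(S1, ceiling(cx + ex + 1))
  yr <- max(1, floor(cy - ey - 1)):min(S2, ceiling(cy + ey + 1))
  if (!length(xr) || !length(yr)) return(lab)
  dx <- outer(xr - cx, rep(1, length(yr)))
  dy <- outer(rep(1, length(xr)), yr - cy)
  uu <- (dx * cos(phi) + dy * sin(phi)) / a
  vv <- (-dx * sin(phi) + dy * cos(phi)) / b
  inside <- uu^2 + vv^2 <= 1
  block <- lab[xr, yr]
  block[inside] <- label
  lab[xr, yr] <- block
  lab
}

#' Generate a labeled synthetic cell mask at a given stretch
#'
#' Renders non-overlapping elliptical cells whose measured circularity
#' index has expectation `baseCI + ciSlope * (lambda - 1)`, with additive
#' Gaussian noise of sd `noiseSD` on each cell's target CI. Cell centroids
#' follow the affine tissue stretch \eqn{(x, y) \mapsto (\lambda x,
#' \lambda^{-\nu} y)} about the image center, and label `i` marks the same
#' cell at every stretch level generated from the same spec, giving a
#' trackable ground truth.
#'
#' Frame noise is drawn from a child seed derived from the spec seed and
#' the stretch level, so each (spec, stretch) pair is reproducible in
#' isolation.
#'
#' @param spec a [CellFieldSpec-class].
#' @param stretch stretch ratio lambda >= 1.
#' @param nu transverse contraction exponent (default 0.5).
#' @return a [CellScene-class].
#' @examples
#' sc <- genCellMasks(CellFieldSpec(nCells = 20, seed = 3), stretch = 1.2)
#' @export
genCellMasks <- function(spec, stretch, nu = 0.5) {
  stopIfNot(is(spec, "CellFieldSpec"), "spec must be a CellFieldSpec",
            "invalidSpecError")
  validObject(spec)
  stopIfNot(is.numeric(stretch) && length(stretch) == 1 && stretch >= 1,
            "stretch must be a scalar >= 1", "invalidProtocolError")
  ciExp <- spec@baseCI + spec@ciSlope * (stretch - 1)
  stopIfNot(ciExp > 0 && ciExp <= 1,
            "expected CI falls outside (0, 1] at this stretch",
            "invalidSpecError")
  S <- spec@imageSize
  cen <- (S + 1) / 2
  n <- spec@nCells
  base <- withSeed(spec@seed, {
    # base positions on a jittered grid inside a region that stays in
    # frame up to lambda ~1.7 (x) while y only contracts
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
    gx <- seq(0.24, 0.76, length.out = nx) * S
    gy <- seq(0.12, 0.88, length.out = ny) * S
    pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
    jit <- min(diff(range(gx)) / max(1, nx - 1),
               diff(range(gy)) / max(1, ny - 1)) * 0.08
    list(x = pos$x + stats::runif(n, -jit, jit),
         y = pos$y + stats::runif(n, -jit, jit),
         r0 = stats::runif(n, 0.018, 0.024) * S,
         phi = stats::rnorm(n, 0, 8) * pi / 180)
  })
  ciNoise <- if (spec@noiseSD > 0)
    withSeed(childSeed(spec@seed, round(stretch * 1000)),
             stats::rnorm(n, 0, spec@noiseSD)) else numeric(n)
  ciCell <- clamp(ciExp + ciNoise, 0.02, 1)
  lab <- matrix(0L, S, S)
  truth <- data.frame(cellId = seq_len(n), x = NA_real_, y = NA_real_,
                      a = NA_real_, b = NA_real_, phiDeg = NA_real_,
                      targetCI = ciCell)
  for (i in seq_len(n)) {
    e <- aspectForCI(ciCell[i])
    a <- base$r0[i] / sqrt(e)
    b <- base$r0[i] * sqrt(e)
    cx <- cen + stretch * (base$x[i] - cen)
    cy <- cen + stretch^(-nu) * (base$y[i] - cen)
    lab <- paintEllipse(lab, i, cx, cy, a, b, base$phi[i])
    truth[i, c("x", "y", "a", "b", "phiDeg")] <-
      c(cx, cy, a, b, base$phi[i] * 180 / pi)
  }
  new("CellScene", labels = lab, truth = truth, stretch = stretch,
      spec = spec)
}
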