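#' Generate a confocal-like crimped-fiber image at a given stretch
#'
#' Renders a field of sinusoidally crimped polyline fibers. Unloaded fiber
#' orientations are drawn from an axial von Mises-type law about the loading
#' axis (x) with concentration kappa (`orientationConcentration`; 0 =
#' isotropic). The scene is then mapped by the affine stretch
#' \eqn{(x, y) \mapsto (\lambda x, \lambda^{-\nu} y)} about the image
#' center, which rotates orientations toward the axis and flattens the
#' crimp, emulating fiber un-crimping and alignment under load. Identical
#' spec + seed reproduces the raster bit-for-bit.
#'
#' @param spec a [FiberFieldSpec-class].
#' @param stretch stretch ratio lambda >= 1.
#' @param nu transverse contraction exponent (default 0.5).
#' @return a [FiberScene-class]: the grayscale raster in \[0,1\] plus the
#'   analytic post-stretch segment orientations as ground truth.
#' @examples
#' sc <- genFiberImage(FiberFieldSpec(seed = 7), stretch = 1.3)
#' @export
genFiberImage <- function(spec, stretch, nu = 0.5) {
  stopIfNot(is(spec, "FiberFieldSpec"), "spec must be a FiberFieldSpec",
            "invalidSpecError")
  validObject(spec)
  stopIfNot(is.numeric(stretch) && length(stretch) == 1 && stretch >= 1,
            "stretch must be a scalar >= 1", "invalidProtocolError")
  S <- spec@imageSize
  cen <- (S + 1) / 2
  withSeed(spec@seed, {
    n <- spec@nFibers
    phi <- rAxialOrientation(n, spec@orientationConcentration)
    cx <- stats::runif(n, 0.05 * S, 0.95 * S)
    cy <- stats::runif(n, 0.05 * S, 0.95 * S)
    len <- stats::runif(n, 0.5, 0.9) * S * 1.3
    phase <- stats::runif(n, 0, 2 * pi)
    img <- matrix(0, S, S)
    segs <- vector("list", n)
    for (i in seq_len(n)) {
      t <- seq(-len[i] / 2, len[i] / 2, by = 0.3)
      u <- c(cos(phi[i]), sin(phi[i]))
      nrm <- c(-sin(phi[i]), cos(phi[i]))
      crimp <- spec@crimpAmplitude *
        sin(2 * pi * t / spec@crimpWavelength + phase[i])
      x <- cx[i] + t * u[1] + crimp * nrm[1]
      y <- cy[i] + t * u[2] + crimp * nrm[2]
      # affine stretch about the image center
      xs <- cen + stretch * (x - cen)
      ys <- cen + stretch^(-nu) * (y - cen)
      xi <- round(xs); yi <- round(ys)
      ok <- xi >= 1 & xi <= S & yi >= 1 & yi <= S
      if (any(ok)) img[cbind(xi[ok], yi[ok])] <- 1
      # analytic ground truth on a coarser subsample of the mapped polyline
      sub <- seq(1, length(xs), by = 5)
      dx <- diff(xs[sub]); dy <- diff(ys[sub])
      keep <- dx != 0 | dy != 0
      segs[[i]] <- data.frame(
        fiber = i,
        angleDeg = (atan2(dy[keep], dx[keep]) * 180 / pi) %% 180,
        lengthPx = sqrt(dx[keep]^2 + dy[keep]^2))
    }
    stopIfNot(sum(img) > 0, "all fibers fell outside the frame",
              "degenerateSceneError")
    bw <- max(3L, 2L * floor(spec@fiberWidth / 2) + 1L)
    img <- EBImage::dilate(img, EBImage::makeBrush(bw, "disc"))
    img <- EBImage::imageData(EBImage::gblur(asImage(img), sigma = 0.7))
    dim(img) <- c(S, S)
    img <- clamp(img / max(img), 0, 1)
    new("FiberScene", image = img, segments = do.call(rbind, segs),
        stretch = stretch, spec = spec)
  })
}

#' Analytic alignment index of a synthetic fiber scene
#'
#' Brute-force alignment index computed from the generator's analytic
#' polyline orientations (fraction of total fiber length whose axial
#' orientation lies within `halfWidth` degrees of `axis`), independent of
#' any rasterization or Fourier analysis. Used as the ground-truth oracle
#' for the image-based index.
#'
#' @param scene a [FiberScene-class].
#' @param axis loading-axis angle in degrees (default 0).
#' @param halfWidth angular half-window in degrees (default 10).
#' @return a fraction in \[0, 1\].
#' @export
analyticAlignmentIndex <- function(scene, axis = 0, halfWidth = 10) {
  stopIfNot(is(scene, "FiberScene"), "scene must be a FiberScene",
            "invalidSpecError")
  seg <- scene@segments
  sum(seg$lengthPx[axialDistance(seg$angleDeg, axis) <= halfWidth]) /
    sum(seg$lengthPx)
}
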