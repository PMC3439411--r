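#' Angular power spectrum of a fiber image by 2D FFT
#'
#' Quantifies fiber orientation content: the image is mean-subtracted,
#' apodized with a 2D raised-cosine (Hann) window, Fourier transformed, and
#' the power spectrum is accumulated into orientation bins over a radial
#' annulus of the centered spectrum (DC and corner frequencies excluded).
#' A grating concentrates spectral power perpendicular to its stripes, so
#' the spectral angle is rotated by +90 degrees to refer to fiber
#' orientation; 0 degrees is the image horizontal / loading axis.
#'
#' @param image grayscale raster (matrix indexed `[x, y]`, or a
#'   [FiberScene-class]), at least 64 x 64, nonconstant.
#' @param binWidth orientation bin width in degrees (default 1).
#' @param annulus radial band in units of the Nyquist frequency (default
#'   `c(0.1, 0.8)`).
#' @param window apply the Hann apodization (default TRUE).
#' @return an [OrientationSpectrum-class].
#' @examples
#' img <- outer(1:128, 1:128, function(x, y) sin(2 * pi * y / 8))
#' sp <- orientationSpectrum(img)
#' binAngles(sp)[which.max(binPower(sp))]  # ~0 deg: stripes along x
#' @export
orientationSpectrum <- function(image, binWidth = 1,
                                annulus = c(0.1, 0.8), window = TRUE) {
  if (is(image, "FiberScene")) image <- image@image
  stopIfNot(is.matrix(image) && min(dim(image)) >= 64,
            "image must be a matrix of at least 64 x 64",
            "invalidSpecError")
  stopIfNot(180 %% binWidth == 0 || abs(180 / binWidth -
              round(180 / binWidth)) < 1e-9,
            "binWidth must divide 180", "invalidSpecError")
  stopIfNot(diff(range(image)) > 0, "constant image has no orientation power",
            "zeroPowerError")
  nx <- nrow(image); ny <- ncol(image)
  x <- image - mean(image)
  if (window) {
    hx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
    hy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
    x <- x * outer(hx, hy)
  }
  P <- Mod(stats::fft(x))^2
  # centered spectrum: index (cx, cy) holds DC after the shift
  cx <- floor(nx / 2) + 1L; cy <- floor(ny / 2) + 1L
  P <- P[c((cx):nx, seq_len(cx - 1L)), c((cy):ny, seq_len(cy - 1L))]
  # resample on a uniform polar grid: the square frequency lattice is not
  # angularly uniform (axis-aligned directions collect ~3x more samples),
  # so both diffuse and ridge-like spectra are integrated along rays with
  # the polar Jacobian instead of by lattice-sample counting
  nb <- round(180 / binWidth)
  sub <- c(-1, 0, 1) / 3 * binWidth
  ang <- (rep((seq_len(nb) - 0.5) * binWidth, each = length(sub)) +
            sub + 90) * pi / 180  # spectral angle of each fiber-angle ray
  rr <- seq(annulus[1] * 0.5, annulus[2] * 0.5,
            length.out = max(16L, ceiling(diff(annulus) * 0.5 *
                                            min(nx, ny) * 1.5)))
  FXq <- outer(cos(ang), rr)
  FYq <- outer(sin(ang), rr)
  bilin <- function(ix, iy) {
    ix <- as.vector(ix); iy <- as.vector(iy)
    i0 <- floor(ix); j0 <- floor(iy)
    wx <- ix - i0; wy <- iy - j0
    P[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
      P[cbind(i0 + 1, j0)] * wx * (1 - wy) +
      P[cbind(i0, j0 + 1)] * (1 - wx) * wy +
      P[cbind(i0 + 1, j0 + 1)] * wx * wy
  }
  vals <- bilin(FXq * nx + cx, FYq * ny + cy) * rep(rr, each = nrow(FXq))
  perRay <- rowSums(matrix(vals, nrow(FXq), length(rr)))
  pw <- colMeans(matrix(perRay, length(sub), nb))
  stopIfNot(sum(pw) > 0, "no spectral power in the annulus",
            "zeroPowerError")
  OrientationSpectrum(unname(pw), binWidth = binWidth)
}

#' Fiber alignment index from an orientation spectrum
#'
#' Fraction of total angular power whose axial distance (period 180
#' degrees) from the loading axis is at most `halfWidth` degrees. With the
#' defaults (axis 0, half-width 10) this is the fraction of Fourier power
#' within +/- 10 degrees of the image horizontal; a perfectly flat spectrum
#' gives 20/180 and a spectrum fully concentrated on the axis gives 1.
#'
#' @param spectrum an [OrientationSpectrum-class].
#' @param axis loading-axis angle, degrees.
#' @param halfWidth angular half-window in degrees, in (0, 90).
#' @return a fraction in \[0, 1\].
#' @export
fai <- function(spectrum, axis = 0, halfWidth = 10) {
  stopIfNot(is(spectrum, "OrientationSpectrum"),
            "spectrum must be an OrientationSpectrum", "invalidSpecError")
  stopIfNot(halfWidth > 0 && halfWidth < 90,
            "halfWidth must lie in (0, 90) degrees", "invalidSpecError")
  inWin <- axialDistance(spectrum@angleBins, axis) <= halfWidth
  sum(spectrum@power[inWin]) / spectrum@totalPower
}

#' Alignment-index trajectory versus stretch
#'
#' Computes the alignment index for one fiber image per stretch level and
#' fits its ordinary least-squares linear trend on stretch.
#'
#' @param images list of grayscale matrices or [FiberScene-class] objects,
#'   one per stretch level.
#' @param stretch stretch ratio per level, strictly increasing, >= 2 levels.
#' @param axis,halfWidth passed to [fai()].
#' @param ... passed to [orientationSpectrum()].
#' @return an [AlignmentTrajectory-class].
#' @export
faiTrajectory <- function(images, stretch, axis = 0, halfWidth = 10, ...) {
  stopIfNot(length(images) == length(stretch) && length(stretch) >= 2,
            "need one image per stretch level and at least 2 levels",
            "invalidSpecError")
  vals <- vapply(seq_along(images), function(i) {
    tryCatch(fai(orientationSpectrum(images[[i]], ...), axis, halfWidth),
             error = function(e) {
               stopIfNot(FALSE, paste0("stretch level ", stretch[i], ": ",
                                       conditionMessage(e)),
                         "levelFailureError")
             })
  }, numeric(1))
  tr <- linearTrend(stretch, vals)
  new("AlignmentTrajectory", stretch = as.numeric(stretch),
      fai = clamp(vals, 0, 1), slope = tr$slope, intercept = tr$intercept,
      rSquared = tr$rSquared)
}
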