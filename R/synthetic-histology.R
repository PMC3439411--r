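# Default paint colors (RGB in [0,1]) per constituent, loosely following
# the palette conventions of the supported stains.
defaultConstituentColors <- function() {
  list(collagen = c(0.85, 0.73, 0.15),          # yellow (pentachrome)
       gag = c(0.25, 0.50, 0.80),               # blue/green
       connective_tissue = c(0.20, 0.35, 0.75), # trichrome blue
       elastin = c(0.22, 0.10, 0.24),           # dark purple/black
       background = c(0.96, 0.95, 0.93))
}

#' Generate a synthetic stained slide with known area fractions
#'
#' Paints constituents in distinct colors inside an elliptical leaflet
#' mask. Spatially contiguous blobs are produced by ranking leaflet pixels
#' on a smoothed Gaussian random field and assigning quantile bands to
#' constituents, so realized pixel fractions match the request to within
#' one pixel. The remainder of the leaflet is near-white background;
#' Gaussian color noise of sd `colorNoise` is added per channel.
#'
#' @param fractions named nonnegative fractions summing to <= 1 (e.g.
#'   `c(collagen = 0.6, gag = 0.2)`); names must have configured colors.
#' @param imageSize square raster side in pixels.
#' @param seed RNG seed.
#' @param colorNoise per-channel Gaussian color noise sd (default 0.02).
#' @param colors named list of RGB triplets overriding the defaults.
#' @return a [HistologySlide-class].
#' @examples
#' sl <- genHistologySlide(c(collagen = 0.6, gag = 0.2), 128, seed = 1)
#' @export
genHistologySlide <- function(fractions, imageSize = 256, seed = 1L,
                              colorNoise = 0.02,
                              colors = defaultConstituentColors()) {
  stopIfNot(length(fractions) >= 1 && !is.null(names(fractions)) &&
              all(names(fractions) != ""),
            "fractions must be a named vector", "invalidSpecError")
  stopIfNot(all(fractions >= 0), "fractions must be nonnegative",
            "invalidSpecError")
  stopIfNot(sum(fractions) <= 1 + 1e-12,
            "constituent fractions sum to more than 1", "invalidSpecError")
  stopIfNot(all(names(fractions) %in% names(colors)),
            "no configured color for some constituent", "configError")
  S <- as.integer(imageSize)
  cen <- (S + 1) / 2
  xx <- matrix(seq_len(S), S, S)
  yy <- t(xx)
  leaflet <- ((xx - cen) / (0.42 * S))^2 + ((yy - cen) / (0.30 * S))^2 <= 1
  idxLeaf <- which(leaflet)
  N <- length(idxLeaf)
  withSeed(seed, {
    field <- matrix(stats::rnorm(S * S), S, S)
    field <- EBImage::imageData(EBImage::gblur(asImage(field),
                                               sigma = S / 24))
    dim(field) <- c(S, S)
    ord <- idxLeaf[order(field[idxLeaf], decreasing = TRUE)]
    rgb <- array(1, c(S, S, 3))
    bg <- colors$background
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[idxLeaf] <- bg[ch]
      rgb[, , ch] <- plane
    }
    truth <- list()
    at <- 0L
    for (nm in names(fractions)) {
      nPix <- round(fractions[[nm]] * N)
      mask <- matrix(FALSE, S, S)
      if (nPix > 0) {
        take <- ord[(at + 1L):min(N, at + nPix)]
        at <- at + length(take)
        mask[take] <- TRUE
        col <- colors[[nm]]
        for (ch in 1:3) {
          plane <- rgb[, , ch]
          plane[take] <- col[ch]
          rgb[, , ch] <- plane
        }
      }
      truth[[nm]] <- mask
    }
    if (colorNoise > 0)
      rgb <- clamp(rgb + stats::rnorm(length(rgb), 0, colorNoise), 0, 1)
    new("HistologySlide", rgb = rgb, leafletMask = leaflet,
        truthMasks = truth,
        requestedFractions = unlist(fractions))
  })
}
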