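# Rasters are held in memory as [x, y] (x rightward = loading axis);
# TIFF files are row-major [y, x], so transpose at the file boundary.

#' Write a synthetic scene to TIFF with a ground-truth sidecar
#'
#' Fiber scenes are written as grayscale TIFF, cell scenes as 16-bit
#' labeled TIFF (labels scaled by 1/65535), under the filename pattern
#' `<prefix>_l<stretch>.tif` (stretch printed with two decimals). A YAML
#' sidecar `<prefix>_l<stretch>.yaml` records the generating spec and the
#' scene's ground truth.
#'
#' @param scene a [FiberScene-class] or [CellScene-class].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix (default `"scene"`).
#' @return the TIFF path, invisibly.
#' @export
writeScene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_l%.2f", prefix, scene@stretch))
  tif <- paste0(stem, ".tif")
  if (is(scene, "FiberScene")) {
    tiff::writeTIFF(t(scene@image), tif, bits.per.sample = 8)
    spec <- scene@spec
    yaml::write_yaml(list(
      type = "fiber", stretch = scene@stretch,
      spec = list(n_fibers = spec@nFibers, image_size = spec@imageSize,
                  crimp_amplitude = spec@crimpAmplitude,
                  crimp_wavelength = spec@crimpWavelength,
                  orientation_concentration = spec@orientationConcentration,
                  fiber_width = spec@fiberWidth, seed = spec@seed),
      analytic_fai = analyticAlignmentIndex(scene)), paste0(stem, ".yaml"))
  } else if (is(scene, "CellScene")) {
    tiff::writeTIFF(t(scene@labels) / 65535, tif, bits.per.sample = 16)
    spec <- scene@spec
    yaml::write_yaml(list(
      type = "cell", stretch = scene@stretch,
      spec = list(n_cells = spec@nCells, image_size = spec@imageSize,
                  base_ci = spec@baseCI, ci_slope = spec@ciSlope,
                  noise_sd = spec@noiseSD, seed = spec@seed),
      cells = lapply(seq_len(nrow(scene@truth)), function(i)
        as.list(scene@truth[i, ]))), paste0(stem, ".yaml"))
  } else {
    stopIfNot(FALSE, "scene must be a FiberScene or CellScene",
              "invalidSpecError")
  }
  invisible(tif)
}

#' Read a grayscale or labeled raster from TIFF
#'
#' Returns the `[x, y]`-indexed matrix; `labeled = TRUE` rescales a 16-bit
#' label file back to integer labels.
#'
#' @param path TIFF path.
#' @param labeled read as a 16-bit labeled mask (default FALSE).
#' @return a numeric (or integer, if labeled) matrix.
#' @export
readSceneImage <- function(path, labeled = FALSE) {
  img <- t(tiff::readTIFF(path))
  if (labeled) {
    img <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  }
  img
}

#' Alignment trajectory from a directory of per-stretch TIFFs
#'
#' Reads a manifest CSV with columns `filename,stretch`, loads each image
#' and returns the fitted [AlignmentTrajectory-class]. The companion
#' writer emits a `stretch,fai` CSV with a trailing fit-summary line.
#'
#' @param dir directory containing the TIFFs and the manifest.
#' @param manifest manifest filename (default `"manifest.csv"`).
#' @param ... passed to [faiTrajectory()].
#' @return an [AlignmentTrajectory-class].
#' @export
faiTrajectoryFromDir <- function(dir, manifest = "manifest.csv", ...) {
  man <- utils::read.csv(file.path(dir, manifest))
  stopIfNot(all(c("filename", "stretch") %in% names(man)),
            "manifest needs filename,stretch columns", "configError")
  man <- man[order(man$stretch), ]
  imgs <- lapply(file.path(dir, man$filename), readSceneImage)
  faiTrajectory(imgs, man$stretch, ...)
}

#' @param trajectory an [AlignmentTrajectory-class].
#' @param path CSV path.
#' @rdname faiTrajectoryFromDir
#' @export
writeFAITrajectory <- function(trajectory, path) {
  tab <- data.frame(stretch = trajectory@stretch, fai = trajectory@fai)
  utils::write.csv(tab, path, row.names = FALSE)
  cat(sprintf("fit,slope=%.6g,intercept=%.6g,r2=%.6g\n",
              trajectory@slope, trajectory@intercept, trajectory@rSquared),
      file = path, append = TRUE)
  invisible(tab)
}
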