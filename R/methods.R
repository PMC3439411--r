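#' @describeIn accessors fitted (alpha, beta) of a FungFit.
#' @export
setMethod("coef", "FungFit", function(object, ...)
  c(alpha = object@alpha, beta = object@beta))

#' @describeIn accessors effective tangent modulus (Pa) stored in a FungFit.
#' @export
setMethod("effModulus", "FungFit", function(object) object@effModulus)

#' @describeIn accessors coefficient of determination.
#' @export
setMethod("rSquared", "FungFit", function(object) object@rSquared)

#' @export
setMethod("rSquared", "CircularityTrajectory", function(object) object@rSquared)

#' @export
setMethod("rSquared", "AlignmentTrajectory", function(object) object@rSquared)

#' @describeIn accessors linear-trend slope of a trajectory.
#' @export
setMethod("trendSlope", "CircularityTrajectory", function(object) object@slope)

#' @export
setMethod("trendSlope", "AlignmentTrajectory", function(object) object@slope)

#' @describeIn accessors linear-trend intercept of a trajectory.
#' @export
setMethod("trendIntercept", "CircularityTrajectory",
          function(object) object@intercept)

#' @export
setMethod("trendIntercept", "AlignmentTrajectory",
          function(object) object@intercept)

#' @describeIn accessors stretch ratios of a record or trajectory.
#' @export
setMethod("stretchLevels", "StressStrainCurve", function(object) object@stretch)

#' @export
setMethod("stretchLevels", "CircularityTrajectory",
          function(object) object@stretch)

#' @export
setMethod("stretchLevels", "AlignmentTrajectory", function(object) object@stretch)

#' @describeIn accessors nominal stresses (Pa) of a curve.
#' @export
setMethod("stressValues", "StressStrainCurve", function(object) object@stress)

#' @describeIn accessors grayscale raster of a fiber scene.
#' @export
setMethod("sceneImage", "FiberScene", function(object) object@image)

#' @describeIn accessors labeled raster of a cell scene.
#' @export
setMethod("cellLabels", "CellScene", function(object) object@labels)

#' @describeIn accessors analytic ground truth of a synthetic scene.
#' @export
setMethod("groundTruth", "FiberScene", function(object) object@segments)

#' @export
setMethod("groundTruth", "CellScene", function(object) object@truth)

#' @export
setMethod("groundTruth", "HistologySlide",
          function(object) object@truthMasks)

#' @describeIn accessors orientation-bin centers (degrees).
#' @export
setMethod("binAngles", "OrientationSpectrum", function(object) object@angleBins)

#' @describeIn accessors per-bin angular power.
#' @export
setMethod("binPower", "OrientationSpectrum", function(object) object@power)

#' @describeIn accessors total annulus power.
#' @export
setMethod("totalPower", "OrientationSpectrum",
          function(object) object@totalPower)

#' @describeIn accessors alignment-index values of a trajectory.
#' @export
setMethod("faiValues", "AlignmentTrajectory", function(object) object@fai)

#' @describeIn accessors mean circularity per stretch level.
#' @export
setMethod("meanCI", "CircularityTrajectory", function(object) object@meanCI)

#' @describeIn accessors named constituent area fractions.
#' @export
setMethod("fractions", "CompositionFractions", function(object)
  object@fractions)

#' @describeIn accessors collagen/GAG fractional ratio (NA when undefined).
#' @export
setMethod("collagenGagRatio", "CompositionFractions",
          function(object) object@collagenGagRatio)

#' @describeIn accessors leaflet area in pixels.
#' @export
setMethod("leafletArea", "CompositionFractions",
          function(object) object@leafletArea)

#' @describeIn accessors p-value of a comparison.
#' @export
setMethod("pValue", "ComparisonResult", function(object) object@pValue)

#' @describeIn accessors test statistic of a comparison.
#' @export
setMethod("testStatistic", "ComparisonResult", function(object)
  object@statistic)

#' @describeIn accessors compact letter display, named by group.
#' @export
setMethod("letterDisplay", "ComparisonResult", function(object) {
  l <- object@letters
  names(l) <- object@groups
  l
})

setMethod("show", "PostGeometry", function(object) {
  k <- 3 * object@elasticModulus * pi * object@diameter^4 / 64 /
    object@length^3
  cat("PostGeometry: d =", object@diameter * 1e3, "mm, L =",
      object@length * 1e3, "mm, E =", object@elasticModulus / 1e6,
      "MPa, s0 =", object@baseSeparation * 1e6, "um\n")
  cat("  bending stiffness k = 3EI/L^3 =", signif(k, 4), "N/m\n")
})

setMethod("show", "TissueModel", function(object) {
  cat("TissueModel (sigma = alpha (exp(beta eps) - 1)):",
      "alpha =", object@alpha, "Pa, beta =", object@beta, "\n")
  cat("  cross-section", object@width * 1e3, "x",
      object@thickness * 1e6 / 1e3, "mm, rest length",
      object@restLength * 1e6, "um\n")
})

setMethod("show", "StressStrainCurve", function(object) {
  cat("StressStrainCurve:", length(object@stretch), "points, lambda in [",
      min(object@stretch), ",", max(object@stretch), "], peak stress",
      signif(max(object@stress), 4), "Pa\n")
})

setMethod("show", "FungFit", function(object) {
  cat("FungFit: alpha =", signif(object@alpha, 5), "Pa, beta =",
      signif(object@beta, 5), "\n")
  cat("  effective modulus", signif(object@effModulus / 1e6, 4),
      "MPa at eps_ref =", object@epsRef, "; r^2 =",
      signif(object@rSquared, 4), "\n")
})

setMethod("show", "OrientationSpectrum", function(object) {
  cat("OrientationSpectrum:", length(object@angleBins), "bins of",
      object@binWidth, "deg; peak at",
      object@angleBins[which.max(object@power)], "deg\n")
})

setMethod("show", "CircularityTrajectory", function(object) {
  cat("CircularityTrajectory:", length(object@stretch), "levels,",
      nrow(object@perCellCI), "cells; slope =", signif(object@slope, 4),
      "per unit stretch (r^2 =", signif(object@rSquared, 3), ")\n")
})

setMethod("show", "AlignmentTrajectory", function(object) {
  cat("AlignmentTrajectory:", length(object@stretch), "levels; slope =",
      signif(object@slope, 4), "per unit stretch (r^2 =",
      signif(object@rSquared, 3), ")\n")
})

setMethod("show", "FiberScene", function(object) {
  cat("FiberScene:", nrow(object@image), "x", ncol(object@image),
      "raster at lambda =", object@stretch, ";", object@spec@nFibers,
      "fibers, kappa =", object@spec@orientationConcentration, "\n")
})

setMethod("show", "CellScene", function(object) {
  cat("CellScene:", nrow(object@labels), "x", ncol(object@labels),
      "labeled raster at lambda =", object@stretch, ";",
      nrow(object@truth), "cells\n")
})

setMethod("show", "CompositionFractions", function(object) {
  cat("CompositionFractions over", object@leafletArea, "leaflet px:\n")
  for (nm in names(object@fractions))
    cat("  ", nm, "=", signif(object@fractions[[nm]], 4), "\n")
  if (object@ratioDefined)
    cat("  collagen/GAG ratio =", signif(object@collagenGagRatio, 4), "\n")
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult:", object@test, "; statistic =",
      signif(object@statistic, 5), ", p =", signif(object@pValue, 4), "\n")
  if (length(object@letters))
    cat("  letters:", paste(object@groups, object@letters, sep = ":",
                            collapse = "  "), "\n")
})
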