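#' Cantilever post geometry
#'
#' Dimensions and material modulus of one cylindrical elastomeric cantilever
#' post. The pair of posts is the force transducer of the miniature uniaxial
#' stretch device: tissue tension deflects each post, and classical
#' Euler-Bernoulli beam mechanics converts the measured tip deflection to
#' force.
#'
#' @slot diameter post diameter in m.
#' @slot length free (axial) post length in m.
#' @slot elasticModulus elastomer Young's modulus in Pa.
#' @slot baseSeparation rest tip-to-tip post separation in m.
#'
#' @seealso [postBendingStiffness()], [simulateTwoPostTest()]
#' @export
setClass("PostGeometry",
  representation(diameter = "numeric", length = "numeric",
                 elasticModulus = "numeric", baseSeparation = "numeric"),
  validity = function(object) {
    v <- c(object@diameter, object@length, object@elasticModulus,
           object@baseSeparation)
    if (length(v) != 4 || any(!is.finite(v)) || any(v <= 0))
      return("all geometry fields must be finite scalars > 0")
    TRUE
  })

#' @param diameter,length,elasticModulus,baseSeparation see slots.
#' @rdname PostGeometry-class
#' @return a `PostGeometry` object.
#' @examples
#' PostGeometry(diameter = 2e-3, length = 6e-3,
#'              elasticModulus = 1e6, baseSeparation = 500e-6)
#' @export
PostGeometry <- function(diameter = 2e-3, length = 6e-3,
                         elasticModulus = 1e6, baseSeparation = 500e-6) {
  new("PostGeometry", diameter = diameter, length = length,
      elasticModulus = elasticModulus, baseSeparation = baseSeparation)
}

#' Exponential (Fung-type) tissue model
#'
#' Ground-truth constitutive description of a uniaxial specimen: nominal
#' stress follows \eqn{\sigma = \alpha (e^{\beta \epsilon} - 1)} with
#' engineering strain \eqn{\epsilon = \lambda - 1}, on a rectangular
#' cross-section `width` x `thickness` at rest length `restLength`.
#'
#' @slot alpha stress scale, Pa.
#' @slot beta dimensionless nonlinearity parameter.
#' @slot width specimen width in m.
#' @slot thickness specimen thickness in m.
#' @slot restLength rest (gauge) length in m.
#' @export
setClass("TissueModel",
  representation(alpha = "numeric", beta = "numeric", width = "numeric",
                 thickness = "numeric", restLength = "numeric"),
  validity = function(object) {
    v <- c(object@alpha, object@beta, object@width, object@thickness,
           object@restLength)
    if (any(!is.finite(v))) return("all fields must be finite")
    if (object@alpha < 0 || object@beta <= 0)
      return("alpha must be >= 0 and beta > 0")
    if (any(c(object@width, object@thickness, object@restLength) <= 0))
      return("all dimensions must be > 0")
    TRUE
  })

#' @param alpha,beta,width,thickness,restLength see slots. `alpha = 0` is
#'   accepted as the degenerate "no tissue" limit used in null simulations.
#' @rdname TissueModel-class
#' @return a `TissueModel` object.
#' @examples
#' TissueModel(alpha = 0.02e6, beta = 8)
#' @export
TissueModel <- function(alpha, beta, width = 1e-3, thickness = 40e-6,
                        restLength = 500e-6) {
  new("TissueModel", alpha = alpha, beta = beta, width = width,
      thickness = thickness, restLength = restLength)
}

#' Uniaxial stress-stretch record
#'
#' A stretch-ordered record of nominal (first Piola) stress versus stretch
#' ratio for one specimen, with the undeformed cross-section used to refer
#' force to stress.
#'
#' @slot stretch stretch ratios \eqn{\lambda \ge 1}, strictly increasing.
#' @slot stress nominal stresses in Pa, same length as `stretch`.
#' @slot specimenWidth undeformed width in m.
#' @slot specimenThickness undeformed thickness in m.
#' @seealso [fitFung()]
#' @export
setClass("StressStrainCurve",
  representation(stretch = "numeric", stress = "numeric",
                 specimenWidth = "numeric", specimenThickness = "numeric"),
  validity = function(object) {
    if (length(object@stretch) != length(object@stress))
      return("stretch and stress must have equal length")
    if (length(object@stretch) < 3)
      return("need at least 3 points")
    if (any(object@stretch < 1))
      return("stretch ratios must be >= 1")
    if (any(diff(object@stretch) <= 0))
      return("stretch must be strictly increasing")
    if (any(c(object@specimenWidth, object@specimenThickness) <= 0))
      return("specimen dimensions must be > 0")
    TRUE
  })

#' @param stretch,stress,specimenWidth,specimenThickness see slots.
#' @rdname StressStrainCurve-class
#' @return a `StressStrainCurve`.
#' @export
StressStrainCurve <- function(stretch, stress, specimenWidth = 1e-3,
                              specimenThickness = 40e-6) {
  new("StressStrainCurve", stretch = as.numeric(stretch),
      stress = as.numeric(stress), specimenWidth = specimenWidth,
      specimenThickness = specimenThickness)
}

#' Fitted exponential constitutive law
#'
#' Result of least-squares fitting \eqn{\sigma = \alpha(e^{\beta\epsilon}-1)}
#' to a [StressStrainCurve], together with the tangent (effective) modulus
#' \eqn{d\sigma/d\epsilon = \alpha\beta e^{\beta\epsilon_{ref}}} evaluated at
#' the reference strain used.
#'
#' @slot alpha fitted stress scale, Pa.
#' @slot beta fitted nonlinearity, dimensionless.
#' @slot effModulus tangent modulus at `epsRef`, Pa.
#' @slot epsRef reference engineering strain of the reported modulus.
#' @slot residualNorm root-sum-of-squares residual, Pa.
#' @slot rSquared coefficient of determination of the fit.
#' @export
setClass("FungFit",
  representation(alpha = "numeric", beta = "numeric", effModulus = "numeric",
                 epsRef = "numeric", residualNorm = "numeric",
                 rSquared = "numeric"),
  validity = function(object) {
    if (object@alpha <= 0 || object@beta <= 0)
      return("fitted alpha and beta must be > 0")
    if (!is.finite(object@rSquared) || object@rSquared > 1 + 1e-12)
      return("rSquared must be finite and <= 1")
    TRUE
  })

#' Fiber-field scene specification
#'
#' Parameters of the synthetic fiber channel: a field of sinusoidally crimped
#' fibers whose orientations are drawn from an axial (period-180 degree)
#' von Mises-type distribution about the loading axis with concentration
#' `orientationConcentration` (0 = isotropic). Emulates a fluorescently
#' labeled matrix-fiber channel imaged at stepped stretch levels.
#'
#' @slot nFibers number of fibers, >= 1.
#' @slot imageSize square raster side, pixels.
#' @slot crimpAmplitude unloaded crimp amplitude, pixels.
#' @slot crimpWavelength crimp wavelength, pixels, > 0.
#' @slot orientationConcentration concentration kappa >= 0 of the axial
#'   orientation law.
#' @slot fiberWidth drawn fiber width, pixels.
#' @slot seed RNG seed; identical spec + seed gives a bit-identical raster.
#' @seealso [genFiberImage()]
#' @export
setClass("FiberFieldSpec",
  representation(nFibers = "integer", imageSize = "integer",
                 crimpAmplitude = "numeric", crimpWavelength = "numeric",
                 orientationConcentration = "numeric", fiberWidth = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nFibers < 1L) return("nFibers must be >= 1")
    if (object@imageSize < 64L) return("imageSize must be >= 64")
    if (object@crimpWavelength <= 0) return("crimpWavelength must be > 0")
    if (object@orientationConcentration < 0) return("kappa must be >= 0")
    if (object@fiberWidth <= 0) return("fiberWidth must be > 0")
    TRUE
  })

#' @param nFibers,imageSize,crimpAmplitude,crimpWavelength see slots.
#' @param orientationConcentration,fiberWidth,seed see slots.
#' @rdname FiberFieldSpec-class
#' @return a `FiberFieldSpec`.
#' @export
FiberFieldSpec <- function(nFibers = 60, imageSize = 256,
                           crimpAmplitude = 1.5, crimpWavelength = 64,
                           orientationConcentration = 2, fiberWidth = 2,
                           seed = 1L) {
  new("FiberFieldSpec", nFibers = as.integer(nFibers),
      imageSize = as.integer(imageSize), crimpAmplitude = crimpAmplitude,
      crimpWavelength = crimpWavelength,
      orientationConcentration = orientationConcentration,
      fiberWidth = fiberWidth, seed = as.integer(seed))
}

#' Cell-field scene specification
#'
#' Parameters of the synthetic cell channel: elliptical cells whose measured
#' circularity index has expectation `baseCI + ciSlope * (lambda - 1)` at
#' stretch lambda, with additive Gaussian noise of sd `noiseSD` on the
#' per-cell target CI. Cell labels are stable across stretch levels for a
#' fixed seed.
#'
#' @slot nCells number of cells.
#' @slot imageSize square raster side, pixels.
#' @slot baseCI circularity at rest (lambda = 1), in (0, 1].
#' @slot ciSlope change in CI per unit stretch (typically negative).
#' @slot noiseSD per-cell, per-frame Gaussian noise sd on CI, >= 0.
#' @slot seed RNG seed.
#' @seealso [genCellMasks()]
#' @export
setClass("CellFieldSpec",
  representation(nCells = "integer", imageSize = "integer", baseCI = "numeric",
                 ciSlope = "numeric", noiseSD = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nCells < 1L) return("nCells must be >= 1")
    if (object@imageSize < 64L) return("imageSize must be >= 64")
    if (object@baseCI <= 0 || object@baseCI > 1)
      return("baseCI must lie in (0, 1]")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    TRUE
  })

#' @param nCells,imageSize,baseCI,ciSlope,noiseSD,seed see slots.
#' @rdname CellFieldSpec-class
#' @return a `CellFieldSpec`.
#' @export
CellFieldSpec <- function(nCells = 50, imageSize = 512, baseCI = 0.9,
                          ciSlope = -0.3, noiseSD = 0.01, seed = 1L) {
  new("CellFieldSpec", nCells = as.integer(nCells),
      imageSize = as.integer(imageSize), baseCI = baseCI, ciSlope = ciSlope,
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' Rendered fiber scene
#'
#' A rasterized synthetic fiber field at one stretch level, with its analytic
#' ground truth: the post-stretch orientation and length of every rendered
#' polyline segment, which downstream alignment analysis can be validated
#' against.
#'
#' @slot image grayscale raster in \[0,1\], indexed `[x, y]`.
#' @slot segments data.frame with columns `fiber`, `angleDeg` (axial, degrees
#'   in \[0,180)), `lengthPx` per rendered segment.
#' @slot stretch stretch ratio of the scene.
#' @slot spec the generating [FiberFieldSpec-class].
#' @export
setClass("FiberScene",
  representation(image = "matrix", segments = "data.frame",
                 stretch = "numeric", spec = "FiberFieldSpec"))

#' Rendered cell scene
#'
#' A labeled synthetic cell mask at one stretch level. Label `i` marks cell
#' `i` at every stretch level generated from the same spec, so trajectories
#' can be validated against the generator's targets.
#'
#' @slot labels integer raster, 0 = background, `i` = cell i, indexed `[x, y]`.
#' @slot truth data.frame with per-cell ground truth (`cellId`, centroid
#'   `x`, `y`, semi-axes `a`, `b`, orientation `phiDeg`, `targetCI`).
#' @slot stretch stretch ratio of the scene.
#' @slot spec the generating [CellFieldSpec-class].
#' @export
setClass("CellScene",
  representation(labels = "matrix", truth = "data.frame", stretch = "numeric",
                 spec = "CellFieldSpec"))

#' Angular power spectrum of a fiber image
#'
#' Distribution of 2D Fourier power over fiber orientation, on bins covering
#' \[0, 180) degrees exactly once (centers at `binWidth * (k + 1/2)`). Power
#' is accumulated over a radial annulus of the centered spectrum; the
#' spectral angle is rotated by 90 degrees so bins refer to fiber (stripe)
#' orientation, with 0 = loading axis.
#'
#' @slot angleBins bin centers, degrees.
#' @slot power nonnegative power per bin; sums to `totalPower`.
#' @slot totalPower total annulus power.
#' @slot binWidth bin width, degrees.
#' @seealso [orientationSpectrum()], [fai()]
#' @export
setClass("OrientationSpectrum",
  representation(angleBins = "numeric", power = "numeric",
                 totalPower = "numeric", binWidth = "numeric"),
  validity = function(object) {
    if (length(object@angleBins) != length(object@power))
      return("angleBins and power must have equal length")
    if (any(object@power < 0)) return("power must be nonnegative")
    if (abs(sum(object@power) - object@totalPower) >
        1e-8 * max(1, object@totalPower))
      return("power must sum to totalPower")
    if (abs(length(object@angleBins) * object@binWidth - 180) > 1e-9)
      return("bins must tile [0, 180) exactly")
    TRUE
  })

#' @param power nonnegative power per bin over \[0, 180).
#' @param binWidth bin width in degrees; `length(power) * binWidth` must
#'   equal 180.
#' @rdname OrientationSpectrum-class
#' @return an `OrientationSpectrum`.
#' @export
OrientationSpectrum <- function(power, binWidth = 180 / length(power)) {
  n <- length(power)
  new("OrientationSpectrum", angleBins = (seq_len(n) - 0.5) * binWidth,
      power = as.numeric(power), totalPower = sum(power), binWidth = binWidth)
}

#' Circularity-index trajectory
#'
#' Mean cell circularity index per stretch level with its ordinary
#' least-squares linear trend, plus the per-cell CI table for inspection.
#'
#' @slot stretch stretch ratios, strictly increasing.
#' @slot meanCI mean CI per level.
#' @slot perCellCI matrix (cells x levels) of per-cell CI, NA where a cell
#'   was not measured.
#' @slot slope,intercept,rSquared OLS fit of mean CI on stretch.
#' @export
setClass("CircularityTrajectory",
  representation(stretch = "numeric", meanCI = "numeric",
                 perCellCI = "matrix", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric"),
  validity = function(object) {
    if (any(diff(object@stretch) <= 0))
      return("stretch must be strictly increasing")
    if (length(object@stretch) != length(object@meanCI))
      return("stretch and meanCI must have equal length")
    ci <- object@meanCI
    if (any(ci <= 0 | ci > 1 + 0.05))
      return("mean CI values must lie in (0, 1] up to discretization")
    TRUE
  })

#' Fiber-alignment trajectory
#'
#' Fiber alignment index per stretch level with its ordinary least-squares
#' linear trend.
#'
#' @slot stretch stretch ratios, strictly increasing.
#' @slot fai alignment index per level, in \[0, 1\].
#' @slot slope,intercept,rSquared OLS fit of FAI on stretch.
#' @export
setClass("AlignmentTrajectory",
  representation(stretch = "numeric", fai = "numeric", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric"),
  validity = function(object) {
    if (any(diff(object@stretch) <= 0))
      return("stretch must be strictly increasing")
    if (length(object@stretch) != length(object@fai))
      return("stretch and fai must have equal length")
    if (any(object@fai < 0 | object@fai > 1))
      return("fai values must lie in [0, 1]")
    TRUE
  })

#' Cell outline polygon
#'
#' A simple planar polygon tracing one cell in one frame, in pixel
#' coordinates (origin top-left, x rightward along the loading axis).
#'
#' @slot cellId cell label.
#' @slot frame frame index (1-based).
#' @slot vertices n x 2 matrix of (x, y) vertices, n >= 3.
#' @export
setClass("CellOutline",
  representation(cellId = "character", frame = "integer",
                 vertices = "matrix"),
  validity = function(object) {
    if (nrow(object@vertices) < 3) return("need at least 3 vertices")
    if (ncol(object@vertices) != 2) return("vertices must be n x 2")
    TRUE
  })

#' @param cellId,frame,vertices see slots.
#' @rdname CellOutline-class
#' @return a `CellOutline`.
#' @export
CellOutline <- function(vertices, cellId = "cell", frame = 1L) {
  new("CellOutline", cellId = as.character(cellId), frame = as.integer(frame),
      vertices = as.matrix(vertices))
}

#' Fiducial marker track
#'
#' Per-frame positions of one virtual fiducial marker followed by normalized
#' cross-correlation template matching. Once tracking fails the marker is
#' flagged lost for every later frame; lost positions are NA and never
#' interpolated.
#'
#' @slot markerId marker label.
#' @slot positions n_frames x 2 matrix of (x, y), NA once lost.
#' @slot lost logical per frame, TRUE from the first failed frame onward.
#' @slot searchWindow half-width of the search window, pixels.
#' @export
setClass("MarkerTrack",
  representation(markerId = "character", positions = "matrix",
                 lost = "logical", searchWindow = "numeric"),
  validity = function(object) {
    if (nrow(object@positions) != length(object@lost))
      return("one lost flag per frame required")
    if (any(diff(object@lost) < 0))
      return("lost flags cannot revert to FALSE")
    TRUE
  })

#' Stain color-classification profile
#'
#' Per-constituent color rules for a histological stain. Each rule names its
#' channel space (`cmyk`, `rgb_diff`, or `inv_luminance`), the channel(s) it
#' uses, and a threshold policy (`"otsu"` or a fixed value in \[0,1\]).
#'
#' @slot stainName one of `movat`, `trichrome`, `vvg`.
#' @slot rules named list of per-constituent rules.
#' @seealso [stainProfile()], [splitConstituents()]
#' @export
setClass("StainProfile",
  representation(stainName = "character", rules = "list"),
  validity = function(object) {
    if (!object@stainName %in% c("movat", "trichrome", "vvg"))
      return("stainName must be one of movat, trichrome, vvg")
    if (is.null(names(object@rules)) || any(names(object@rules) == ""))
      return("every rule must be named by its constituent")
    for (r in object@rules) {
      if (is.null(r$space) ||
          !r$space %in% c("cmyk", "rgb_diff", "inv_luminance"))
        return("every rule must name a known channel space")
    }
    TRUE
  })

#' Synthetic stained slide
#'
#' An RGB histology raster with its leaflet mask and the painted
#' ground-truth constituent masks.
#'
#' @slot rgb numeric array `[x, y, 3]` in \[0,1\].
#' @slot leafletMask logical matrix `[x, y]`, TRUE inside the leaflet.
#' @slot truthMasks named list of logical ground-truth constituent masks.
#' @slot requestedFractions named numeric, the requested area fractions.
#' @export
setClass("HistologySlide",
  representation(rgb = "array", leafletMask = "matrix", truthMasks = "list",
                 requestedFractions = "numeric"))

#' Constituent area fractions
#'
#' Per-constituent area fractions of a stained section, normalized to the
#' leaflet area, with the collagen/GAG ratio attached when both constituents
#' are defined (NA with `ratioDefined = FALSE` when the GAG fraction is 0).
#'
#' @slot fractions named numeric in \[0,1\].
#' @slot leafletArea leaflet area in pixels.
#' @slot collagenGagRatio collagen fraction / GAG fraction, or NA.
#' @slot ratioDefined FALSE when the ratio is undefined (zero GAG area).
#' @export
setClass("CompositionFractions",
  representation(fractions = "numeric", leafletArea = "numeric",
                 collagenGagRatio = "numeric", ratioDefined = "logical"),
  validity = function(object) {
    f <- object@fractions
    if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
    if (object@leafletArea <= 0) return("leafletArea must be > 0")
    TRUE
  })

#' Group-comparison result
#'
#' Result of a one-way ANOVA with Tukey HSD post hoc, or of a two-sample
#' t-test. For Tukey results each group carries a compact letter display:
#' groups sharing no letter differ at level `alpha`.
#'
#' @slot test test name.
#' @slot statistic test statistic (F or t).
#' @slot pValue omnibus or test p-value.
#' @slot df degrees of freedom (length 1 for t, 2 for F).
#' @slot alpha significance level used.
#' @slot groups group labels.
#' @slot letters compact letter display per group (empty for t-tests).
#' @slot pairs data.frame of pairwise comparisons (Tukey-adjusted p for
#'   ANOVA; single row for t-tests), or a zero-row data.frame.
#' @export
setClass("ComparisonResult",
  representation(test = "character", statistic = "numeric",
                 pValue = "numeric", df = "numeric", alpha = "numeric",
                 groups = "character", letters = "character",
                 pairs = "data.frame"),
  validity = function(object) {
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  })
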