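#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes; prefer these
#' over direct slot access.
#'
#' @param x,object an object of one of the package's S4 classes.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("effModulus", function(object) standardGeneric("effModulus"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("trendSlope", function(object) standardGeneric("trendSlope"))

#' @rdname accessors
#' @export
setGeneric("trendIntercept", function(object) standardGeneric("trendIntercept"))

#' @rdname accessors
#' @export
setGeneric("stretchLevels", function(object) standardGeneric("stretchLevels"))

#' @rdname accessors
#' @export
setGeneric("stressValues", function(object) standardGeneric("stressValues"))

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("binAngles", function(object) standardGeneric("binAngles"))

#' @rdname accessors
#' @export
setGeneric("binPower", function(object) standardGeneric("binPower"))

#' @rdname accessors
#' @export
setGeneric("totalPower", function(object) standardGeneric("totalPower"))

#' @rdname accessors
#' @export
setGeneric("faiValues", function(object) standardGeneric("faiValues"))

#' @rdname accessors
#' @export
setGeneric("meanCI", function(object) standardGeneric("meanCI"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("collagenGagRatio", function(object) standardGeneric("collagenGagRatio"))

#' @rdname accessors
#' @export
setGeneric("leafletArea", function(object) standardGeneric("leafletArea"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname accessors
#' @export
setGeneric("letterDisplay", function(object) standardGeneric("letterDisplay"))
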