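#' @include AllClasses.R
NULL

#' Accessors for calibration objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{channelName} returns the channel label of a fit, \code{slope},
#' \code{intercept} and \code{rSquared} the linear-fit parameters,
#' \code{grayWeights} the named grayscale weight vector, \code{channelFit}
#' and \code{exponentialFit} extract per-channel fits from a
#' \code{\linkS4class{CalibrationModel}}, \code{mlssHat} and
#' \code{predictionFlags} unpack a \code{\linkS4class{Prediction}}, and
#' \code{rgbValues} returns the (r, g, b) means of an
#' \code{\linkS4class{RGBMean}}.
#'
#' @param object an object of the documented classes.
#' @param channel channel id: "R", "G", "B" or "GRAY".
#' @return The extracted component (see details per generic).
#' @name accessors
#' @examples
#' tab <- referenceCalibration(fittedOnly = TRUE)
#' model <- buildModel(tab)
#' slope(channelFit(model, "B"))
#' grayWeights(model)
NULL

#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("grayWeights", function(object) standardGeneric("grayWeights"))

#' @rdname accessors
#' @export
setGeneric("channelFit", function(object, channel) standardGeneric("channelFit"))

#' @rdname accessors
#' @export
setGeneric("exponentialFit",
           function(object, channel) standardGeneric("exponentialFit"))

#' @rdname accessors
#' @export
setGeneric("mlssHat", function(object) standardGeneric("mlssHat"))

#' @rdname accessors
#' @export
setGeneric("predictionFlags",
           function(object) standardGeneric("predictionFlags"))

#' @rdname accessors
#' @export
setGeneric("rgbValues", function(object) standardGeneric("rgbValues"))

#' Convert RGB values to the calibrated gray composite
#'
#' Applies gray = kR*R + kG*G + kB*B with slope-derived weights. Because the
#' weights sum to one, a neutral input (r = g = b) maps to itself.
#'
#' @param rgb an \code{\linkS4class{RGBMean}}, a numeric length-3 vector
#'   (r, g, b), or an n-by-3 matrix with one row per sample.
#' @param k a \code{\linkS4class{GrayCoefficients}} object.
#' @return Gray intensity (0-255 scale); a vector for matrix input.
#' @examples
#' k <- grayCoefficients(-5.3117, -8.9099, -14.404)
#' toGrayscale(c(232.08, 232.09, 233.6), k)
#' @export
setGeneric("toGrayscale", function(rgb, k) standardGeneric("toGrayscale"))
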