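#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("channelName", "ChannelFit", function(object) object@channel)

#' @rdname accessors
setMethod("channelName", "ExponentialFit", function(object) object@channel)

#' @rdname accessors
setMethod("slope", "ChannelFit", function(object) object@slope)

#' @rdname accessors
setMethod("intercept", "ChannelFit", function(object) object@intercept)

#' @rdname accessors
setMethod("rSquared", "ChannelFit", function(object) object@rSquared)

#' @rdname accessors
setMethod("rSquared", "ExponentialFit", function(object) {
  c(log = object@rSquaredLog, linear = object@rSquaredLinear)
})

#' @rdname accessors
setMethod("grayWeights", "GrayCoefficients", function(object) {
  c(kR = object@kR, kG = object@kG, kB = object@kB)
})

#' @rdname accessors
setMethod("grayWeights", "CalibrationModel", function(object) {
  grayWeights(object@gray)
})

#' @rdname accessors
setMethod("channelFit", "CalibrationModel", function(object, channel) {
  channel <- match.arg(channel, .CHANNELS)
  object@channelFits[[channel]]
})

#' @rdname accessors
setMethod("exponentialFit", "CalibrationModel", function(object, channel) {
  channel <- match.arg(channel, .CHANNELS)
  if (is.null(object@exponentialFits[[channel]])) {
    stopUsage("no exponential fit stored for channel ", channel)
  }
  object@exponentialFits[[channel]]
})

#' @rdname accessors
setMethod("mlssHat", "Prediction", function(object) object@mlssHat)

#' @rdname accessors
setMethod("predictionFlags", "Prediction", function(object) object@flags)

#' @rdname accessors
setMethod("rgbValues", "RGBMean", function(object) {
  c(r = object@r, g = object@g, b = object@b)
})

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI: centre (%.2f, %.2f), radius %.2f px\n",
              object@cx, object@cy, object@radius))
})

setMethod("show", "RGBMean", function(object) {
  cat(sprintf("RGBMean: R %.3f  G %.3f  B %.3f  (%d pixels)\n",
              object@r, object@g, object@b, as.integer(object@nPixels)))
})

setMethod("show", "ChannelFit", function(object) {
  cat(sprintf(
    "ChannelFit [%s]: intensity = %.4f %+.4f * MLSS, R^2 = %.4f (n = %d)\n",
    object@channel, object@intercept, object@slope, object@rSquared, object@n))
})

setMethod("show", "GrayCoefficients", function(object) {
  cat(sprintf("GrayCoefficients: kR %.5f  kG %.5f  kB %.5f\n",
              object@kR, object@kG, object@kB))
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf(
    "ExponentialFit [%s]: V = %.3f * exp(-%.5f * MLSS), MLSS <= %g g/L\n",
    object@channel, object@v0, object@kappa, object@mlssMax))
  cat(sprintf("  R^2 (log scale) %.4f, R^2 (intensity scale) %.4f, n = %d\n",
              object@rSquaredLog, object@rSquaredLinear, object@n))
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel\n")
  for (fit in object@channelFits) {
    cat("  "); show(fit)
  }
  cat("  "); show(object@gray)
  if (length(object@exponentialFits)) {
    cat(sprintf("  exponential fits: %s\n",
                paste(names(object@exponentialFits), collapse = ", ")))
  }
})

setMethod("show", "Prediction", function(object) {
  fl <- if (length(object@flags)) paste(object@flags, collapse = ", ") else "none"
  cat(sprintf("Prediction [%s, %s]: MLSS %.4f g/L (flags: %s)\n",
              object@channel, object@modelKind, object@mlssHat, fl))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: RMSE %.4f  MAE %.4f  MAPE %.3f%%  R^2 %.4f (n = %d, %d excluded from MAPE)\n",
    object@rmse, object@mae, object@mape, object@rSquared,
    object@nUsed, object@nExcludedMape))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %dx%d px, dish at (%g, %g) radius %g (rim %g)\n",
              object@width, object@height, object@dishCenter[1],
              object@dishCenter[2], object@dishRadius, object@rimWidth))
  cat(sprintf("  base colour (%g, %g, %g), attenuation (%g, %g, %g) per g/L, noise sd %g, seed %d\n",
              object@baseColor[1], object@baseColor[2], object@baseColor[3],
              object@attenuation[1], object@attenuation[2],
              object@attenuation[3], object@noiseSd, object@seed))
})

#' Convert a MetricsReport to a one-row data frame
#'
#' @param x a \code{\linkS4class{MetricsReport}}.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return A one-row \code{data.frame} with columns rmse, mae, mape,
#'   r_squared, n_used, n_excluded_mape.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(rmse = x@rmse, mae = x@mae, mape = x@mape,
             r_squared = x@rSquared, n_used = x@nUsed,
             n_excluded_mape = x@nExcludedMape,
             stringsAsFactors = FALSE, row.names = row.names)
}
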