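#' @import methods
NULL

.CHANNELS <- c("R", "G", "B", "GRAY")

#' Circular region of interest
#'
#' Describes the circular dish region over which channel intensities are
#' averaged. Coordinates follow image conventions: the origin is the top-left
#' image corner, x grows rightward, y grows downward, and the centre of the
#' pixel in row i, column j is (j - 0.5, i - 0.5).
#'
#' @slot cx,cy centre of the circle in pixel coordinates.
#' @slot radius circle radius in pixels; must be positive.
#' @export
setClass("CircularROI",
  representation(cx = "numeric", cy = "numeric", radius = "numeric"),
  validity = function(object) {
    if (length(object@cx) != 1L || length(object@cy) != 1L ||
        length(object@radius) != 1L) {
      return("cx, cy and radius must be scalars")
    }
    if (!all(is.finite(c(object@cx, object@cy, object@radius)))) {
      return("cx, cy and radius must be finite")
    }
    if (object@radius <= 0) return("radius must be positive")
    TRUE
  }
)

#' @rdname CircularROI-class
#' @param cx,cy,radius circle centre and radius in pixels.
#' @return A \code{CircularROI} object.
#' @examples
#' circularROI(200, 200, 150)
#' @export
circularROI <- function(cx, cy, radius) {
  new("CircularROI", cx = as.numeric(cx), cy = as.numeric(cy),
      radius = as.numeric(radius))
}

#' Mean channel intensities of an image region
#'
#' Holds the arithmetic mean red, green and blue intensities (on the 8-bit
#' 0-255 scale, fractional values allowed) of the pixels inside a region,
#' together with the number of pixels that contributed.
#'
#' @slot r,g,b mean channel intensities in [0, 255].
#' @slot nPixels number of pixels averaged (summed across replicates after
#'   \code{\link{averageReplicates}}).
#' @export
setClass("RGBMean",
  representation(r = "numeric", g = "numeric", b = "numeric",
                 nPixels = "numeric"),
  validity = function(object) {
    v <- c(object@r, object@g, object@b)
    if (length(v) != 3L) return("r, g and b must be scalars")
    if (!all(is.finite(v))) return("channel means must be finite")
    if (any(v < 0) || any(v > 255)) return("channel means must lie in [0, 255]")
    if (length(object@nPixels) != 1L || object@nPixels < 1) {
      return("nPixels must be a scalar >= 1")
    }
    TRUE
  }
)

#' @rdname RGBMean-class
#' @param r,g,b mean channel intensities in [0, 255].
#' @param nPixels number of pixels the means were computed from.
#' @return An \code{RGBMean} object.
#' @examples
#' rgbMean(232.08, 232.09, 233.6, nPixels = 1000)
#' @export
rgbMean <- function(r, g, b, nPixels = 1) {
  new("RGBMean", r = as.numeric(r), g = as.numeric(g), b = as.numeric(b),
      nPixels = as.numeric(nPixels))
}

#' Linear calibration of one channel against MLSS
#'
#' Ordinary least-squares line of channel intensity (response) on MLSS
#' (predictor). The slope is in intensity units per g/L; for the colour
#' channels it is the quantity from which the grayscale weights are derived.
#'
#' @slot channel one of "R", "G", "B", "GRAY".
#' @slot slope,intercept fitted line; intensity = intercept + slope * MLSS.
#' @slot rSquared coefficient of determination of the fit.
#' @slot n number of calibration samples used.
#' @slot mlssRange range (min, max) of MLSS values used in the fit, g/L;
#'   inverse predictions outside it are flagged.
#' @export
setClass("ChannelFit",
  representation(channel = "character", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 n = "integer", mlssRange = "numeric"),
  validity = function(object) {
    if (!object@channel %in% .CHANNELS) {
      return(sprintf("channel must be one of %s",
                     paste(.CHANNELS, collapse = ", ")))
    }
    if (object@n < 3L) return("a channel fit needs at least 3 samples")
    if (!is.finite(object@rSquared) || object@rSquared > 1 + 1e-12) {
      return("rSquared must be finite and <= 1")
    }
    if (length(object@mlssRange) != 2L || diff(object@mlssRange) < 0) {
      return("mlssRange must be c(min, max)")
    }
    TRUE
  }
)

#' Grayscale conversion weights
#'
#' Weights of the composite gray index gray = kR*R + kG*G + kB*B, each equal
#' to its channel's calibration slope divided by the sum of the three slopes,
#' so that the weights sum to one.
#'
#' @slot kR,kG,kB dimensionless channel weights summing to 1.
#' @export
setClass("GrayCoefficients",
  representation(kR = "numeric", kG = "numeric", kB = "numeric"),
  validity = function(object) {
    k <- c(object@kR, object@kG, object@kB)
    if (length(k) != 3L || !all(is.finite(k))) {
      return("weights must be finite scalars")
    }
    if (abs(sum(k) - 1) > 1e-9) return("weights must sum to 1 (within 1e-9)")
    TRUE
  }
)

#' Beer-Lambert exponential calibration of one channel
#'
#' Low-turbidity model V = v0 * exp(-kappa * MLSS), fitted by ordinary least
#' squares of log-intensity on MLSS over samples with MLSS <= mlssMax.
#'
#' @slot channel one of "R", "G", "B", "GRAY".
#' @slot v0 intensity at zero MLSS (0-255 scale), positive.
#' @slot kappa attenuation coefficient per g/L (positive for cultures that
#'   darken with biomass).
#' @slot rSquaredLog R^2 of the straight-line fit on the log-intensity scale.
#' @slot rSquaredLinear R^2 of the back-transformed predictions on the
#'   intensity scale.
#' @slot mlssMax upper MLSS bound (g/L) of the fitted regime.
#' @slot n number of samples in the fitted subset.
#' @export
setClass("ExponentialFit",
  representation(channel = "character", v0 = "numeric", kappa = "numeric",
                 rSquaredLog = "numeric", rSquaredLinear = "numeric",
                 mlssMax = "numeric", n = "integer"),
  validity = function(object) {
    if (!object@channel %in% .CHANNELS) return("invalid channel")
    if (!is.finite(object@v0) || object@v0 <= 0) return("v0 must be positive")
    if (object@n < 3L) return("an exponential fit needs at least 3 samples")
    TRUE
  }
)

#' Full colorimetric calibration model
#'
#' Aggregates the per-channel linear fits, the slope-derived grayscale
#' weights, the gray-composite fit, and (optionally) per-channel Beer-Lambert
#' exponential fits, plus free-form metadata such as capture settings.
#'
#' @slot channelFits named list of \code{\linkS4class{ChannelFit}} objects
#'   ("R", "G", "B", "GRAY").
#' @slot gray \code{\linkS4class{GrayCoefficients}} derived from the three
#'   colour-channel slopes; the "GRAY" fit is computed from the composite
#'   values these weights produce.
#' @slot exponentialFits named list of \code{\linkS4class{ExponentialFit}}
#'   objects (possibly empty).
#' @slot metadata free-form list (e.g. camera settings, creation time).
#' @export
setClass("CalibrationModel",
  representation(channelFits = "list", gray = "GrayCoefficients",
                 exponentialFits = "list", metadata = "list"),
  validity = function(object) {
    if (!all(c("R", "G", "B", "GRAY") %in% names(object@channelFits))) {
      return("channelFits must contain R, G, B and GRAY")
    }
    ok <- vapply(object@channelFits, is, logical(1), class2 = "ChannelFit")
    if (!all(ok)) return("channelFits must all be ChannelFit objects")
    if (length(object@exponentialFits)) {
      ok <- vapply(object@exponentialFits, is, logical(1),
                   class2 = "ExponentialFit")
      if (!all(ok)) return("exponentialFits must all be ExponentialFit objects")
    }
    TRUE
  }
)

#' A single MLSS prediction
#'
#' @slot mlssHat predicted MLSS in g/L. May be negative (flagged, and clipped
#'   only on request).
#' @slot channel channel the prediction was made from.
#' @slot modelKind "linear" or "exponential".
#' @slot flags character vector; "below-zero" when the raw inverse prediction
#'   is negative, "above-calibration-range" when it exceeds the fitted range.
#' @export
setClass("Prediction",
  representation(mlssHat = "numeric", channel = "character",
                 modelKind = "character", flags = "character"),
  validity = function(object) {
    if (!object@modelKind %in% c("linear", "exponential")) {
      return("modelKind must be 'linear' or 'exponential'")
    }
    TRUE
  }
)

#' Prediction error statistics
#'
#' @slot rmse root mean squared error, g/L.
#' @slot mae mean absolute error, g/L.
#' @slot mape mean absolute percentage error (percent), computed over samples
#'   with actual MLSS > 0.
#' @slot rSquared 1 - SS_res / SS_tot on the actual values.
#' @slot nUsed number of (actual, predicted) pairs.
#' @slot nExcludedMape number of zero-MLSS pairs excluded from MAPE.
#' @export
setClass("MetricsReport",
  representation(rmse = "numeric", mae = "numeric", mape = "numeric",
                 rSquared = "numeric", nUsed = "integer",
                 nExcludedMape = "integer"),
  validity = function(object) {
    if (object@nUsed < 1L) return("nUsed must be >= 1")
    if (is.finite(object@rmse) && is.finite(object@mae) &&
        object@rmse < object@mae - 1e-12) {
      return("rmse cannot be smaller than mae")
    }
    TRUE
  }
)

#' Synthetic dish scene description
#'
#' Parameters of the synthetic petri-dish renderer: geometry, colours, the
#' per-channel Beer-Lambert attenuation of the dish interior with MLSS, the
#' additive Gaussian sensor noise, and the root seed of the random stream.
#' Defaults emulate the bundled reference calibration: an interior near
#' (232, 232, 234) at zero MLSS and attenuation coefficients ordered
#' kappa_B > kappa_G > kappa_R, as expected when blue light is absorbed most
#' strongly by the darkening culture.
#'
#' @slot width,height image size in pixels.
#' @slot dishCenter numeric length-2 (cx, cy) in pixel coordinates.
#' @slot dishRadius outer dish radius in pixels (includes the rim).
#' @slot rimWidth width of the bright rim annulus in pixels.
#' @slot rimColor,backgroundColor,baseColor length-3 RGB values in [0, 255];
#'   baseColor is the interior colour at MLSS 0.
#' @slot attenuation length-3 per-channel attenuation coefficients per g/L.
#' @slot noiseSd additive Gaussian noise standard deviation, intensity units.
#' @slot seed integer root seed; per-image streams are derived from it and the
#'   (sample, replicate) indices.
#' @export
setClass("SceneConfig",
  representation(width = "integer", height = "integer",
                 dishCenter = "numeric", dishRadius = "numeric",
                 rimWidth = "numeric", rimColor = "numeric",
                 backgroundColor = "numeric", baseColor = "numeric",
                 attenuation = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@width < 1L || object@height < 1L) {
      return("image size must be at least 1x1")
    }
    if (length(object@dishCenter) != 2L) return("dishCenter must be (cx, cy)")
    if (object@dishRadius <= 0) return("dishRadius must be positive")
    if (object@rimWidth < 0 || object@rimWidth >= object@dishRadius) {
      return("rimWidth must be in [0, dishRadius)")
    }
    for (nm in c("rimColor", "backgroundColor", "baseColor")) {
      v <- slot(object, nm)
      if (length(v) != 3L || any(v < 0) || any(v > 255)) {
        return(sprintf("%s must be 3 values in [0, 255]", nm))
      }
    }
    if (any(object@baseColor <= 0)) {
      return("baseColor channels must be positive")
    }
    if (length(object@attenuation) != 3L || any(object@attenuation < 0)) {
      return("attenuation must be 3 non-negative values")
    }
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    TRUE
  }
)
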