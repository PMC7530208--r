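#' @include AllClasses.R AllGenerics.R conditions.R
NULL

channelColumn <- function(samples, channel) {
  col <- switch(channel, R = "r", G = "g", B = "b", GRAY = "gray")
  if (is.null(col) || !col %in% names(samples)) {
    stopUsage("channel ", channel, " not available in the sample table",
              if (identical(channel, "GRAY"))
                " (the gray column is added by buildModel)" else "")
  }
  samples[[col]]
}

checkDesign <- function(mlss, n_min = 3L) {
  keep <- is.finite(mlss)
  if (sum(keep) < n_min) {
    stopInput("insufficient samples: at least ", n_min,
              " calibration samples with known MLSS are required")
  }
  if (length(unique(mlss[keep])) < 2L) {
    stopDegenerate("degenerate design: all MLSS values are identical")
  }
  keep
}

rSquaredOf <- function(y, fitted) {
  sstot <- sum((y - mean(y))^2)
  if (sstot < .Machine$double.eps) return(1)
  1 - sum((y - fitted)^2) / sstot
}

#' Fit a linear channel calibration
#'
#' Ordinary least squares of channel intensity (response) on MLSS
#' (predictor), with intercept. This direction matches the definition of the
#' grayscale weights, which are ratios of the intensity-per-g/L slopes; MLSS
#' is later predicted by inverting the fitted line, not by re-regressing.
#'
#' @param samples calibration table (see \code{\link{readCalibrationTable}})
#'   with finite \code{mlss} for at least 3 samples at 2 distinct values.
#' @param channel "R", "G", "B", or "GRAY" (the latter requires a
#'   \code{gray} column, normally added by \code{\link{buildModel}}).
#' @return A \code{\linkS4class{ChannelFit}}.
#' @examples
#' fitChannel(referenceCalibration(fittedOnly = TRUE), "B")
#' @export
fitChannel <- function(samples, channel = c("R", "G", "B", "GRAY")) {
  channel <- match.arg(channel)
  y <- channelColumn(samples, channel)
  keep <- checkDesign(samples$mlss)
  x <- samples$mlss[keep]
  y <- y[keep]
  fit <- stats::lm(y ~ x)
  new("ChannelFit", channel = channel,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = rSquaredOf(y, stats::fitted(fit)),
      n = length(x), mlssRange = range(x))
}

#' Derive grayscale weights from channel slopes
#'
#' Each weight is its channel's calibration slope divided by the sum of the
#' three slopes, so the weights sum to one and the composite preserves the
#' neutral axis. The slopes must be nonzero and share a sign (all channels
#' fading together as the culture darkens); mixed signs would put weights
#' outside (0, 1) and indicate pathological calibration data.
#'
#' @param mR,mG,mB channel slopes, intensity units per g/L.
#' @return A \code{\linkS4class{GrayCoefficients}}.
#' @examples
#' grayCoefficients(-5.3117, -8.9099, -14.404)
#' @export
grayCoefficients <- function(mR, mG, mB) {
  m <- c(mR, mG, mB)
  if (length(m) != 3L || any(!is.finite(m))) {
    stopUsage("mR, mG and mB must be finite scalars")
  }
  if (any(m == 0) || length(unique(sign(m))) != 1L) {
    stopDegenerate("channel slopes must be nonzero and share the same sign ",
                   "to define grayscale weights")
  }
  k <- m / sum(m)
  new("GrayCoefficients", kR = k[1L], kG = k[2L], kB = k[3L])
}

#' @rdname toGrayscale
setMethod("toGrayscale", signature(rgb = "RGBMean", k = "GrayCoefficients"),
  function(rgb, k) k@kR * rgb@r + k@kG * rgb@g + k@kB * rgb@b)

#' @rdname toGrayscale
setMethod("toGrayscale", signature(rgb = "numeric", k = "GrayCoefficients"),
  function(rgb, k) {
    if (length(rgb) != 3L) stopUsage("rgb must be a length-3 (r, g, b) vector")
    k@kR * rgb[1L] + k@kG * rgb[2L] + k@kB * rgb[3L]
  })

#' @rdname toGrayscale
setMethod("toGrayscale", signature(rgb = "matrix", k = "GrayCoefficients"),
  function(rgb, k) {
    if (ncol(rgb) != 3L) stopUsage("rgb matrix must have 3 columns (r, g, b)")
    as.numeric(rgb %*% c(k@kR, k@kG, k@kB))
  })

#' Fit the low-turbidity Beer-Lambert model for one channel
#'
#' In the optical-diffuse regime, transmitted intensity decays exponentially
#' with absorber concentration: V = v0 * exp(-kappa * MLSS). The model is fit
#' by ordinary least squares of log-intensity on MLSS over the samples with
#' MLSS <= \code{mlssMax}, which is deterministic and needs no starting
#' values. Because it is unclear whether fit quality for such models is
#' conventionally judged on the log or the intensity scale, both R^2 values
#' are reported.
#'
#' @param samples calibration table; intensities in the fitted subset must be
#'   strictly positive.
#' @param channel "R", "G", "B", or "GRAY" (requires a gray column).
#' @param mlssMax upper MLSS bound (g/L) of the exponential regime; the
#'   default of 8 g/L is where deviations from the diffuse approximation
#'   become substantial for activated sludge.
#' @return An \code{\linkS4class{ExponentialFit}}.
#' @examples
#' fitExponential(referenceCalibration(), "B")
#' @export
fitExponential <- function(samples, channel = c("R", "G", "B", "GRAY"),
                           mlssMax = 8) {
  channel <- match.arg(channel)
  if (length(mlssMax) != 1L || !is.finite(mlssMax) || mlssMax <= 0) {
    stopUsage("mlssMax must be a positive scalar")
  }
  y <- channelColumn(samples, channel)
  sel <- is.finite(samples$mlss) & samples$mlss <= mlssMax & is.finite(y)
  if (sum(sel) < 3L) {
    stopInput("insufficient samples: at least 3 samples with MLSS <= ",
              mlssMax, " are required for the exponential fit")
  }
  x <- samples$mlss[sel]
  y <- y[sel]
  if (length(unique(x)) < 2L) {
    stopDegenerate("degenerate design: all MLSS values are identical")
  }
  if (any(y <= 0)) {
    stopDegenerate("cannot fit exponential model: channel ", channel,
                   " has intensities <= 0 in the MLSS <= ", mlssMax,
                   " subset (log undefined)")
  }
  fit <- stats::lm(log(y) ~ x)
  v0 <- exp(unname(stats::coef(fit)[1L]))
  kappa <- -unname(stats::coef(fit)[2L])
  back <- v0 * exp(-kappa * x)
  new("ExponentialFit", channel = channel, v0 = v0, kappa = kappa,
      rSquaredLog = rSquaredOf(log(y), stats::fitted(fit)),
      rSquaredLinear = rSquaredOf(y, back),
      mlssMax = mlssMax, n = length(x))
}

#' Build the full calibration model
#'
#' Fits the R, G and B channel lines against MLSS, derives the grayscale
#' weights from the three slopes, computes the gray composite for every
#' sample and fits it as a fourth channel, and (optionally) fits the
#' Beer-Lambert exponential model per channel on the low-MLSS subset.
#' Channels whose low-MLSS intensities are not strictly positive are skipped
#' in the exponential stage.
#'
#' @param samples calibration table (see \code{\link{readCalibrationTable}}).
#' @param mlssMax upper MLSS bound (g/L) for the exponential fits.
#' @param exponential logical; fit the exponential models?
#' @param metadata free-form list stored with the model (e.g. capture
#'   settings such as aperture, shutter time and ISO).
#' @return A \code{\linkS4class{CalibrationModel}}.
#' @examples
#' model <- buildModel(referenceCalibration(fittedOnly = TRUE))
#' grayWeights(model)
#' @export
buildModel <- function(samples, mlssMax = 8, exponential = TRUE,
                       metadata = list()) {
  fits <- list(
    R = fitChannel(samples, "R"),
    G = fitChannel(samples, "G"),
    B = fitChannel(samples, "B")
  )
  gray <- grayCoefficients(fits$R@slope, fits$G@slope, fits$B@slope)
  samples$gray <- toGrayscale(cbind(samples$r, samples$g, samples$b), gray)
  fits$GRAY <- fitChannel(samples, "GRAY")
  expo <- list()
  if (isTRUE(exponential)) {
    for (ch in .CHANNELS) {
      y <- channelColumn(samples, ch)
      sel <- is.finite(samples$mlss) & samples$mlss <= mlssMax & is.finite(y)
      if (sum(sel) >= 3L && all(y[sel] > 0) &&
          length(unique(samples$mlss[sel])) >= 2L) {
        expo[[ch]] <- fitExponential(samples, ch, mlssMax)
      }
    }
  }
  meta <- c(metadata, list(created = format(Sys.time(), tz = "UTC",
                                            usetz = TRUE),
                           n_samples = fits$R@n))
  new("CalibrationModel", channelFits = fits, gray = gray,
      exponentialFits = expo, metadata = meta)
}

#' Serialize a calibration model to JSON
#'
#' The stored fields round-trip at full double precision:
#' \code{readModelJSON(writeModelJSON(m, f))} reproduces every numeric slot
#' bit for bit.
#'
#' @param model a \code{\linkS4class{CalibrationModel}}.
#' @param path output JSON path.
#' @return \code{writeModelJSON}: the path, invisibly. \code{readModelJSON}:
#'   the reconstructed \code{CalibrationModel}.
#' @examples
#' model <- buildModel(referenceCalibration(fittedOnly = TRUE))
#' f <- tempfile(fileext = ".json")
#' writeModelJSON(model, f)
#' readModelJSON(f)
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "CalibrationModel"))
  chans <- lapply(model@channelFits, function(f) {
    list(slope = f@slope, intercept = f@intercept, r_squared = f@rSquared,
         n = f@n, mlss_min = f@mlssRange[1L], mlss_max = f@mlssRange[2L])
  })
  expo <- lapply(model@exponentialFits, function(f) {
    list(v0 = f@v0, kappa = f@kappa, r_squared_log = f@rSquaredLog,
         r_squared_linear = f@rSquaredLinear, mlss_max = f@mlssMax, n = f@n)
  })
  obj <- list(
    channels = chans,
    gray = list(k_r = model@gray@kR, k_g = model@gray@kG,
                k_b = model@gray@kB),
    exponential = expo,
    metadata = model@metadata
  )
  # digits = I(17): decimal text round-trips IEEE doubles bit for bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  if (!file.exists(path)) stopInput("cannot read model file: ", path)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stopInput("malformed model JSON: ", path,
                                  " (", conditionMessage(e), ")")
  )
  if (is.null(obj$channels) || is.null(obj$gray)) {
    stopInput("model JSON ", path, " lacks required 'channels'/'gray' blocks")
  }
  fits <- list()
  for (ch in names(obj$channels)) {
    f <- obj$channels[[ch]]
    fits[[ch]] <- new("ChannelFit", channel = ch, slope = f$slope,
                      intercept = f$intercept, rSquared = f$r_squared,
                      n = as.integer(f$n),
                      mlssRange = c(f$mlss_min, f$mlss_max))
  }
  expo <- list()
  for (ch in names(obj$exponential)) {
    f <- obj$exponential[[ch]]
    expo[[ch]] <- new("ExponentialFit", channel = ch, v0 = f$v0,
                      kappa = f$kappa, rSquaredLog = f$r_squared_log,
                      rSquaredLinear = f$r_squared_linear,
                      mlssMax = f$mlss_max, n = as.integer(f$n))
  }
  gray <- new("GrayCoefficients", kR = obj$gray$k_r, kG = obj$gray$k_g,
              kB = obj$gray$k_b)
  meta <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
  new("CalibrationModel", channelFits = fits, gray = gray,
      exponentialFits = expo, metadata = meta)
}
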