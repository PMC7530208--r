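#' @include AllClasses.R AllGenerics.R conditions.R calibration.R
NULL

#' Predict MLSS by inverting a linear channel calibration
#'
#' Inverse prediction: MLSS = (intensity - intercept) / slope. Estimates
#' below zero or beyond the calibrated MLSS range are flagged, never silently
#' clipped; set \code{clip = TRUE} to apply max(0, .) for operational use
#' (the flag is kept either way).
#'
#' @param value observed intensity (0-255 scale) of the fit's channel.
#' @param fit a \code{\linkS4class{ChannelFit}} with nonzero slope.
#' @param clip logical; clip negative estimates to zero.
#' @return A \code{\linkS4class{Prediction}}.
#' @examples
#' fit <- fitChannel(referenceCalibration(fittedOnly = TRUE), "B")
#' predictLinear(150, fit)
#' @export
predictLinear <- function(value, fit, clip = FALSE) {
  stopifnot(is(fit, "ChannelFit"))
  if (length(value) != 1L || !is.finite(value)) {
    stopUsage("value must be a finite scalar intensity")
  }
  if (fit@slope == 0) {
    stopDegenerate("cannot invert a zero-slope calibration line")
  }
  est <- (value - fit@intercept) / fit@slope
  flags <- character(0)
  if (est < 0) flags <- c(flags, "below-zero")
  if (est > fit@mlssRange[2L]) flags <- c(flags, "above-calibration-range")
  if (isTRUE(clip)) est <- max(0, est)
  new("Prediction", mlssHat = est, channel = fit@channel,
      modelKind = "linear", flags = flags)
}

#' Predict MLSS by inverting the Beer-Lambert model
#'
#' Inverse of V = v0 * exp(-kappa * MLSS): MLSS = log(v0 / V) / kappa.
#' Estimates beyond the fitted regime (above \code{mlssMax}) or below zero
#' are flagged.
#'
#' @param value observed intensity, strictly positive.
#' @param fit an \code{\linkS4class{ExponentialFit}} with nonzero kappa.
#' @param clip logical; clip negative estimates to zero.
#' @return A \code{\linkS4class{Prediction}}.
#' @examples
#' fit <- fitExponential(referenceCalibration(), "B")
#' predictExponential(180, fit)
#' @export
predictExponential <- function(value, fit, clip = FALSE) {
  stopifnot(is(fit, "ExponentialFit"))
  if (length(value) != 1L || !is.finite(value)) {
    stopUsage("value must be a finite scalar intensity")
  }
  if (value <= 0) {
    stopUsage("value must be positive: the exponential model is defined ",
              "for positive intensities only")
  }
  if (fit@kappa == 0) {
    stopDegenerate("cannot invert an exponential fit with zero attenuation")
  }
  est <- log(fit@v0 / value) / fit@kappa
  flags <- character(0)
  if (est < 0) flags <- c(flags, "below-zero")
  if (est > fit@mlssMax) flags <- c(flags, "above-calibration-range")
  if (isTRUE(clip)) est <- max(0, est)
  new("Prediction", mlssHat = est, channel = fit@channel,
      modelKind = "exponential", flags = flags)
}

#' Prediction error statistics
#'
#' RMSE = sqrt(mean((a - p)^2)), MAE = mean(|a - p|), MAPE = 100 *
#' mean(|a - p| / a) over pairs with actual > 0 (zero-MLSS pairs are excluded
#' from MAPE and counted in \code{nExcludedMape}), and R^2 = 1 - SS_res /
#' SS_tot computed on the actual values.
#'
#' @param actual,predicted numeric vectors of equal nonzero length, g/L.
#' @return A \code{\linkS4class{MetricsReport}}.
#' @examples
#' predictionMetrics(c(1, 2), c(2, 4))
#' @export
predictionMetrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stopUsage("actual and predicted must have equal length")
  }
  if (length(actual) == 0L) stopUsage("empty input")
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stopUsage("actual and predicted must be finite")
  }
  if (length(unique(actual)) < 2L) {
    stopDegenerate("r_squared is undefined when all actual values are equal")
  }
  err <- actual - predicted
  pos <- actual > 0
  mape <- if (any(pos)) 100 * mean(abs(err[pos]) / actual[pos]) else NaN
  new("MetricsReport",
      rmse = sqrt(mean(err^2)),
      mae = mean(abs(err)),
      mape = mape,
      rSquared = 1 - sum(err^2) / sum((actual - mean(actual))^2),
      nUsed = length(actual),
      nExcludedMape = sum(!pos))
}

channelValues <- function(model, samples, channel) {
  if (channel == "GRAY") {
    toGrayscale(cbind(samples$r, samples$g, samples$b), model@gray)
  } else {
    channelColumn(samples, channel)
  }
}

#' Rank channels by inverse-prediction accuracy
#'
#' Predicts MLSS for every sample from each requested channel by inverting
#' its linear calibration, computes error statistics per channel, and
#' returns the channel with the highest R^2 (ties broken by lowest RMSE,
#' then by the fixed order B, GRAY, G, R). On wide MLSS ranges the blue
#' channel is expected to win among the primaries because its absorption by
#' the darkening culture is strongest.
#'
#' @param model a \code{\linkS4class{CalibrationModel}}.
#' @param samples calibration table with known MLSS.
#' @param channels channels to compare (default all four).
#' @param clip logical; clip negative predictions to zero before scoring.
#' @return A list with elements \code{best} (channel id), \code{metrics}
#'   (named list of \code{\linkS4class{MetricsReport}}), and
#'   \code{predictions} (data.frame: sample_id, channel, model_kind,
#'   mlss_hat, flags).
#' @examples
#' tab <- referenceCalibration(fittedOnly = TRUE)
#' res <- selectBestChannel(buildModel(tab), tab, channels = c("R", "G", "B"))
#' res$best
#' @export
selectBestChannel <- function(model, samples, channels = .CHANNELS,
                              clip = FALSE) {
  stopifnot(is(model, "CalibrationModel"))
  channels <- match.arg(channels, .CHANNELS, several.ok = TRUE)
  if (nrow(samples) == 0L) stopUsage("empty sample table")
  keep <- is.finite(samples$mlss)
  if (!any(keep)) stopInput("samples have no known MLSS values")
  samples <- samples[keep, , drop = FALSE]
  metrics <- list()
  predRows <- list()
  for (ch in channels) {
    vals <- channelValues(model, samples, ch)
    preds <- lapply(vals, predictLinear, fit = model@channelFits[[ch]],
                    clip = clip)
    est <- vapply(preds, mlssHat, numeric(1))
    flg <- vapply(preds, function(p)
      paste(predictionFlags(p), collapse = ";"), character(1))
    metrics[[ch]] <- predictionMetrics(samples$mlss, est)
    predRows[[ch]] <- data.frame(
      sample_id = samples$sample_id, channel = ch, model_kind = "linear",
      mlss_hat = est, flags = flg, stringsAsFactors = FALSE)
  }
  r2 <- vapply(metrics, function(m) m@rSquared, numeric(1))
  rmse <- vapply(metrics, function(m) m@rmse, numeric(1))
  tieOrder <- match(names(metrics), c("B", "GRAY", "G", "R"))
  best <- names(metrics)[order(-r2, rmse, tieOrder)][1L]
  list(best = best, metrics = metrics,
       predictions = do.call(rbind, c(predRows, make.row.names = FALSE)))
}
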