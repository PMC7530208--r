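#' @include AllClasses.R conditions.R
NULL

# An "image grid" throughout the package is an integer array of dimension
# (height, width, 3) holding 8-bit channel values 0-255.
assertImageGrid <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stopUsage("image must be a height x width x 3 array of 8-bit values")
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255)) {
    stopUsage("image channel values must lie in [0, 255]")
  }
  invisible(image)
}

# PNG stores its bit depth in byte 25 (after the 8-byte signature and the
# IHDR length/type/width/height fields).
pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) return(NA_integer_)
  as.integer(hdr[25L])
}

# Promote grayscale to three equal channels, drop alpha, return integer array.
normalizeChannels <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  nc <- dim(arr)[3]
  arr <- switch(as.character(nc),
    "1" = array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L)),
    "2" = array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L)),
    "3" = arr,
    "4" = arr[, , 1:3, drop = FALSE],
    stopInput("unsupported channel count (", nc, ") in ", path)
  )
  storage.mode(arr) <- "integer"
  arr
}

#' Load an 8-bit RGB image
#'
#' Decodes a PNG, TIFF or JPEG file into an integer array of dimension
#' (height, width, 3) with channel values 0-255. Grayscale images are
#' promoted to three equal channels; an alpha channel is dropped. Images
#' stored at other bit depths are rejected rather than silently rescaled.
#'
#' @param path path to a PNG, TIFF (8-bit) or JPEG file.
#' @return Integer array (height, width, 3), values in 0-255.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(rep(c(10, 20, 30) / 255, each = 4), c(2, 2, 3)), f)
#' loadImage(f)[1, 1, ]
#' @export
loadImage <- function(path) {
  if (length(path) != 1L || !is.character(path)) {
    stopUsage("path must be a single file path")
  }
  if (!file.exists(path)) stopInput("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  decode <- function(expr) {
    tryCatch(expr, error = function(e) {
      stopInput("unreadable or corrupt image file: ", path,
                " (", conditionMessage(e), ")")
    })
  }
  if (ext == "png") {
    bd <- pngBitDepth(path)
    if (!is.na(bd) && bd != 8L) {
      stopInput("unsupported bit depth (", bd, "-bit) in ", path,
                "; only 8-bit images are supported")
    }
    arr <- decode(png::readPNG(path))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- decode(tiff::readTIFF(path, info = TRUE))
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && !identical(as.integer(bits), 8L)) {
      stopInput("unsupported bit depth (", bits, "-bit) in ", path,
                "; only 8-bit images are supported")
    }
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- decode(jpeg::readJPEG(path))
  } else {
    stopInput("unsupported image format '", ext, "': ", path)
  }
  normalizeChannels(round(arr * 255), path)
}

# Logical mask of pixels whose centres fall strictly inside the circle.
roiMask <- function(image, cx, cy, radius) {
  h <- dim(image)[1]; w <- dim(image)[2]
  dy2 <- ((seq_len(h) - 0.5) - cy)^2
  dx2 <- ((seq_len(w) - 0.5) - cx)^2
  outer(dy2, dx2, `+`) < radius^2
}

checkInside <- function(image, cx, cy, radius, what) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (cx - radius < 0 || cx + radius > w || cy - radius < 0 ||
      cy + radius > h) {
    stopUsage(what, " extends outside the image bounds")
  }
}

#' Detect the dish region of interest
#'
#' Locates a single bright-rimmed circular dish on a darker or uniform
#' background. Pixels deviating from the border-estimated background colour
#' are labelled; the largest connected component is accepted as the dish if
#' it is plausibly circular, and its centroid and area define the returned
#' circle. Detection is deterministic for a fixed image. An explicitly
#' supplied ROI should always be preferred in scripted pipelines.
#'
#' @param image an image array as returned by \code{\link{loadImage}}.
#' @param threshold minimum per-channel deviation from the background colour
#'   (intensity units) for a pixel to count as foreground.
#' @return A \code{\linkS4class{CircularROI}}.
#' @examples
#' cfg <- sceneConfig(noiseSd = 0)
#' img <- renderDishImage(cfg, mlss = 2)
#' detectDishROI(img)
#' @export
detectDishROI <- function(image, threshold = 20) {
  assertImageGrid(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  border <- rbind(image[c(1L, h), , ], image[, c(1L, w), ])
  dev <- matrix(0, h, w)
  for (c in 1:3) {
    bg <- stats::median(border[, c])
    dev <- pmax(dev, abs(image[, , c] - bg))
  }
  mask <- dev > threshold
  fail <- function() {
    stopInput("no circle found in image; supply an explicit ROI ",
              "(e.g. --roi cx,cy,r)")
  }
  if (!any(mask)) fail()
  labels <- EBImage::bwlabel(mask * 1)
  counts <- tabulate(labels[labels > 0])
  idx <- which(labels == which.max(counts), arr.ind = TRUE)
  n <- nrow(idx)
  hgt <- diff(range(idx[, 1])) + 1L
  wid <- diff(range(idx[, 2])) + 1L
  fill <- n / (pi * (max(hgt, wid) / 2)^2)
  if (n < 50L || abs(hgt - wid) > 0.2 * max(hgt, wid) ||
      fill < 0.8 || fill > 1.2) {
    fail()
  }
  cy <- mean(idx[, 1]) - 0.5
  cx <- mean(idx[, 2]) - 0.5
  radius <- sqrt(n / pi)
  if (cx - radius < -0.5 || cx + radius > w + 0.5 ||
      cy - radius < -0.5 || cy + radius > h + 0.5) {
    stopInput("detected dish touches the image border; supply an explicit ROI")
  }
  circularROI(cx, cy, radius)
}

#' Mean channel intensities inside a (shrunken) circular ROI
#'
#' Averages each channel over pixels whose centres fall strictly inside the
#' circle of radius \code{shrink * radius(roi)}. The default shrink of 0.8
#' excludes the dish rim and meniscus highlights from the average.
#'
#' @param image an image array as returned by \code{\link{loadImage}}.
#' @param roi a \code{\linkS4class{CircularROI}}.
#' @param shrink radius multiplier in (0, 1].
#' @return An \code{\linkS4class{RGBMean}}.
#' @examples
#' img <- array(rep(c(10L, 20L, 30L), each = 100), c(10, 10, 3))
#' meanRGB(img, circularROI(5, 5, 4))
#' @export
meanRGB <- function(image, roi, shrink = 0.8) {
  assertImageGrid(image)
  stopifnot(is(roi, "CircularROI"))
  if (length(shrink) != 1L || !is.finite(shrink) || shrink <= 0 ||
      shrink > 1) {
    stopUsage("shrink must lie in (0, 1]")
  }
  rs <- roi@radius * shrink
  checkInside(image, roi@cx, roi@cy, rs, "shrunken ROI")
  m <- roiMask(image, roi@cx, roi@cy, rs)
  n <- sum(m)
  if (n == 0L) {
    stopUsage("empty ROI: no pixel centres fall inside the shrunken circle")
  }
  rgbMean(mean(image[, , 1][m]), mean(image[, , 2][m]),
          mean(image[, , 3][m]), nPixels = n)
}

#' Average replicate measurements
#'
#' Unweighted per-channel arithmetic mean of replicate \code{RGBMean}
#' values (the three-images-per-sample protocol); pixel counts are summed.
#'
#' @param means non-empty list of \code{\linkS4class{RGBMean}} objects.
#' @return An \code{\linkS4class{RGBMean}}.
#' @examples
#' averageReplicates(list(rgbMean(1, 1, 1), rgbMean(3, 3, 3)))
#' @export
averageReplicates <- function(means) {
  if (!is.list(means) || length(means) == 0L) {
    stopUsage("means must be a non-empty list of RGBMean objects")
  }
  if (!all(vapply(means, is, logical(1), class2 = "RGBMean"))) {
    stopUsage("means must be a non-empty list of RGBMean objects")
  }
  vals <- vapply(means, rgbValues, numeric(3))
  rgbMean(mean(vals["r", ]), mean(vals["g", ]), mean(vals["b", ]),
          nPixels = sum(vapply(means, function(x) x@nPixels, numeric(1))))
}

#' Fraction of saturated pixels inside an ROI
#'
#' Quality check for over-exposure: the fraction of in-ROI pixels with any
#' channel at the 8-bit ceiling of 255. Channel means computed from images
#' with a noticeable saturated fraction (conventionally above 1\%) are biased
#' downward in truth and should be treated with suspicion.
#'
#' @param image an image array as returned by \code{\link{loadImage}}.
#' @param roi a \code{\linkS4class{CircularROI}} (full radius, no shrink).
#' @return Fraction in [0, 1].
#' @examples
#' img <- array(100L, c(10, 10, 3))
#' saturationFraction(img, circularROI(5, 5, 4))
#' @export
saturationFraction <- function(image, roi) {
  assertImageGrid(image)
  stopifnot(is(roi, "CircularROI"))
  checkInside(image, roi@cx, roi@cy, roi@radius, "ROI")
  m <- roiMask(image, roi@cx, roi@cy, roi@radius)
  if (!any(m)) stopUsage("empty ROI")
  sat <- (image[, , 1] == 255L) | (image[, , 2] == 255L) |
    (image[, , 3] == 255L)
  mean(sat[m])
}

#' Read and write calibration / extraction tables
#'
#' The on-disk schema is a CSV with header \code{sample_id, mlss_g_per_L,
#' r_mean, g_mean, b_mean, n_pixels, n_replicates} (MLSS may be empty for
#' extraction output of unknown samples; extra columns are preserved). In
#' memory the package uses columns \code{sample_id, mlss, r, g, b, n_pixels,
#' n_replicates}.
#'
#' @param path CSV file path.
#' @return \code{readCalibrationTable}: a \code{data.frame} in the in-memory
#'   schema. \code{writeExtractionTable}: the path, invisibly.
#' @examples
#' tab <- referenceCalibration()
#' f <- tempfile(fileext = ".csv")
#' writeExtractionTable(tab, f)
#' head(readCalibrationTable(f))
#' @export
readCalibrationTable <- function(path) {
  if (!file.exists(path)) stopInput("cannot read table: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stopInput("malformed CSV table: ", path,
                                  " (", conditionMessage(e), ")")
  )
  need <- c("sample_id", "r_mean", "g_mean", "b_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopInput("table ", path, " is missing required columns: ",
              paste(miss, collapse = ", "))
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    mlss = if ("mlss_g_per_L" %in% names(df))
      as.numeric(df$mlss_g_per_L) else NA_real_,
    r = as.numeric(df$r_mean),
    g = as.numeric(df$g_mean),
    b = as.numeric(df$b_mean),
    n_pixels = if ("n_pixels" %in% names(df))
      as.numeric(df$n_pixels) else NA_real_,
    n_replicates = if ("n_replicates" %in% names(df))
      as.integer(df$n_replicates) else 1L,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(df), c("sample_id", "mlss_g_per_L", "r_mean",
                                "g_mean", "b_mean", "n_pixels",
                                "n_replicates"))
  for (nm in extra) out[[nm]] <- df[[nm]]
  bad <- is.finite(out$r + out$g + out$b) &
    (out$r < 0 | out$r > 255 | out$g < 0 | out$g > 255 |
       out$b < 0 | out$b > 255)
  if (any(bad)) {
    stopInput("table ", path, " has channel values outside [0, 255]")
  }
  out
}

#' @rdname readCalibrationTable
#' @param samples a \code{data.frame} in the in-memory schema.
#' @export
writeExtractionTable <- function(samples, path) {
  need <- c("sample_id", "r", "g", "b")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stopUsage("samples is missing columns: ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    sample_id = samples$sample_id,
    mlss_g_per_L = if ("mlss" %in% names(samples)) samples$mlss else NA_real_,
    r_mean = samples$r,
    g_mean = samples$g,
    b_mean = samples$b,
    n_pixels = if ("n_pixels" %in% names(samples))
      samples$n_pixels else NA_real_,
    n_replicates = if ("n_replicates" %in% names(samples))
      samples$n_replicates else 1L,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(samples),
                   c("sample_id", "mlss", "r", "g", "b", "n_pixels",
                     "n_replicates"))
  for (nm in extra) out[[nm]] <- samples[[nm]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
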