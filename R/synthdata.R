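#' @include AllClasses.R conditions.R imaging.R
NULL

#' Construct a synthetic dish scene configuration
#'
#' Defaults emulate the bundled reference calibration: a near-white interior
#' (232, 232, 234) at zero MLSS, per-channel attenuation (0.020, 0.038,
#' 0.090) per g/L as fitted from the reference table's low-MLSS regime, a
#' bright rim, a dark background, and 1 intensity unit of Gaussian sensor
#' noise.
#'
#' @param width,height image size in pixels.
#' @param dishCenter length-2 (cx, cy) centre; defaults to the image centre.
#' @param dishRadius outer dish radius in pixels (rim included).
#' @param rimWidth rim annulus width in pixels.
#' @param rimColor,backgroundColor,baseColor length-3 RGB in [0, 255].
#' @param attenuation length-3 per-channel attenuation per g/L; the default
#'   ordering kappa_B > kappa_G > kappa_R reflects the stronger absorption of
#'   blue light by the darkening culture.
#' @param noiseSd additive Gaussian noise sd in intensity units.
#' @param seed integer root seed for the per-image random streams.
#' @return A \code{\linkS4class{SceneConfig}}.
#' @examples
#' sceneConfig(noiseSd = 0)
#' @export
sceneConfig <- function(width = 400L, height = 400L,
                        dishCenter = c(width / 2, height / 2),
                        dishRadius = 150, rimWidth = 10,
                        rimColor = c(255, 255, 255),
                        backgroundColor = c(40, 40, 40),
                        baseColor = c(232, 232, 234),
                        attenuation = c(0.020, 0.038, 0.090),
                        noiseSd = 1, seed = 1L) {
  cfg <- new("SceneConfig", width = as.integer(width),
             height = as.integer(height),
             dishCenter = as.numeric(dishCenter),
             dishRadius = as.numeric(dishRadius),
             rimWidth = as.numeric(rimWidth),
             rimColor = as.numeric(rimColor),
             backgroundColor = as.numeric(backgroundColor),
             baseColor = as.numeric(baseColor),
             attenuation = as.numeric(attenuation),
             noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
  cfg
}

#' Beer-Lambert attenuation
#'
#' Transmitted intensity after passage through a culture of concentration
#' \code{mlss}: \code{base * exp(-kappa * mlss)}. Vectorized over any
#' argument.
#'
#' @param base intensity at zero concentration (>= 0).
#' @param kappa attenuation coefficient per g/L (>= 0).
#' @param mlss concentration in g/L (>= 0).
#' @return Attenuated intensity.
#' @examples
#' attenuate(200, 0.1, 10) # 200 / e
#' @export
attenuate <- function(base, kappa, mlss) {
  if (any(base < 0) || any(kappa < 0) || any(mlss < 0)) {
    stopUsage("base, kappa and mlss must be non-negative")
  }
  base * exp(-kappa * mlss)
}

# Derived per-image seed: reproducible in isolation for any (sample,
# replicate) pair, and well below 2^31.
deriveSeed <- function(root, sampleIndex, replicateIndex) {
  as.integer((((root %% 20011) + 1) * 100003 +
                sampleIndex * 1009 + replicateIndex * 31) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a synthetic dish image
#'
#' Fills the background, draws the bright rim annulus, and sets every
#' interior pixel per channel to the Beer-Lambert value
#' \code{attenuate(base, kappa, mlss)} plus additive Gaussian sensor noise,
#' then rounds and clamps to the 8-bit range (clamping models sensor
#' saturation). The noise stream is seeded from the scene seed and the
#' (sample, replicate) indices, so any single image regenerates identically
#' in isolation.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param mlss concentration in g/L.
#' @param sampleIndex,replicateIndex indices identifying the image within a
#'   series; they select the noise stream.
#' @return Integer image array (height, width, 3).
#' @examples
#' img <- renderDishImage(sceneConfig(noiseSd = 0), mlss = 5)
#' img[200, 200, ]
#' @export
renderDishImage <- function(config, mlss, sampleIndex = 1L,
                            replicateIndex = 1L) {
  stopifnot(is(config, "SceneConfig"))
  if (length(mlss) != 1L || !is.finite(mlss) || mlss < 0) {
    stopUsage("mlss must be a non-negative scalar")
  }
  cx <- config@dishCenter[1L]; cy <- config@dishCenter[2L]
  r <- config@dishRadius
  if (cx - r < 0 || cx + r > config@width || cy - r < 0 ||
      cy + r > config@height) {
    stopUsage("dish does not fit inside the image")
  }
  h <- config@height; w <- config@width
  dy2 <- ((seq_len(h) - 0.5) - cy)^2
  dx2 <- ((seq_len(w) - 0.5) - cx)^2
  d2 <- outer(dy2, dx2, `+`)
  rimInner <- r - config@rimWidth
  interior <- d2 < rimInner^2
  rim <- d2 < r^2 & !interior
  img <- array(0, dim = c(h, w, 3L))
  mu <- attenuate(config@baseColor, config@attenuation, mlss)
  nInt <- sum(interior)
  noise <- if (config@noiseSd > 0 && nInt > 0) {
    withSeed(deriveSeed(config@seed, sampleIndex, replicateIndex),
             matrix(stats::rnorm(3L * nInt, 0, config@noiseSd), nInt, 3L))
  } else {
    matrix(0, nInt, 3L)
  }
  for (c in 1:3) {
    plane <- matrix(config@backgroundColor[c], h, w)
    plane[rim] <- config@rimColor[c]
    plane[interior] <- mu[c] + noise[, c]
    img[, , c] <- plane
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Generate a synthetic calibration series
#'
#' For each requested MLSS value, produces \code{replicates} measurements
#' and averages them into one calibration row, mirroring the
#' three-images-per-sample protocol. With \code{rasterize = TRUE} the
#' measurements go through the full imaging path (render, then
#' \code{\link{meanRGB}} over the dish interior); the default analytic
#' shortcut emits each replicate's channel means directly as the
#' Beer-Lambert value plus Gaussian noise of sd \code{noiseSd /
#' sqrt(nPixels)} (the sampling noise of a mean over that many pixels),
#' skipping quantization. The shortcut keeps large simulations cheap; the
#' rasterized path exists to validate the full pipeline.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param mlssValues numeric vector of true MLSS values, g/L.
#' @param replicates images per sample (>= 1).
#' @param rasterize render full images instead of the analytic shortcut.
#' @param shrink ROI shrink factor used when rasterizing.
#' @param outdir if non-NULL (implies rasterization), PNG images named
#'   \code{sample<ID>_rep<K>.png} and a \code{manifest.csv} (extraction
#'   schema plus a \code{true_mlss} column) are written there.
#' @return Calibration table (in-memory schema; \code{mlss} holds the true
#'   values).
#' @examples
#' cfg <- sceneConfig(noiseSd = 0)
#' generateSeries(cfg, mlssValues = 0:7, replicates = 1)
#' @export
generateSeries <- function(config, mlssValues, replicates = 3L,
                           rasterize = FALSE, shrink = 0.8, outdir = NULL) {
  stopifnot(is(config, "SceneConfig"))
  if (length(replicates) != 1L || replicates < 1L) {
    stopUsage("replicates must be >= 1")
  }
  if (!is.null(outdir)) {
    rasterize <- TRUE
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  empty <- data.frame(sample_id = character(0), mlss = numeric(0),
                      r = numeric(0), g = numeric(0), b = numeric(0),
                      n_pixels = numeric(0), n_replicates = integer(0),
                      stringsAsFactors = FALSE)
  if (length(mlssValues) == 0L) return(empty)
  if (any(!is.finite(mlssValues)) || any(mlssValues < 0)) {
    stopUsage("mlssValues must be non-negative and finite")
  }
  roi <- circularROI(config@dishCenter[1L], config@dishCenter[2L],
                     config@dishRadius)
  if (!rasterize) {
    # pixel count of the shrunken interior, matching the rasterized path
    dy2 <- ((seq_len(config@height) - 0.5) - roi@cy)^2
    dx2 <- ((seq_len(config@width) - 0.5) - roi@cx)^2
    nPix <- sum(outer(dy2, dx2, `+`) < (roi@radius * shrink)^2)
    if (nPix == 0L) stopUsage("shrunken ROI contains no pixels")
  }
  rows <- vector("list", length(mlssValues))
  for (i in seq_along(mlssValues)) {
    m <- mlssValues[i]
    reps <- vector("list", replicates)
    for (k in seq_len(replicates)) {
      if (rasterize) {
        img <- renderDishImage(config, m, sampleIndex = i,
                               replicateIndex = k)
        if (!is.null(outdir)) {
          png::writePNG(img / 255,
                        file.path(outdir,
                                  sprintf("sample%03d_rep%d.png", i, k)))
        }
        reps[[k]] <- meanRGB(img, roi, shrink = shrink)
      } else {
        mu <- attenuate(config@baseColor, config@attenuation, m)
        eps <- if (config@noiseSd > 0) {
          withSeed(deriveSeed(config@seed, i, k),
                   stats::rnorm(3L, 0, config@noiseSd / sqrt(nPix)))
        } else c(0, 0, 0)
        v <- pmin(255, pmax(0, mu + eps))
        reps[[k]] <- rgbMean(v[1L], v[2L], v[3L], nPixels = nPix)
      }
    }
    avg <- averageReplicates(reps)
    rows[[i]] <- data.frame(
      sample_id = sprintf("sample%03d", i), mlss = m,
      r = avg@r, g = avg@g, b = avg@b, n_pixels = avg@nPixels,
      n_replicates = as.integer(replicates), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(outdir)) {
    manifest <- out
    manifest$true_mlss <- manifest$mlss
    writeExtractionTable(manifest, file.path(outdir, "manifest.csv"))
  }
  out
}

#' Bundled reference calibration table
#'
#' The packaged reference dataset: 23 activated-sludge dish measurements
#' spanning MLSS 0 to 14.901 g/L, each row the average of three images, with
#' mean red, green and blue intensities on the 0-255 scale. Two rows (MLSS
#' 12.98 and 13.52 g/L) are marked as excluded from the canonical reference
#' fit: the reference slopes, grayscale weights and error statistics that
#' this dataset reproduces derive from the remaining 21 samples, and the two
#' extra rows are kept for validation.
#'
#' @param fittedOnly logical; return only the 21 rows belonging to the
#'   canonical reference fit.
#' @return Calibration table in the in-memory schema (see
#'   \code{\link{readCalibrationTable}}), with the logical column
#'   \code{in_reference_fit}.
#' @examples
#' nrow(referenceCalibration())            # 23
#' nrow(referenceCalibration(fittedOnly = TRUE)) # 21
#' @export
referenceCalibration <- function(fittedOnly = FALSE) {
  path <- system.file("extdata", "reference_calibration.csv",
                      package = "sludgeRGB", mustWork = TRUE)
  tab <- readCalibrationTable(path)
  tab$in_reference_fit <- as.logical(tab$in_reference_fit)
  if (isTRUE(fittedOnly)) tab <- tab[tab$in_reference_fit, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
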