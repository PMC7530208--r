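test_that("loadImage decodes 8-bit images, promotes grayscale, drops alpha", {
  f <- tempfile(fileext = ".png")
  png::writePNG(array(rep(c(10, 20, 30) / 255, each = 4), c(2, 2, 3)), f)
  img <- loadImage(f)
  expect_identical(dim(img), c(2L, 2L, 3L))
  expect_true(all(img[, , 1] == 10L & img[, , 2] == 20L & img[, , 3] == 30L))

  g <- tempfile(fileext = ".png")
  png::writePNG(matrix(77 / 255, 3, 4), g)
  gi <- loadImage(g)
  expect_identical(dim(gi), c(3L, 4L, 3L))
  expect_true(all(gi == 77L))

  a <- tempfile(fileext = ".png")
  png::writePNG(array(c(rep(0.5, 12), rep(1, 4)), c(2, 2, 4)), a)
  ai <- loadImage(a)
  expect_identical(dim(ai), c(2L, 2L, 3L))

  j <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(array(0.5, c(4, 4, 3)), j, quality = 1)
  expect_identical(dim(loadImage(j)), c(4L, 4L, 3L))
})

test_that("loadImage rejects unsupported depths, formats and corrupt files", {
  t16 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(2, 2, 3)), t16, bits.per.sample = 16L)
  expect_error(loadImage(t16), "unsupported bit depth",
               class = "sludgeInputError")

  bad <- tempfile(fileext = ".png")
  writeLines("this is not a png", bad)
  expect_error(loadImage(bad), "corrupt", class = "sludgeInputError")

  expect_error(loadImage(tempfile(fileext = ".png")),
               class = "sludgeInputError")
  txt <- tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(loadImage(txt), "unsupported image format",
               class = "sludgeInputError")
})

test_that("meanRGB averages exactly on constant images for any valid ROI", {
  img <- uniformImage(30, 40, c(10, 20, 30))
  for (roi in list(circularROI(20, 15, 10), circularROI(10.5, 14.2, 7))) {
    for (shrink in c(1, 0.8, 0.3)) {
      m <- meanRGB(img, roi, shrink = shrink)
      expect_equal(unname(rgbValues(m)), c(10, 20, 30))
    }
  }
})

test_that("meanRGB recovers rendered interior colour and flags bad ROIs", {
  img <- drawDisk(100, 100, 50, 50, 40, fg = c(200, 150, 100),
                  bg = c(255, 255, 255))
  m <- meanRGB(img, circularROI(50, 50, 40), shrink = 0.8)
  expect_lt(max(abs(unname(rgbValues(m)) - c(200, 150, 100))), 0.5)

  expect_error(meanRGB(img, circularROI(50, 50, 0.3), shrink = 1),
               "empty ROI", class = "sludgeUsageError")
  expect_error(meanRGB(img, circularROI(95, 50, 40), shrink = 1),
               "outside the image", class = "sludgeUsageError")
})

test_that("meanRGB is invariant under joint image/ROI translation", {
  base <- drawDisk(80, 80, 30, 35, 20, fg = c(120, 90, 60))
  shifted <- drawDisk(80, 80, 42, 29, 20, fg = c(120, 90, 60))
  m1 <- meanRGB(base, circularROI(30, 35, 20), shrink = 0.9)
  m2 <- meanRGB(shifted, circularROI(42, 29, 20), shrink = 0.9)
  expect_equal(rgbValues(m1), rgbValues(m2))
  expect_equal(m1@nPixels, m2@nPixels)
})

test_that("averageReplicates is an unweighted mean, permutation-invariant", {
  expect_equal(unname(rgbValues(averageReplicates(
    list(rgbMean(1, 1, 1), rgbMean(3, 3, 3))))), c(2, 2, 2))
  expect_equal(unname(rgbValues(averageReplicates(list(rgbMean(5, 5, 5))))),
               c(5, 5, 5))
  trio <- list(rgbMean(0, 0, 0), rgbMean(255, 255, 255), rgbMean(0, 0, 0))
  expect_equal(unname(rgbValues(averageReplicates(trio))), rep(255 / 3, 3))
  expect_equal(rgbValues(averageReplicates(trio)),
               rgbValues(averageReplicates(rev(trio))))
  # unweighted regardless of per-image pixel counts
  uneven <- list(rgbMean(10, 10, 10, nPixels = 1000),
                 rgbMean(20, 20, 20, nPixels = 1))
  avg <- averageReplicates(uneven)
  expect_equal(unname(rgbValues(avg)), c(15, 15, 15))
  expect_equal(avg@nPixels, 1001)
  expect_error(averageReplicates(list()), class = "sludgeUsageError")
})

test_that("saturationFraction counts clipped pixels inside the ROI", {
  expect_equal(saturationFraction(uniformImage(20, 20, c(255, 255, 255)),
                                  circularROI(10, 10, 8)), 1.0)
  expect_equal(saturationFraction(uniformImage(20, 20, c(100, 100, 100)),
                                  circularROI(10, 10, 8)), 0.0)
  # left half of the image saturated in one channel only
  img <- uniformImage(40, 40, c(0, 0, 0))
  img[, 1:20, 1] <- 255L
  frac <- saturationFraction(img, circularROI(20, 20, 15))
  expect_lt(abs(frac - 0.5), 1 / (pi * 15^2 / 40)) # within one pixel row
})

test_that("detectDishROI finds a rendered dish to within 2 px", {
  cfg <- sceneConfig(noiseSd = 0)
  img <- renderDishImage(cfg, mlss = 3)
  roi <- detectDishROI(img)
  expect_lt(abs(roi@cx - 200), 2)
  expect_lt(abs(roi@cy - 200), 2)
  expect_lt(abs(roi@radius - 150), 2)
  # detection is deterministic
  roi2 <- detectDishROI(img)
  expect_identical(c(roi@cx, roi@cy, roi@radius),
                   c(roi2@cx, roi2@cy, roi2@radius))
})

test_that("detectDishROI refuses featureless and border-clipped scenes", {
  expect_error(detectDishROI(uniformImage(60, 60, c(90, 90, 90))),
               "no circle found", class = "sludgeInputError")
  clipped <- drawDisk(100, 100, 15, 50, 30, fg = c(230, 230, 230))
  expect_error(detectDishROI(clipped), class = "sludgeInputError")
})

test_that("extraction tables round-trip through CSV", {
  tab <- makeTable(c(0, 1, 2), c(230, 220, 210), c(231, 215, 200),
                   c(233, 210, 180))
  f <- tempfile(fileext = ".csv")
  writeExtractionTable(tab, f)
  back <- readCalibrationTable(f)
  expect_equal(back$mlss, tab$mlss)
  expect_equal(back$b, tab$b)
  header <- readLines(f, n = 1)
  expect_match(header,
               '"sample_id","mlss_g_per_L","r_mean","g_mean","b_mean"')
  expect_error(readCalibrationTable(tempfile()), class = "sludgeInputError")
})
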