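test_that("fitChannel matches closed-form OLS on hand-worked cases", {
  collinear <- makeTable(c(0, 1, 2), r = c(10, 8, 6), g = c(10, 8, 6),
                         b = c(10, 8, 6))
  fit <- fitChannel(collinear, "B")
  expect_equal(slope(fit), -2)
  expect_equal(intercept(fit), 10)
  expect_equal(rSquared(fit), 1)

  # SS_res = 1.5, SS_tot = 2 by hand
  wiggly <- makeTable(c(0, 1, 2), r = c(1, 3, 2), g = c(1, 3, 2),
                      b = c(1, 3, 2))
  fit <- fitChannel(wiggly, "R")
  expect_equal(slope(fit), 0.5)
  expect_equal(intercept(fit), 1.5)
  expect_equal(rSquared(fit), 0.25)
})

test_that("fitChannel rejects degenerate designs", {
  expect_error(fitChannel(makeTable(c(0, 1), c(1, 2), c(1, 2), c(1, 2)), "R"),
               "insufficient samples", class = "sludgeInputError")
  same <- makeTable(c(2, 2, 2), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_error(fitChannel(same, "G"), "identical",
               class = "sludgeDegenerateError")
})

test_that("fitChannel agrees with the sigma-formula oracle on random data", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- round(runif(n, 0, 15), 3)
    if (length(unique(x)) < 2) next
    y <- round(240 - 9 * x + rnorm(n, 0, 4), 3)
    y <- pmin(255, pmax(0, y))
    tab <- makeTable(x, y, y, y)
    fit <- fitChannel(tab, "B")
    orc <- olsOracle(x, y)
    expect_equal(slope(fit), orc$slope, tolerance = 1e-9)
    expect_equal(intercept(fit), orc$intercept, tolerance = 1e-9)
    expect_equal(rSquared(fit), orc$r2, tolerance = 1e-9)
  }
})

test_that("grayCoefficients normalizes slopes and polices signs", {
  k <- grayCoefficients(-1, -1, -1)
  expect_equal(unname(grayWeights(k)), rep(1 / 3, 3))
  expect_error(grayCoefficients(2, -1, -1), class = "sludgeDegenerateError")
  expect_error(grayCoefficients(0, -1, -1), class = "sludgeDegenerateError")

  set.seed(7)
  for (i in 1:50) {
    m <- -runif(3, 0.1, 20)
    k <- unname(grayWeights(do.call(grayCoefficients, as.list(m))))
    expect_lt(abs(sum(k) - 1), 1e-9)
    expect_true(all(k > 0 & k < 1))
    # permuting the slopes permutes the weights identically
    p <- sample(3)
    kp <- unname(grayWeights(do.call(grayCoefficients, as.list(m[p]))))
    expect_equal(kp, k[p], tolerance = 1e-12)
  }
})

test_that("toGrayscale is a weight-preserving linear map", {
  k <- grayCoefficients(-5.3117, -8.9099, -14.404)
  expect_equal(toGrayscale(c(233.6, 233.6, 233.6), k), 233.6)
  expect_equal(toGrayscale(c(0, 0, 0), k), 0)
  expect_equal(toGrayscale(c(232.08, 232.09, 233.6), k), 232.85,
               tolerance = 5e-5)
  expect_equal(toGrayscale(rgbMean(232.08, 232.09, 233.6), k),
               toGrayscale(c(232.08, 232.09, 233.6), k))
  # linearity over convex combinations
  set.seed(11)
  for (i in 1:20) {
    x <- runif(3, 0, 255); y <- runif(3, 0, 255); a <- runif(1)
    expect_equal(toGrayscale(a * x + (1 - a) * y, k),
                 a * toGrayscale(x, k) + (1 - a) * toGrayscale(y, k),
                 tolerance = 1e-10)
  }
  # matrix method vectorizes row-wise
  m <- rbind(x, y)
  expect_equal(toGrayscale(m, k),
               c(toGrayscale(x, k), toGrayscale(y, k)))
})

test_that("fitExponential recovers exact Beer-Lambert data", {
  m <- 0:7
  tab <- makeTable(m, r = 230 * exp(-0.18 * m), g = 230 * exp(-0.18 * m),
                   b = 230 * exp(-0.18 * m))
  fit <- fitExponential(tab, "B", mlssMax = 8)
  expect_equal(fit@v0, 230, tolerance = 1e-9)
  expect_equal(fit@kappa, 0.18, tolerance = 1e-9)
  expect_equal(fit@rSquaredLog, 1, tolerance = 1e-12)
  expect_equal(fit@rSquaredLinear, 1, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:25) {
    kappa <- runif(1, 0.01, 0.5)
    v0 <- runif(1, 50, 250)
    tab <- makeTable(m, r = v0 * exp(-kappa * m), g = v0 * exp(-kappa * m),
                     b = v0 * exp(-kappa * m))
    fit <- fitExponential(tab, "G", mlssMax = 8)
    expect_equal(fit@v0, v0, tolerance = 1e-9)
    expect_equal(fit@kappa, kappa, tolerance = 1e-9)
  }
})

test_that("fitExponential enforces its log-domain and subset preconditions", {
  tab <- makeTable(0:3, r = c(10, 5, 0, 1), g = c(10, 5, 2, 1),
                   b = c(10, 5, 2, 1))
  expect_error(fitExponential(tab, "R", mlssMax = 8), "<= 0",
               class = "sludgeDegenerateError")
  expect_error(fitExponential(tab, "B", mlssMax = 0.5),
               class = "sludgeInputError")
})

test_that("buildModel assembles consistent fits and weights", {
  tab <- referenceCalibration(fittedOnly = TRUE)
  model <- buildModel(tab)
  k <- grayWeights(model)
  expect_lt(abs(sum(k) - 1), 1e-9)
  # weights are the normalized colour-channel slopes
  m3 <- c(slope(channelFit(model, "R")), slope(channelFit(model, "G")),
          slope(channelFit(model, "B")))
  expect_equal(unname(k), m3 / sum(m3), tolerance = 1e-12)
  # the GRAY fit is the fit of the composite those weights produce
  gray <- toGrayscale(cbind(tab$r, tab$g, tab$b), model@gray)
  orc <- olsOracle(tab$mlss, gray)
  expect_equal(slope(channelFit(model, "GRAY")), orc$slope,
               tolerance = 1e-9)
  expect_equal(rSquared(channelFit(model, "GRAY")), orc$r2,
               tolerance = 1e-9)
  # all-collinear input gives perfect fits across channels
  coll <- makeTable(0:3, r = 200 - 2 * (0:3), g = 210 - 3 * (0:3),
                    b = 220 - 5 * (0:3))
  mc <- buildModel(coll)
  for (ch in c("R", "G", "B", "GRAY")) {
    expect_equal(rSquared(channelFit(mc, ch)), 1, tolerance = 1e-12)
  }
})

test_that("model JSON serialization round-trips bit-stably", {
  model <- buildModel(referenceCalibration(),
                      metadata = list(f_number = 5.6, iso = 100))
  f <- tempfile(fileext = ".json")
  writeModelJSON(model, f)
  back <- readModelJSON(f)
  for (ch in c("R", "G", "B", "GRAY")) {
    expect_identical(slope(channelFit(back, ch)),
                     slope(channelFit(model, ch)))
    expect_identical(intercept(channelFit(back, ch)),
                     intercept(channelFit(model, ch)))
    expect_identical(rSquared(channelFit(back, ch)),
                     rSquared(channelFit(model, ch)))
  }
  expect_identical(grayWeights(back), grayWeights(model))
  eb <- exponentialFit(back, "B"); em <- exponentialFit(model, "B")
  expect_identical(eb@v0, em@v0)
  expect_identical(eb@kappa, em@kappa)
  expect_equal(back@metadata$f_number, 5.6)
})
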