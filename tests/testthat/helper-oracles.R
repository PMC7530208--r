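# Independent oracles and small fixture builders used across the tests.

# Closed-form simple linear regression via explicit sums; deliberately
# independent of stats::lm and of the package's fitting code.
olsOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Uniform-colour image grid.
uniformImage <- function(h, w, rgb) {
  array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3L))
}

# Calibration table from plain vectors.
makeTable <- function(mlss, r, g, b) {
  data.frame(sample_id = sprintf("s%02d", seq_along(mlss)),
             mlss = mlss, r = r, g = g, b = b,
             n_pixels = NA_real_, n_replicates = 1L,
             stringsAsFactors = FALSE)
}

# Draw a hard-edged disk directly (independent of the package renderer):
# pixel centres (col - 0.5, row - 0.5), strict inequality.
drawDisk <- function(h, w, cx, cy, radius, fg, bg = c(0, 0, 0)) {
  img <- uniformImage(h, w, bg)
  d2 <- outer(((seq_len(h) - 0.5) - cy)^2, ((seq_len(w) - 0.5) - cx)^2, `+`)
  m <- d2 < radius^2
  for (c in 1:3) {
    plane <- img[, , c]
    plane[m] <- as.integer(fg[c])
    img[, , c] <- plane
  }
  img
}
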