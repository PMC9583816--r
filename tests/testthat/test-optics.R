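test_that("detection-plane geometry follows the imaging scheme", {
  g <- OpticalGeometry(axialChromaticSeparation = 10, gdpOffset = 4)
  expect_equal(bdpOffset(computeDetectionPlanes(g, "conjugated")), 14)
  expect_equal(bdpOffset(computeDetectionPlanes(g, "optimized")), 0)

  g0 <- OpticalGeometry(axialChromaticSeparation = 0, gdpOffset = 4)
  expect_equal(bdpOffset(computeDetectionPlanes(g0, "conjugated")), 4)

  # conjugated depth is linear in the chromatic separation
  for (delta in c(0.5, 2, 7.3)) {
    gd <- OpticalGeometry(axialChromaticSeparation = 10 + delta,
                          gdpOffset = 4)
    expect_equal(bdpOffset(computeDetectionPlanes(gd, "conjugated")),
                 14 + delta)
  }

  # a plane above the block face is flagged, not raised
  g2 <- OpticalGeometry(axialChromaticSeparation = 10, gdpOffset = 2)
  out <- computeDetectionPlanes(g2, "optimized")
  expect_equal(bdpOffset(out), -2)
  expect_true(out@bdpOutOfSample)

  # FOV side is tied to the pixel grid
  expect_equal(fovSide(g), 1800 * 0.32)
  expect_error(new("OpticalGeometry", axialChromaticSeparation = 10,
                   gdpOffset = 4, fovSide = 500, pixelSizeLateral = 0.32,
                   imageWidthPx = 1800), "fovSide")
})

test_that("Gaussian FWHM fitting is exact on noise-free profiles and
           invariant to background and scaling", {
  x <- seq(-2, 2, by = 0.05)
  f <- fitFwhm(x, exp(-x^2 / (2 * 0.2^2)))
  expect_equal(as.numeric(f), 2 * sqrt(2 * log(2)) * 0.2, tolerance = 1e-6)
  expect_equal(round(as.numeric(f), 4), 0.471)

  # additive offset and multiplicative scaling leave the FWHM unchanged
  xs <- seq(-5, 5, by = 0.1)
  for (sigma in c(0.3, 1.0, 1.7)) {
    base <- exp(-xs^2 / (2 * sigma^2))
    ref <- as.numeric(fitFwhm(xs, base))
    expect_equal(attr(fitFwhm(xs, base), "fit")[["sigma"]], sigma,
                 tolerance = 1e-6)
    expect_equal(as.numeric(fitFwhm(xs, 7 + base)), ref, tolerance = 1e-7)
    expect_equal(as.numeric(fitFwhm(xs, 123 * base)), ref, tolerance = 1e-7)
    expect_equal(as.numeric(fitFwhm(xs, 40 + 555 * base)), ref,
                 tolerance = 1e-7)
  }
  expect_equal(as.numeric(fitFwhm(x, 5 + exp(-x^2 / 2))), 2.3548,
               tolerance = 1e-4)

  # numerically sampled bead profile: sigma = 0.23 um on a 0.1 um grid
  xg <- seq(0, 6, by = 0.1)
  prof <- exp(-(xg - 3.04)^2 / (2 * 0.23^2))
  got <- as.numeric(fitFwhm(xg, prof))
  expect_lt(abs(got - 0.5416) / 0.5416, 0.02)

  expect_error(fitFwhm(x, rep(3, length(x))), class = "wvtMeasurementError")
  expect_error(fitFwhm(1:3, c(0, 1, 0)), class = "wvtMeasurementError")
})

test_that("bead resolution measurement recovers analytic FWHMs and excludes
           merged beads", {
  withr::with_seed(41, {
    bf <- makeBeadField(nBeads = 8, sigmaUm = c(0.2, 1.0),
                        readNoiseSd = 0, shot = FALSE, jitter = FALSE)
    m <- measureBeadResolution(bf$stack)
    # identical noise-free replicates: negligible spread
    expect_lt(m@semLateral, 1e-6)
    expect_lt(m@semAxial, 1e-6)
    expect_equal(m@nBeads, 8L)

    bf2 <- makeBeadField(nBeads = 10, sigmaUm = c(0.2, 1.0))
    m2 <- measureBeadResolution(bf2$stack)
    expect_lt(abs(m2@lateralFwhm - bf2$truth$lateralFwhm) /
                bf2$truth$lateralFwhm, 0.05)
    expect_lt(abs(m2@axialFwhm - bf2$truth$axialFwhm) /
                bf2$truth$axialFwhm, 0.05)
  })
})

test_that("beads closer than the isolation radius are excluded from the
           aggregate", {
  vox <- c(0.32, 0.32, 0.2)
  stack <- array(0, dim = c(64, 64, 60))
  addBead <- function(s, xUm, yUm, zUm) {
    d <- dim(s)
    gx <- exp(-((0:(d[2] - 1)) * vox[1] - xUm)^2 / (2 * 0.2^2))
    gy <- exp(-((0:(d[1] - 1)) * vox[2] - yUm)^2 / (2 * 0.2^2))
    gz <- exp(-((0:(d[3] - 1)) * vox[3] - zUm)^2 / (2 * 1.0^2))
    s + 5000 * outer(gy, gx) %o% gz
  }
  # two isolated beads plus a pair separated well below 3 x FWHM (= 1.41 um)
  stack <- addBead(stack, 5, 5, 5)
  stack <- addBead(stack, 15, 15, 7)
  stack <- addBead(stack, 4.8, 15, 6)
  stack <- addBead(stack, 6.08, 15, 6)
  m <- measureBeadResolution(stack, vox)
  expect_equal(m@nBeads, 2L)
  expect_true(all(m@perBead$y < 10 | m@perBead$x > 10))

  expect_error(measureBeadResolution(array(7, dim = c(16, 16, 16)), vox),
               class = "wvtEmptyMeasurementError")
})
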