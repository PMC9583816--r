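test_that("phantom generation is fully deterministic under its seed and
           honours the requested content", {
  sp <- phantomSpec(nLayers = 2L, imageSizePx = 512L,
                    semiAxes = cbind(c(180, 200), c(130, 150)),
                    nGreen = 400L, nRed = 350L, seed = 99L)
  a <- generatePhantom(sp, renderChannels = TRUE)
  b <- generatePhantom(sp, renderChannels = TRUE)
  expect_identical(a$layers[[1]]$dapi, b$layers[[1]]$dapi)
  expect_identical(a$layers[[2]]$green, b$layers[[2]]$green)
  expect_identical(somaCoords(a$truth$green), somaCoords(b$truth$green))
  expect_identical(a$truth$pairs, b$truth$pairs)
  expect_equal(nSomas(a$truth$green), 400L)
  expect_equal(nSomas(a$truth$red), 350L)

  # caller's RNG stream is untouched by the generator's internal seed
  set.seed(1); u1 <- runif(1)
  set.seed(1); invisible(generatePhantom(sp)); u2 <- runif(1)
  expect_identical(u1, u2)

  sp0 <- phantomSpec(nLayers = 1L, imageSizePx = 512L,
                     semiAxes = cbind(180, 130), nGreen = 300L, nRed = 300L,
                     colocFraction = 0, seed = 12L)
  p0 <- generatePhantom(sp0)
  expect_equal(nrow(p0$truth$pairs), 0L)
  expect_equal(p0$truth$nPairs, 0L)
})

test_that("every phantom soma falls in a labelled atlas voxel consistent
           with its planted region", {
  sp <- phantomSpec(nLayers = 1L, imageSizePx = 512L,
                    semiAxes = cbind(200, 150), nGreen = 800L, nRed = 0L,
                    seed = 23L)
  ph <- generatePhantom(sp)
  rep <- countByRegion(ph$truth$green, ph$truth$atlas, "region")
  tab <- regionTable(rep)
  expect_false(0 %in% tab$region_id)  # nothing unassigned
  expect_equal(tab$count[order(tab$region_id)], ph$truth$regionCounts)
})

test_that("structured-illumination modulation matches its closed form and
           demodulates exactly", {
  sc <- matrix(runif(32 * 32, 100, 900), 32, 32)
  # zero modulation depth halves the scene
  expect_equal(modulateSim(sc, 4, 1.1, modulationDepth = 0), sc / 2)
  expect_error(modulateSim(sc, periodUm = 0.6, 0), class = "wvtInputError")

  # three-phase round trip recovers m * scene / 2 to 1e-9
  for (phi in c(0, 1.2)) {
    tr <- modulateTriplet(sc, periodUm = 5, phase0 = phi,
                          modulationDepth = 0.7)
    out <- tilePixels(reconstructSim(tr))
    expect_lt(max(abs(out - 0.7 * sc / 2) / (0.7 * sc / 2)), 1e-9)
  }
})

test_that("field curvature leaks out-of-focus background into SIM near the
           field edge but not at the centre", {
  n <- 128
  oof <- matrix(1000, n, n)
  scene <- matrix(0, n, n)
  tr <- lapply(c(0, pi / 2, pi), function(p)
    modulateSim(scene, 6, p, 1, outOfFocus = oof, curvature = 0.3))
  sim <- tilePixels(reconstructSim(PhaseTriplet(tr[[1]], tr[[2]], tr[[3]])))
  ctr <- n / 2
  centerRes <- mean(sim[(ctr - 5):(ctr + 5), (ctr - 5):(ctr + 5)])
  edgeRes <- mean(sim[, c(1:6, (n - 5):n)])
  expect_gt(edgeRes, 10 * max(centerRes, 1e-9))
  # flat illumination plane: background fully rejected everywhere
  tr0 <- lapply(c(0, pi / 2, pi), function(p)
    modulateSim(scene, 6, p, 1, outOfFocus = oof, curvature = 0))
  sim0 <- tilePixels(reconstructSim(PhaseTriplet(tr0[[1]], tr0[[2]],
                                                 tr0[[3]])))
  expect_lt(max(sim0), 1e-9)
})

test_that("nuclear crosstalk in the green channel vanishes at the
           crosstalk-free detection depth", {
  expect_equal(stainingWeight(0), 1)
  expect_equal(stainingWeight(2), 0.5)
  expect_equal(stainingWeight(4), 0)
  expect_equal(stainingWeight(10), 0)

  sp <- phantomSpec(nLayers = 1L, imageSizePx = 512L,
                    semiAxes = cbind(200, 150), nGreen = 0L, nRed = 0L,
                    noiseSd = 20, seed = 31L)
  deep <- generatePhantom(sp, renderChannels = TRUE, gdpDepthUm = 4)
  shallow <- generatePhantom(sp, renderChannels = TRUE, gdpDepthUm = 0)
  nuc <- deep$layers[[1]]$nuclearSignal
  bright <- nuc > 3000  # nuclear spots
  # at 4 um depth the nuclear contribution sits at the noise floor ...
  gDeep <- deep$layers[[1]]$green
  expect_lt(abs(mean(gDeep[bright])), 3 * sp@noiseSd)
  expect_lt(stats::sd(gDeep[bright]), 2 * sp@noiseSd)
  # ... while a surface detection plane sees the full nuclear signal
  gShallow <- shallow$layers[[1]]$green
  expect_gt(mean(gShallow[bright]), 50 * sp@noiseSd)
})

test_that("misalignment injection records ground truth and flags transforms
           outside the recovery envelope", {
  ring <- makeRingTarget(96)
  tiles <- list(green = ring, blue = ring)
  idT <- list(blue = SimilarityTransform2D())
  out <- injectMisalignment(tiles, idT)
  expect_identical(out$blue[, ], ring)
  expect_length(attr(out, "warnings"), 0)

  big <- list(blue = SimilarityTransform2D(dx = 20 * 0.32))
  out2 <- injectMisalignment(tiles, big)
  expect_match(attr(out2, "warnings"), "envelope")
})

test_that("bead fields respect separation limits and give seed-independent
           resolution estimates", {
  withr::with_seed(55, {
    expect_error(makeBeadField(nBeads = 200, dims = c(40, 40, 60)),
                 class = "wvtPlacementError")
    b0 <- makeBeadField(nBeads = 0)
    expect_equal(nrow(b0$truth$positionsUm), 0L)
    expect_error(measureBeadResolution(b0$stack),
                 class = "wvtEmptyMeasurementError")

    m1 <- measureBeadResolution(makeBeadField(nBeads = 8)$stack)
    m2 <- measureBeadResolution(makeBeadField(nBeads = 8)$stack)
    expect_lt(abs(m1@lateralFwhm - m2@lateralFwhm), 0.05 * m1@lateralFwhm)
    expect_lt(abs(m1@axialFwhm - m2@axialFwhm), 0.05 * m1@axialFwhm)
  })
})
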