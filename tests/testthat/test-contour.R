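test_that("morphology pipeline is an identity on an ideal filled rectangle", {
  img <- matrix(100, 300, 300)
  img[81:220, 61:240] <- 4000
  # an ideal noise-free input needs no median denoising, and a box element
  # is exact on rectangles (discs round convex corners)
  pBox <- ContourParams(medianKernel = 1L, openingShape = "box")
  ct <- recognizeContour(img, pBox)
  truth <- matrix(0, 300, 300); truth[81:220, 61:240] <- 1
  expect_identical(contourMask(ct), truth)
  expect_equal(contourBBox(ct), c(60, 239, 80, 219) * 1.68)
  # the default disc element rounds the corners by less than its radius
  ctDisc <- recognizeContour(img, ContourParams())
  m <- contourMask(ctDisc)
  expect_gt(sum(m * truth) / sum(pmax(m, truth)), 0.999)
})

test_that("phantom contours: tissue recovered, fragments rejected, ventricle
           filled, noise yields an empty flag", {
  sp <- phantomSpec(nLayers = 1L, nGreen = 0L, nRed = 0L, seed = 71L)
  ph <- generatePhantom(sp)
  L <- ph$layers[[1]]
  ct <- recognizeContour(L$dapi)
  expect_false(isEmptyContour(ct))
  m <- contourMask(ct)
  iou <- sum(m * L$truthMask) / sum(pmax(m, L$truthMask))
  expect_gte(iou, 0.95)
  # the three planted fragments are absent from the mask
  fr <- ph$truth$fragments[[1]]
  expect_equal(nrow(fr), 3L)
  expect_true(all(m[cbind(round(fr[, 2]) + 1, round(fr[, 1]) + 1)] == 0))
  # the ventricle hole is filled: mask has no interior holes
  filled <- EBImage::fillHull(m)
  expect_identical(filled[, ], m)
  n <- sp@imageSizePx; ctr <- round((n - 1) / 2)
  expect_equal(m[round(ctr - 0.2 * sp@semiAxes[1, 2] / 1.68), ctr], 1)

  withr::with_seed(5, {
    noise <- matrix(rnorm(200 * 200, 100, 20), 200, 200)
    expect_true(isEmptyContour(recognizeContour(noise)))
  })
})

test_that("region planning rounds the margin-expanded rectangle up to the
           smallest covering lattice span", {
  sp <- MosaicSpec(fovSide = 576, overlap = 5)
  stride <- mosaicStride(sp)
  expect_equal(stride, 571)

  # 1144 um rectangle + 288 margin: 1720 um needs 4 columns (3 cover 1718)
  r <- planRegion(c(0, 1144, 0, 100), sp, margin = 288)
  expect_equal(r@col1 - r@col0 + 1L, 4L)

  # planning is idempotent for an unchanged rectangle
  r2 <- planRegion(c(0, 1144, 0, 100), sp, margin = 288)
  expect_equal(r@rectUm, r2@rectUm)
  expect_equal(nMosaics(r), nMosaics(r2))

  # margin 0, rectangle exactly one FOV at a lattice site
  r3 <- planRegion(c(571, 571 + 576, 1142, 1142 + 576), sp, margin = 0)
  expect_equal(c(r3@col0, r3@col1, r3@row0, r3@row1), c(1L, 1L, 2L, 2L))
  expect_equal(nMosaics(r3), 1L)

  # brute-force check of the covering span on random rectangles
  withr::with_seed(13, {
    for (i in 1:25) {
      lo <- runif(1, -500, 3000); hi <- lo + runif(1, 10, 4000)
      r <- planRegion(c(lo, hi, 0, 100), sp, margin = 0)
      bs <- bruteSpan1d(lo, hi, sp@fovSide, stride)
      expect_equal(c(r@col0, r@col1), as.integer(bs))
    }
  })

  # monotonicity: a larger rectangle never shrinks the span
  rA <- planRegion(c(100, 900, 100, 900), sp, margin = 288)
  rB <- planRegion(c(50, 1100, 0, 1000), sp, margin = 288)
  expect_lte(rB@col0, rA@col0); expect_gte(rB@col1, rA@col1)
  expect_lte(rB@row0, rA@row0); expect_gte(rB@row1, rA@row1)

  # stage limits: error by default, clipping on request
  expect_error(planRegion(c(0, 1144, 0, 100), sp, margin = 288,
                          stageLimits = c(0, 1200, 0, 1200)),
               class = "wvtPlanningError")
  expect_warning(rc <- planRegion(c(0, 1144, 0, 100), sp, margin = 288,
                                  stageLimits = c(0, 1200, 0, 1200),
                                  onLimit = "clip"), "clipped")
  expect_lte(rc@rectUm[2], 1200)
  expect_error(planRegion(c(0, 100, 0, 100), sp, margin = -1))
})

test_that("whole-brain planning: constant sections give identical regions,
           tapered sections save mosaics, empty layers reuse regions", {
  sp <- MosaicSpec()
  # constant cross-section: all regions identical
  cst <- phantomSpec(nLayers = 3L, semiAxes = cbind(rep(380, 3), rep(280, 3)),
                     nGreen = 0L, nRed = 0L, seed = 5L)
  ph <- generatePhantom(cst)
  pl <- planWholeBrain(lapply(ph$layers, `[[`, "dapi"), sp)
  counts <- pl$perLayer$n_mosaics
  expect_true(all(counts == counts[1]))
  expect_equal(length(unique(vapply(pl$regions, function(r)
    paste(r@col0, r@col1, r@row0, r@row1), ""))), 1L)

  # tapered: counts rise then fall; recognition beats the fixed region
  tp <- phantomSpec(nLayers = 5L, nGreen = 0L, nRed = 0L, seed = 6L)
  ph2 <- generatePhantom(tp)
  pl2 <- planWholeBrain(lapply(ph2$layers, `[[`, "dapi"), sp)
  n2 <- pl2$perLayer$n_mosaics
  expect_lte(n2[1], max(n2))
  expect_true(!is.unsorted(n2[1:which.max(n2)]))
  expect_true(!is.unsorted(rev(n2[which.max(n2):5])))
  expect_lt(sum(n2), sum(pl2$perLayer$n_fixed))
  # consecutive spans live on one fixed lattice: coverage edges are lattice
  # multiples of the stride
  for (r in pl2$regions) {
    cov <- regionCoverage(r, sp)
    expect_equal((cov$x[1]) %% mosaicStride(sp), 0)
    expect_equal((cov$y[1]) %% mosaicStride(sp), 0)
  }

  # a blank (unrecognizable) middle layer reuses the previous region
  blank <- matrix(100, tp@imageSizePx, tp@imageSizePx)
  layers3 <- lapply(ph2$layers, `[[`, "dapi")
  layers3[[3]] <- blank
  pl3 <- planWholeBrain(layers3, sp)
  expect_true(pl3$perLayer$empty_contour[4])
  expect_equal(nMosaics(pl3$regions[[4]]), nMosaics(pl3$regions[[3]]))
})

test_that("stitching blends overlaps without seams and preserves constants", {
  sp <- MosaicSpec(fovSide = 400, overlap = 40)  # 200 px tiles at 2 um/px
  tiles <- list(list(pixels = matrix(100, 200, 200), col = 0, row = 0),
                list(pixels = matrix(100, 200, 200), col = 1, row = 0))
  out <- stitchLayer(tiles, sp, pixelSize = 2)
  expect_equal(dim(out), c(200L, 380L))
  expect_true(all(abs(out - 100) < 1e-9))

  single <- stitchLayer(tiles[1], sp, pixelSize = 2)
  expect_equal(single[, ], matrix(100, 200, 200), tolerance = 1e-12)

  # a smooth ring spanning the seam stays continuous: the intensity gradient
  # across the seam is no larger than twice the off-seam gradient
  n <- 200
  scene <- matrix(0, n, 2 * n - 20)
  cx <- (ncol(scene) - 1) / 2; cy <- (n - 1) / 2
  xs <- matrix(rep(0:(ncol(scene) - 1), each = n), n)
  ys <- matrix(rep(0:(n - 1), ncol(scene)), n)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  scene <- 500 + 400 * cos(2 * pi * rr / 60)
  tA <- scene[, 1:n]; tB <- scene[, (n - 19):(2 * n - 20)]
  out2 <- stitchLayer(list(list(pixels = tA, col = 0, row = 0),
                           list(pixels = tB, col = 1, row = 0)),
                      sp, pixelSize = 2)
  expect_equal(dim(out2), dim(scene))
  gx <- abs(out2[, -1] - out2[, -ncol(out2)])
  seam <- 181:199  # overlap strip columns
  expect_lt(max(gx[, seam]), 2 * max(gx[, -seam]))
  # and the blended mosaic reproduces the underlying scene
  expect_lt(max(abs(out2 - scene)), 1e-9)

  # missing tile: zero-filled and reported in the coverage mask
  out3 <- stitchLayer(list(list(pixels = tA, col = 0, row = 0),
                           list(pixels = tB, col = 2, row = 0)),
                      sp, pixelSize = 2)
  cov <- attr(out3, "coverage")
  expect_true(any(!cov))
  expect_true(all(out3[!cov] == 0))
})
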