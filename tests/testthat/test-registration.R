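px <- 0.32

test_that("transform algebra: identity, inverse and composition", {
  t <- SimilarityTransform2D(dx = 1.1, dy = -0.4, rotation = 0.3,
                             scale = 1.004)
  ti <- invertTransform(t)
  comp <- composeTransforms(ti, t)
  expect_true(isIdentityTransform(comp, tol = 1e-12))
  expect_true(isIdentityTransform(SimilarityTransform2D()))
  expect_error(SimilarityTransform2D(scale = 0), "scale")
})

test_that("applyTransform bypasses interpolation at identity and matches the
           exact index permutation for a 90-degree rotation", {
  withr::with_seed(8, {
    img <- matrix(runif(65 * 65), 65, 65)
    out <- applyTransform(img, SimilarityTransform2D(), px)
    expect_identical(out[, ], img)

    rot <- applyTransform(img, SimilarityTransform2D(rotation = 90), px)
    # oracle: out[i, j] = in[2c - j, i] (0-based, exact for odd sides)
    n <- 65; ctr <- (n - 1) / 2
    oracle <- matrix(0, n, n)
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      src_r <- 2 * ctr - j; src_c <- i
      if (src_r >= 0 && src_r < n)
        oracle[i + 1, j + 1] <- img[src_r + 1, src_c + 1]
    }
    expect_equal(rot[, ], oracle, tolerance = 1e-9)
  })
})

test_that("warp round trip and composition stay within interpolation error", {
  withr::with_seed(9, {
    img <- makeRingTarget(sizePx = 128, pixelSize = px)
    t <- SimilarityTransform2D(dx = 2.3 * px, dy = -1.2 * px,
                               rotation = 0.6, scale = 1.006)
    fwd <- applyTransform(img, t, px)
    back <- applyTransform(fwd, invertTransform(t), px)
    interior <- 11:118
    mad <- mean(abs(back[interior, interior] - img[interior, interior]))
    expect_lt(mad, 0.01 * diff(range(img)))

    t1 <- SimilarityTransform2D(dx = 1.5 * px, dy = 0.7 * px,
                                rotation = 0.4, scale = 1.003)
    t2 <- SimilarityTransform2D(dx = -0.8 * px, dy = 0.5 * px,
                                rotation = -0.2, scale = 0.998)
    two <- applyTransform(applyTransform(img, t1, px), t2, px)
    one <- applyTransform(img, composeTransforms(t2, t1), px)
    expect_lt(mean(abs(two[interior, interior] - one[interior, interior])),
              0.01 * diff(range(img)))
  })
})

test_that("estimateTransform recovers a known similarity warp to sub-pixel
           precision and maximizes the correlation objective", {
  ring <- makeRingTarget(sizePx = 192, pixelSize = px)
  inj <- SimilarityTransform2D(dx = 3.2 * px, dy = -1.5 * px,
                               rotation = 0.10, scale = 1.001)
  moving <- applyTransform(ring, inj, px)
  res <- estimateTransform(ring, moving, pixelSize = px, details = TRUE)
  est <- res$transform
  truth <- invertTransform(inj)
  expect_lt(abs(est@dx - truth@dx) / px, 0.1)
  expect_lt(abs(est@dy - truth@dy) / px, 0.1)
  expect_lt(abs(est@rotation - truth@rotation), 0.05)
  expect_lt(abs(est@scale - truth@scale), 5e-4)
  expect_gt(est@correlation, 0.99)
  # refined optimum dominates every coarse-grid candidate
  expect_gte(est@correlation, max(res$grid$ncc, na.rm = TRUE) - 1e-12)

  expect_error(estimateTransform(ring, matrix(5, 192, 192), pixelSize = px),
               class = "wvtRegistrationError")
  # moving = fixed: identity within numerical tolerance, correlation ~ 1
  same <- estimateTransform(ring, ring, pixelSize = px)
  expect_lt(abs(same@dx) / px, 0.05)
  expect_lt(abs(same@dy) / px, 0.05)
  expect_lt(abs(same@rotation), 0.02)
  expect_lt(abs(same@scale - 1), 2e-4)
  expect_gt(same@correlation, 0.999)
})

test_that("estimate-then-apply leaves sub-pixel residuals across random
           transforms in the recovery envelope", {
  ring <- makeRingTarget(sizePx = 192, pixelSize = px)
  withr::with_seed(21, {
    for (s in 1:5) {
      inj <- SimilarityTransform2D(dx = runif(1, -8, 8) * px,
                                   dy = runif(1, -8, 8) * px,
                                   rotation = runif(1, -1, 1),
                                   scale = 1 + runif(1, -0.01, 0.01))
      moving <- applyTransform(ring, inj, px)
      est <- estimateTransform(ring, moving, pixelSize = px)
      corrected <- applyTransform(moving, est, px)
      err <- measureColocationError(ring, corrected, window = 64,
                                    pixelSize = px, borderPx = 28)
      expect_lt(max(err@residuals, na.rm = TRUE), px)
    }
  })
})

test_that("co-location error probes report windowed displacements in
           micrometres", {
  ring <- makeRingTarget(sizePx = 160, pixelSize = px)
  err0 <- measureColocationError(ring, ring, window = 64, pixelSize = px)
  expect_true(all(err0@residuals < 1e-6))

  # integer 2 px shift: residual 0.64 um at every probe
  shifted <- applyTransform(ring, SimilarityTransform2D(dx = 2 * px), px)
  err2 <- measureColocationError(ring, shifted, window = 64, pixelSize = px)
  expect_equal(unname(err2@residuals), rep(2 * px, 5), tolerance = 0.02)

  # a flat window is skipped with a warning
  flat <- ring; flat[1:70, 1:70] <- 0
  flatB <- flat
  expect_warning(
    errF <- measureColocationError(flat, flatB,
                                   probePoints = rbind(corner1 = c(20, 20),
                                                       center = c(80, 80)),
                                   window = 32, pixelSize = px),
    "flat")
  expect_true(is.na(errF@residuals[1]))
  expect_false(is.na(errF@residuals[2]))
})

test_that("transforms serialize to JSON and back losslessly", {
  t <- SimilarityTransform2D(dx = 1.23456, dy = -0.98765, rotation = 0.111,
                             scale = 1.00123, channel = "red",
                             correlation = 0.987)
  f <- withr::local_tempfile(fileext = ".json")
  writeTransform(t, f)
  t2 <- readTransform(f)
  expect_equal(t2@dx, t@dx)
  expect_equal(t2@dy, t@dy)
  expect_equal(t2@rotation, t@rotation)
  expect_equal(t2@scale, t@scale)
  expect_equal(t2@channel, "red")
})
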