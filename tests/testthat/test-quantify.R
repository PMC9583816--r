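test_that("co-location pairing is strict, mutual and one-to-one", {
  g <- SomaSet(rbind(c(0, 0, 0)))
  r <- SomaSet(rbind(c(0.5, 0, 0)), channel = "red")
  expect_equal(nrow(colocPairs(colocate(g, r))), 1L)

  # a pair at exactly the threshold is excluded (strict less-than)
  rEdge <- SomaSet(rbind(c(1.0, 0, 0)), channel = "red")
  expect_equal(nrow(colocPairs(colocate(g, rEdge, threshold = 1.0))), 0L)
  rIn <- SomaSet(rbind(c(1.0 - 1e-9, 0, 0)), channel = "red")
  expect_equal(nrow(colocPairs(colocate(g, rIn, threshold = 1.0))), 1L)

  # mutual nearest neighbour keeps the pairing one-to-one: two greens near
  # one red produce a single pair with the closer green
  g2 <- SomaSet(rbind(c(0, 0, 0), c(0.9, 0, 0)))
  r2 <- SomaSet(rbind(c(0.5, 0, 0)), channel = "red")
  p2 <- colocPairs(colocate(g2, r2))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$green_id, 2L)  # 0.4 um beats 0.5 um
  expect_false(anyDuplicated(p2$green_id) > 0)

  # symmetry: swapping the channels transposes the pair set
  withr::with_seed(33, {
    a <- SomaSet(matrix(runif(3 * 60, 0, 30), 60, 3))
    b <- SomaSet(matrix(runif(3 * 60, 0, 30), 60, 3), channel = "red")
    pab <- colocPairs(colocate(a, b))
    pba <- colocPairs(colocate(b, a))
    expect_equal(pab[order(pab$green_id), c("green_id", "red_id")],
                 stats::setNames(pba[order(pba$red_id),
                                     c("red_id", "green_id")],
                                 c("green_id", "red_id")),
                 ignore_attr = TRUE)
  })
})

test_that("planted pairs among well-separated distractors are recovered
           exactly", {
  withr::with_seed(14, {
    distract <- placeSeparatedPoints(300, 0, 400, minSep = 5)
    gIdx <- seq_len(150); rIdx <- 151:300
    green <- distract[gIdx, ]
    red <- distract[rIdx, ]
    # 40 true pairs at distance < 0.8 um
    u <- matrix(rnorm(40 * 3), 40, 3); u <- u / sqrt(rowSums(u^2))
    truePos <- placeSeparatedPoints(40, 500, 900, minSep = 5)
    green <- rbind(green, truePos)
    red <- rbind(red, truePos + u * runif(40, 0.05, 0.79))
    pairs <- colocate(SomaSet(green), SomaSet(red, channel = "red"))
    p <- colocPairs(pairs)
    expect_equal(nrow(p), 40L)
    expect_setequal(p$green_id, 151:190)
    expect_true(all(p$distance < 0.8))
  })
})

test_that("region counting assigns by containing voxel and rolls up the
           hierarchy consistently", {
  atlas <- tinyAtlas(nv = 30, vox = 10)  # 300 um cube, bands of 100 um in x
  # all somas inside one sub-region
  s1 <- SomaSet(matrix(rep(c(50, 50, 50), 10), 10, 3, byrow = TRUE))
  r1 <- countByRegion(s1, atlas, "subregion")
  t1 <- regionTable(r1)
  expect_equal(t1$proportion_pct[t1$region_id == 11], 100)
  expect_equal(sum(t1$count), 10)

  # planted 60/30/10 across the three parent bands
  withr::with_seed(4, {
    mk <- function(n, xlo, xhi) cbind(runif(n, xlo, xhi), runif(n, 5, 295),
                                      runif(n, 5, 295))
    somas <- SomaSet(rbind(mk(60, 5, 95), mk(30, 105, 195), mk(10, 205, 295)))
    rep <- countByRegion(somas, atlas, "region")
    tab <- regionTable(rep)
    expect_equal(tab$proportion_pct, c(60, 30, 10))
    # hierarchy consistency: each region equals the sum of its sub-regions
    sub <- regionTable(countByRegion(somas, atlas, "subregion"))
    for (p in 1:3)
      expect_equal(sum(sub$proportion_pct[sub$region_id %/% 10 == p]),
                   tab$proportion_pct[tab$region_id == p])
  })

  # boundary convention: x = 100 lies in voxel 11, i.e. band 2
  sEdge <- SomaSet(rbind(c(100, 50, 50)))
  tEdge <- regionTable(countByRegion(sEdge, atlas, "region"))
  expect_equal(tEdge$count[tEdge$region_id == 2], 1L)

  # out-of-atlas soma lands in the flagged unassigned bin
  sOut <- SomaSet(rbind(c(50, 50, 50), c(1000, 50, 50)))
  expect_warning(rOut <- countByRegion(sOut, atlas, "region"), "unassigned")
  tOut <- regionTable(rOut)
  expect_equal(tOut$count[tOut$region_id == 0], 1L)
  expect_equal(sum(tOut$proportion_pct), 100)
  expect_true("unassigned-somas" %in% rOut@flags)
})

test_that("cross-brain aggregation computes mean and s.e.m. with missing
           regions treated as zero", {
  atlas <- tinyAtlas()
  mkRep <- function(xs) countByRegion(SomaSet(cbind(xs, 50, 50)), atlas,
                                      "region")
  # four identical brains: zero s.e.m.
  reps <- replicate(4, mkRep(c(50, 50, 150, 250)), simplify = FALSE)
  agg <- aggregateBrains(reps)
  expect_equal(agg@nBrains, 4L)
  expect_true(all(regionTable(agg)$sem_pct == 0))

  # hand-computed s.e.m.: proportions 10, 12, 8, 10 -> mean 10, sem 0.816
  mk1 <- function(p) {
    n1 <- p; n3 <- 100 - p
    mkRep(c(rep(50, n1), rep(250, n3)))
  }
  agg2 <- aggregateBrains(lapply(c(10, 12, 8, 10), mk1))
  t2 <- regionTable(agg2)
  expect_equal(t2$mean_pct[t2$region_id == 1], 10)
  expect_equal(t2$sem_pct[t2$region_id == 1], sd(c(10, 12, 8, 10)) / 2,
               tolerance = 1e-12)
  expect_equal(round(t2$sem_pct[t2$region_id == 1], 3), 0.816)

  # a region absent from one brain counts as 0% there
  aggM <- aggregateBrains(list(mkRep(c(50, 150)), mkRep(c(50, 50))))
  tM <- regionTable(aggM)
  expect_equal(tM$mean_pct[tM$region_id == 2], mean(c(50, 0)))

  # single brain: s.e.m. zero and flagged
  agg1 <- aggregateBrains(list(mkRep(50)))
  expect_true("n=1-sem-zero" %in% agg1@flags)
  expect_error(aggregateBrains(list(mkRep(50),
                                    countByRegion(SomaSet(cbind(50, 50, 50)),
                                                  atlas, "subregion"))),
               class = "wvtInputError")
})

test_that("co-location proportions are percentages of each channel", {
  withr::with_seed(10, {
    g <- SomaSet(matrix(runif(3000, 0, 500), 1000, 3))
    r <- SomaSet(matrix(runif(2700, 600, 1100), 900, 3), channel = "red")
    r@coords[1, ] <- g@coords[1, ] + c(0.2, 0, 0)
    r@coords[2, ] <- g@coords[2, ] + c(0, 0.3, 0)
    pairs <- colocate(g, r)
    expect_equal(nrow(colocPairs(pairs)), 2L)
    pr <- colocProportions(pairs, g, r)
    expect_equal(unname(pr["pct_of_green"]), 0.2)
    expect_equal(unname(pr["pct_of_red"]), 100 * 2 / 900)
  })
  e <- SomaSet(matrix(numeric(0), 0, 3))
  g1 <- SomaSet(rbind(c(0, 0, 0)))
  p0 <- colocate(g1, SomaSet(rbind(c(50, 0, 0)), channel = "red"))
  expect_equal(unname(colocProportions(p0, g1, SomaSet(rbind(c(50, 0, 0)),
                                                       channel = "red"))),
               c(0, 0))
  expect_warning(prE <- colocProportions(p0, e, g1), "empty")
  expect_true(is.nan(prE[["pct_of_green"]]))
})

test_that("block-wise soma detection finds planted somas and deduplicates
           across block halos", {
  withr::with_seed(19, {
    pts <- placeSeparatedPoints(60, 15, 110, minSep = 12)
    pts[, 3] <- pts[, 3] * 0.8 + 10  # keep z inside 96 um
    v <- renderSomaVolume(pts, dims = c(128, 128, 48), voxelSize = c(1, 1, 2),
                          sigmaUm = 3, amplitude = 1000, noiseSd = 100)
    det <- detectSomas(v, voxelSize = c(1, 1, 2),
                       blockShape = c(64, 64, 24), haloVox = 8)
    hits <- wvtomo:::.crossPairsWithin(somaCoords(det), pts, 4)
    recall <- length(unique(hits$ri)) / nrow(pts)
    precision <- length(unique(hits$gi)) / nSomas(det)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  })

  # one soma exactly on a block boundary: a single deduplicated detection
  v1 <- renderSomaVolume(rbind(c(32, 20, 24)), dims = c(48, 64, 24),
                         voxelSize = c(1, 1, 2), sigmaUm = 3,
                         amplitude = 1000, noiseSd = 0)
  det1 <- detectSomas(v1, voxelSize = c(1, 1, 2),
                      blockShape = c(32, 48, 24), haloVox = 8)
  expect_equal(nSomas(det1), 1L)
  expect_lt(sqrt(sum((somaCoords(det1) - c(32, 20, 24))^2)), 3)

  expect_equal(nSomas(detectSomas(array(0, dim = c(32, 32, 8)))), 0L)
})
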