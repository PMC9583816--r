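# Synthetic phantom brains, structured-illumination raw frames, chromatic
# misalignments, bead fields and ring targets, all with serialized ground
# truth. Everything is deterministic under the spec's seed.

#' Specify a synthetic phantom brain
#'
#' Defaults describe the standing study conditions of the generator: five
#' coronal layers of 1536 px at 1.68 um/px (recognition resolution) whose
#' superellipse outline grows then shrinks along the anterior-posterior axis
#' (maximum semi-axes 420 x 300 um), a ventricle-like hole, three peripheral
#' sectioning fragments per layer, ~2000 nuclei/mm2 of DAPI-like speckle,
#' 10000 green and 9000 red somas with a planted co-location fraction of
#' 0.22\%, and Gaussian read noise of 50 counts.
#'
#' @param nLayers,imageSizePx,pixelSize,exponent outline geometry.
#' @param semiAxes optional nLayers x 2 matrix of per-layer semi-axes (um);
#'   default tapered profile.
#' @param ventricleFrac,nucleiDensityMm2,nGreen,nRed,colocFraction,nFragments
#'   content parameters (see \linkS4class{PhantomSpec}).
#' @param fragmentSizeRange,noiseSd,poisson,zExtentUm,regionWeights,seed idem.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(nLayers = 5L, imageSizePx = 1536L, pixelSize = 1.68,
                        exponent = 2.5, semiAxes = NULL,
                        ventricleFrac = 0.18, nucleiDensityMm2 = 2000,
                        nGreen = 10000L, nRed = 9000L,
                        colocFraction = 0.0022, nFragments = 3L,
                        fragmentSizeRange = c(30, 80), noiseSd = 50,
                        poisson = FALSE, zExtentUm = 200,
                        regionWeights = c(0.6, 0.3, 0.1), seed = 1L) {
  if (is.null(semiAxes)) {
    # taper strong enough that planned extents cross mosaic-stride boundaries
    f <- pmax(0.15, -0.1 + 1.1 * sin(pi * (seq_len(nLayers) - 0.5) / nLayers))
    semiAxes <- cbind(420 * f, 300 * f)
  }
  new("PhantomSpec", nLayers = as.integer(nLayers),
      imageSizePx = as.integer(imageSizePx), pixelSize = pixelSize,
      exponent = exponent, semiAxes = semiAxes,
      ventricleFrac = ventricleFrac, nucleiDensityMm2 = nucleiDensityMm2,
      nGreen = as.integer(nGreen), nRed = as.integer(nRed),
      colocFraction = colocFraction, nFragments = as.integer(nFragments),
      fragmentSizeRange = fragmentSizeRange, noiseSd = noiseSd,
      poisson = poisson, zExtentUm = zExtentUm,
      regionWeights = regionWeights / sum(regionWeights),
      seed = as.integer(seed))
}

# Superellipse tissue mask with a low-order angular wobble (irregular coronal
# outline). Returns a 0/1 matrix. The wobble harmonics are evaluated from
# cos/sin via Chebyshev identities to avoid per-pixel atan2.
.tissueMask <- function(sizePx, pixelSize, semiA, semiB, exponent,
                        wobblePhase = c(0, 0), wobbleAmp = c(0.05, 0.03)) {
  n <- sizePx
  ctr <- (n - 1) / 2
  # evaluate only inside the outline's bounding window (wobble-inflated)
  halfW <- min(ctr, ceiling(1.15 * semiA / pixelSize) + 2)
  halfH <- min(ctr, ceiling(1.15 * semiB / pixelSize) + 2)
  cols <- (floor(ctr) - halfW):(ceiling(ctr) + halfW)
  rows <- (floor(ctr) - halfH):(ceiling(ctr) + halfH)
  nw <- length(cols); nh <- length(rows)
  x <- (rep(cols, each = nh) - ctr) * pixelSize
  y <- (rep(rows, times = nw) - ctr) * pixelSize
  r <- sqrt(x^2 + y^2)
  r[r == 0] <- 1
  cth <- x / r; sth <- y / r
  s3 <- 3 * sth - 4 * sth^3
  c3 <- 4 * cth^3 - 3 * cth
  c5 <- 16 * cth^5 - 20 * cth^3 + 5 * cth
  s5 <- 16 * sth^5 - 20 * sth^3 + 5 * sth
  wob <- 1 +
    wobbleAmp[1] * (s3 * cos(wobblePhase[1]) + c3 * sin(wobblePhase[1])) +
    wobbleAmp[2] * (c5 * cos(wobblePhase[2]) - s5 * sin(wobblePhase[2]))
  v <- (abs(x) / (semiA * wob))^exponent + (abs(y) / (semiB * wob))^exponent
  out <- matrix(0, n, n)
  out[rows + 1, cols + 1] <- matrix(as.numeric(v <= 1), nh, nw)
  out
}

.ellipseMask <- function(sizePx, pixelSize, cxUm, cyUm, a, b) {
  n <- sizePx
  ctr <- (n - 1) / 2
  x <- (rep(0:(n - 1), each = n) - ctr) * pixelSize - cxUm
  y <- (rep(0:(n - 1), times = n) - ctr) * pixelSize - cyUm
  matrix(as.numeric((x / a)^2 + (y / b)^2 <= 1), n, n)
}

# Stamp isotropic Gaussian spots (positions in 0-based px) onto img.
.stampSpots <- function(img, xs, ys, amps, sigmaPx) {
  r <- ceiling(3 * sigmaPx)
  off <- -r:r
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(xs)) {
    c0 <- round(xs[i]); r0 <- round(ys[i])
    cs <- c0 + off; rs <- r0 + off
    ok_c <- cs >= 0 & cs <= nc - 1; ok_r <- rs >= 0 & rs <= nr - 1
    if (!any(ok_c) || !any(ok_r)) next
    gx <- exp(-((cs[ok_c] - xs[i])^2) / (2 * sigmaPx^2))
    gy <- exp(-((rs[ok_r] - ys[i])^2) / (2 * sigmaPx^2))
    patch <- amps[i] * outer(gy, gx)
    img[rs[ok_r] + 1, cs[ok_c] + 1] <- img[rs[ok_r] + 1, cs[ok_c] + 1] + patch
  }
  img
}

# Uniform sample of k points inside a 0/1 mask (0-based px coords + jitter).
# `on` may carry precomputed which(mask > 0) to avoid rescanning the mask.
.samplePointsInMask <- function(mask, k, on = NULL) {
  if (is.null(on)) on <- which(mask > 0)
  if (length(on) == 0 || k <= 0)
    return(cbind(x = numeric(0), y = numeric(0)))
  pick <- on[sample.int(length(on), k, replace = TRUE)]
  nr <- nrow(mask)
  rr <- (pick - 1) %% nr
  cc <- (pick - 1) %/% nr
  cbind(x = cc + stats::runif(k, -0.5, 0.5),
        y = rr + stats::runif(k, -0.5, 0.5))
}

#' Depth weight of the surface-confined nuclear counterstain
#'
#' Real-time counterstaining only penetrates the freshly cut block face;
#' the crosstalk it generates in the green channel decays with imaging depth
#' and reaches the noise floor at \code{stainingDepthUm} (4 um). Modelled as
#' a linear ramp from 1 at the surface to 0 at the staining depth.
#'
#' @param depthUm detection-plane depth below the block face, micrometres.
#' @param stainingDepthUm staining penetration depth (4).
#' @return Weight in [0, 1].
#' @export
stainingWeight <- function(depthUm, stainingDepthUm = 4) {
  pmax(0, 1 - depthUm / stainingDepthUm)
}

#' Generate a phantom brain with full ground truth
#'
#' Produces per-layer coronal images at recognition resolution and the soma /
#' atlas content used by the quantification modules. The blue (DAPI) image of
#' each layer holds nuclear speckle and diffuse tissue signal inside the
#' tissue outline (ventricle dark), plus peripheral sectioning fragments and
#' read noise; the green image holds rendered soma spots plus the nuclear
#' crosstalk attenuated by \code{\link{stainingWeight}} at the green detection
#' depth. Somas are placed inside an eroded reference tissue mask with parent
#' regions drawn from \code{regionWeights}; a binomially drawn fraction of
#' green somas is duplicated in red within 0.8 um (the planted co-located
#' neurons), and all other red somas keep at least 2 um clearance from any
#' green soma.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param renderChannels also render green-channel images (slower).
#' @param gdpDepthUm green detection-plane depth used for the crosstalk
#'   weight (4 um, the optimized scheme).
#' @return List with \code{layers} (per layer: \code{dapi}, optional
#'   \code{green}, \code{truthMask}) and \code{truth} (soma sets, planted
#'   pair table, atlas, per-region planted counts, fragment centres, layer
#'   bounding boxes in um).
#' @export
generatePhantom <- function(spec, renderChannels = FALSE, gdpDepthUm = 4) {
  withSeed(spec@seed, {
    n <- spec@imageSizePx
    px <- spec@pixelSize
    ctr <- (n - 1) / 2
    layers <- vector("list", spec@nLayers)
    bboxes <- matrix(NA_real_, spec@nLayers, 4)
    fragCenters <- list()
    wobPhase <- stats::runif(2, 0, 2 * pi)
    refMask <- NULL
    for (k in seq_len(spec@nLayers)) {
      a <- spec@semiAxes[k, 1]; b <- spec@semiAxes[k, 2]
      mask <- .tissueMask(n, px, a, b, spec@exponent, wobPhase)
      vent <- if (spec@ventricleFrac > 0)
        .ellipseMask(n, px, 0, -0.2 * b, spec@ventricleFrac * a,
                     spec@ventricleFrac * b) * mask
      else matrix(0, n, n)
      stained <- mask * (1 - vent)
      img <- matrix(100, n, n)           # offset/background counts
      img <- img + 1500 * stained        # diffuse tissue signal
      areaMm2 <- sum(stained) * px^2 * 1e-6
      nNuc <- stats::rpois(1, spec@nucleiDensityMm2 * areaMm2)
      nucXY <- .samplePointsInMask(stained, nNuc)
      amps <- pmax(stats::rnorm(nNuc, 6000, 1000), 2000)
      img <- .stampSpots(img, nucXY[, 1], nucXY[, 2], amps, sigmaPx = 1.5)
      nuclearOnly <- img - 100  # tissue + nuclei, no fragments/noise
      # peripheral sectioning fragments, beyond the fragment-distance limit
      boundRadius <- sqrt(a^2 + b^2) * 1.1  # wobble-inflated bound, um
      maxR <- (ctr - 30) * px
      fr <- matrix(NA_real_, 0, 2)
      if (spec@nFragments > 0 && boundRadius + 600 < maxR) {
        rad <- stats::runif(spec@nFragments, boundRadius + 600, maxR)
        ang <- stats::runif(spec@nFragments, 0, 2 * pi)
        fx <- ctr + rad * cos(ang) / px
        fy <- ctr + rad * sin(ang) / px
        fd <- stats::runif(spec@nFragments, spec@fragmentSizeRange[1],
                           spec@fragmentSizeRange[2])
        for (j in seq_len(spec@nFragments)) {
          fm <- .ellipseMask(n, px, (fx[j] - ctr) * px, (fy[j] - ctr) * px,
                             fd[j] / 2, fd[j] / 2 * stats::runif(1, 0.6, 1))
          img <- img + 1500 * fm
        }
        fr <- cbind(fx, fy)
      }
      fragCenters[[k]] <- fr
      if (spec@poisson)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), n, n)
      img <- img + matrix(stats::rnorm(n * n, 0, spec@noiseSd), n, n)
      on <- which(mask > 0, arr.ind = TRUE)
      bboxes[k, ] <- c((min(on[, 2]) - 1) * px, (max(on[, 2]) - 1) * px,
                       (min(on[, 1]) - 1) * px, (max(on[, 1]) - 1) * px)
      layers[[k]] <- list(dapi = img, truthMask = mask,
                          nuclearSignal = nuclearOnly)
      if (k == ceiling(spec@nLayers / 2)) refMask <- mask
    }
    # ---- somas and atlas in the volume [0, W] x [0, W] x [0, zExtent] um
    er <- EBImage::erode(refMask, EBImage::makeBrush(21, "disc"))
    bb <- range(which(er > 0, arr.ind = TRUE)[, 2])
    xminUm <- (bb[1] - 1) * px; xmaxUm <- (bb[2] - 1) * px
    avox <- 8  # um, isotropic atlas voxel
    # region cuts snap to atlas-voxel boundaries so that a soma's parent
    # region (by exact x) always matches its containing voxel's label
    cuts <- round((xminUm + (xmaxUm - xminUm) * c(1, 2) / 3) / avox) * avox
    parentOf <- function(xUm) 1L + (xUm >= cuts[1]) + (xUm >= cuts[2])
    nParents <- length(spec@regionWeights)
    stopifnot(nParents == 3)  # synthetic atlas partitions into 3 regions
    # green somas: parent region drawn per soma from regionWeights, position
    # uniform over the region's pixels of the eroded reference mask
    onEr <- which(er > 0)
    erN <- nrow(er)
    onX <- ((onEr - 1) %/% erN) * px
    onReg <- 1L + (onX >= cuts[1]) + (onX >= cuts[2])
    onByReg <- split(onEr, onReg)
    regG <- sample.int(nParents, spec@nGreen, replace = TRUE,
                       prob = spec@regionWeights)
    gxy <- matrix(NA_real_, spec@nGreen, 2)
    for (r in seq_len(nParents)) {
      kk <- which(regG == r)
      if (length(kk))
        gxy[kk, ] <- .samplePointsInMask(er, length(kk),
                                         on = onByReg[[as.character(r)]])
    }
    gz <- stats::runif(spec@nGreen, 0.05, 0.95) * spec@zExtentUm
    gCoords <- cbind(gxy[, 1] * px, gxy[, 2] * px, gz)
    # planted co-located somas: binomial draw of green somas duplicated in red
    nPairs <- min(stats::rbinom(1, spec@nGreen, spec@colocFraction),
                  spec@nRed)
    pairIdx <- if (nPairs > 0) sample.int(spec@nGreen, nPairs) else integer(0)
    dupOff <- function(k) {
      u <- matrix(stats::rnorm(3 * k), k, 3)
      u <- u / sqrt(rowSums(u^2))
      u * stats::runif(k, 0.1, 0.75)
    }
    redDup <- if (nPairs > 0) gCoords[pairIdx, , drop = FALSE] + dupOff(nPairs)
      else matrix(numeric(0), 0, 3)
    # distractor reds keep >= 2 um from every green soma
    nDist <- spec@nRed - nPairs
    rxy <- .samplePointsInMask(er, nDist, on = onEr)
    rz <- stats::runif(nDist, 0.05, 0.95) * spec@zExtentUm
    rCoords <- cbind(rxy[, 1] * px, rxy[, 2] * px, rz)
    bad <- unique(.crossPairsWithin(rCoords, gCoords, 2.0)$gi)
    tries <- 0
    while (length(bad) && tries < 50) {
      nb <- length(bad)
      nxy <- .samplePointsInMask(er, nb, on = onEr)
      rCoords[bad, ] <- cbind(nxy[, 1] * px, nxy[, 2] * px,
                              stats::runif(nb, 0.05, 0.95) * spec@zExtentUm)
      bad <- unique(.crossPairsWithin(rCoords, gCoords, 2.0)$gi)
      tries <- tries + 1
    }
    redCoords <- rbind(redDup, rCoords)
    redIds <- seq_len(nrow(redCoords))
    green <- SomaSet(gCoords, channel = "green", brainId = "phantom")
    red <- SomaSet(redCoords, ids = redIds, channel = "red",
                   brainId = "phantom")
    # red duplicate i (rows of redDup) carries red id i and green id pairIdx[i]
    pairTable <- if (nPairs > 0) {
      ord <- order(pairIdx)
      data.frame(green_id = pairIdx[ord], red_id = ord)
    } else data.frame(green_id = integer(), red_id = integer())
    # ---- synthetic atlas: 3 parent regions x 2 sub-regions (y split)
    av <- avox
    nax <- ceiling(n * px / av); naz <- ceiling(spec@zExtentUm / av)
    yCut <- (stats::median(((onEr - 1) %% erN)) ) * px
    axc <- (seq_len(nax) - 0.5) * av
    # atlas footprint from the full reference mask so that every soma placed
    # in the eroded mask falls in a labelled voxel
    maskAt <- function(xu, yu) {
      cc <- pmin(pmax(round(xu / px) + 1, 1), n)
      rr <- pmin(pmax(round(yu / px) + 1, 1), n)
      refMask[cbind(rr, cc)] > 0
    }
    gridXY <- expand.grid(x = axc, y = axc)
    inside <- maskAt(gridXY$x, gridXY$y)
    par2d <- ifelse(inside, 1L + (gridXY$x >= cuts[1]) +
                      (gridXY$x >= cuts[2]), 0L)
    sub2d <- ifelse(inside, par2d * 10L + ifelse(gridXY$y < yCut, 1L, 2L), 0L)
    slice <- matrix(sub2d, nax, nax, byrow = TRUE)  # [row=y, col=x]
    labels <- array(rep(slice, naz), dim = c(nax, nax, naz))
    hier <- do.call(rbind, lapply(1:3, function(p)
      data.frame(id = p * 10L + 1:2,
                 name = paste0("R", p, c("a", "b")),
                 parent_id = p, parent_name = paste0("R", p))))
    atlas <- AtlasVolume(labels, voxelSize = c(av, av, av), hierarchy = hier)
    # ground-truth region of each soma from its realized coordinate (jitter
    # can move a borderline soma across a cut relative to its drawn region)
    regionCounts <- tabulate(parentOf(gCoords[, 1]), nbins = nParents)
    list(
      layers = if (renderChannels) lapply(seq_along(layers), function(k) {
        L <- layers[[k]]
        somaImg <- matrix(0, n, n)
        zlo <- (k - 1) / spec@nLayers * spec@zExtentUm
        zhi <- k / spec@nLayers * spec@zExtentUm
        inL <- green@coords[, 3] >= zlo & green@coords[, 3] < zhi
        somaImg <- .stampSpots(somaImg, green@coords[inL, 1] / px,
                               green@coords[inL, 2] / px,
                               rep(4000, sum(inL)), sigmaPx = 2.5)
        L$green <- somaImg +
          stainingWeight(gdpDepthUm) * L$nuclearSignal +
          matrix(stats::rnorm(n * n, 0, spec@noiseSd), n, n)
        L
      }) else layers,
      truth = list(green = green, red = red, pairs = pairTable,
                   nPairs = nPairs, atlas = atlas,
                   regionCounts = regionCounts, regionWeights =
                     spec@regionWeights, bboxes = bboxes,
                   fragments = fragCenters, referenceMask = refMask,
                   pixelSize = px)
    )
  })
}

#' Structured-illumination modulation of a 2D scene
#'
#' Produces one raw frame: the in-focus scene is modulated by a sinusoidal
#' fringe (the DMD's binary fringes reach the sample as sinusoids because the
#' objective passes only the fundamental), and an optional unmodulated
#' out-of-focus term is added. With \code{curvature > 0} the out-of-focus
#' term acquires a residual modulation growing quadratically towards the
#' field edge, emulating the field curvature of the illumination plane (the
#' crosstalk is strongest near the FOV edge).
#'
#' @param scene numeric matrix, in-focus intensity.
#' @param periodUm fringe period at the sample, micrometres (> 2 pixels).
#' @param phase fringe phase, radians.
#' @param modulationDepth m in [0, 1].
#' @param pixelSize micrometres per pixel.
#' @param outOfFocus unmodulated background (matrix or scalar).
#' @param curvature edge modulation depth of the out-of-focus term (0 = flat
#'   illumination plane).
#' @return Raw frame \code{scene (1 + m cos(2 pi x / period + phase)) / 2 +
#'   oof (1 + m_oof(r) cos(.)) / 2}.
#' @export
modulateSim <- function(scene, periodUm, phase, modulationDepth = 1,
                        pixelSize = 0.32, outOfFocus = 0, curvature = 0) {
  if (periodUm <= 2 * pixelSize)
    wvtStop("fringe period at or below Nyquist: aliasing", "wvtInputError")
  nr <- nrow(scene); nc <- ncol(scene)
  xUm <- matrix(rep((0:(nc - 1)) * pixelSize, each = nr), nr, nc)
  th <- 2 * pi * xUm / periodUm + phase
  raw <- scene * (1 + modulationDepth * cos(th)) / 2
  if (is.matrix(outOfFocus) || any(outOfFocus != 0)) {
    ctrX <- (nc - 1) / 2; ctrY <- (nr - 1) / 2
    r2 <- (matrix(rep(0:(nc - 1), each = nr), nr, nc) - ctrX)^2 +
      (matrix(rep(0:(nr - 1), times = nc), nr, nc) - ctrY)^2
    mo <- pmin(curvature * r2 / max(r2), 1)
    raw <- raw + outOfFocus * (1 + mo * cos(th)) / 2
  }
  raw
}

#' Three-phase triplet of a modulated scene
#'
#' Convenience wrapper generating the raws at phases \code{phase0},
#' \code{phase0 + pi/2}, \code{phase0 + pi} (the instrument's phase step).
#'
#' @inheritParams modulateSim
#' @param phase0 base fringe phase.
#' @param channel channel label of the triplet.
#' @return A \linkS4class{PhaseTriplet}.
#' @export
modulateTriplet <- function(scene, periodUm, phase0 = 0, modulationDepth = 1,
                            pixelSize = 0.32, outOfFocus = 0, curvature = 0,
                            channel = "green") {
  raws <- lapply(phase0 + c(0, pi / 2, pi), function(p)
    modulateSim(scene, periodUm, p, modulationDepth, pixelSize, outOfFocus,
                curvature))
  PhaseTriplet(raws[[1]], raws[[2]], raws[[3]], channel = channel)
}

#' Warp per-channel tiles by known similarity transforms
#'
#' Inverse problem for the registration module: the blue/red tiles are warped
#' by the given transforms and the exact parameters are recorded as ground
#' truth. Transforms outside the registration module's stated recovery
#' envelope (|shift| <= 10 px, |rot| <= 1 deg, |scale-1| <= 0.01) are applied
#' anyway but flagged in the returned \code{"warnings"} attribute.
#'
#' @param tiles named list of matrices (channel -> tile).
#' @param transforms named list of \linkS4class{SimilarityTransform2D}.
#' @param pixelSize micrometres per pixel.
#' @return Named list of warped tiles with attribute \code{"truth"} (the
#'   transforms) and \code{"warnings"}.
#' @export
injectMisalignment <- function(tiles, transforms, pixelSize = 0.32) {
  warns <- character()
  out <- lapply(names(tiles), function(ch) {
    t <- transforms[[ch]]
    if (is.null(t)) return(tiles[[ch]])
    if (max(abs(c(t@dx, t@dy))) / pixelSize > 10 + 1e-9 ||
        abs(t@rotation) > 1 + 1e-9 || abs(t@scale - 1) > 0.01 + 1e-9)
      warns <<- c(warns, sprintf(
        "transform for channel %s outside recovery envelope", ch))
    applyTransform(tiles[[ch]], t, pixelSize)
  })
  names(out) <- names(tiles)
  attr(out, "truth") <- transforms
  attr(out, "warnings") <- warns
  out
}

#' Synthetic sub-diffraction bead stack
#'
#' Gaussian point emitters on a dark background with optional shot and read
#' noise, placed with a minimum mutual separation so that the bead-isolation
#' rule of \code{\link{measureBeadResolution}} accepts them.
#'
#' @param nBeads number of beads.
#' @param sigmaUm c(lateral, axial) Gaussian sigma in micrometres.
#' @param voxelSize c(x, y, z) micrometres (0.32, 0.32, 0.2: the bead
#'   calibration protocol's 200 nm z step).
#' @param dims stack size (y, x, z) in voxels.
#' @param minSeparationUm minimum 3D distance between beads; default 3x the
#'   larger FWHM.
#' @param amplitude,background,readNoiseSd,shot intensity model (counts).
#' @param jitter place beads at random sub-voxel positions (TRUE) or exactly
#'   on voxel centres (FALSE, giving identical replicates).
#' @return List \code{(stack, truth)} where truth holds the planted positions
#'   (um) and the analytic FWHMs \code{2 sqrt(2 ln 2) sigma}.
#' @export
makeBeadField <- function(nBeads = 10, sigmaUm = c(0.2, 1.0),
                          voxelSize = c(0.32, 0.32, 0.2),
                          dims = c(96, 96, 120), minSeparationUm = NULL,
                          amplitude = 5000, background = 100,
                          readNoiseSd = 10, shot = TRUE, jitter = TRUE) {
  fwhm <- 2 * sqrt(2 * log(2)) * sigmaUm
  if (is.null(minSeparationUm)) minSeparationUm <- 3 * max(fwhm)
  ext <- c(dims[2] * voxelSize[1], dims[1] * voxelSize[2],
           dims[3] * voxelSize[3])
  marg <- c(8 * voxelSize[1] + 4 * sigmaUm[1],
            8 * voxelSize[2] + 4 * sigmaUm[1],
            max(6 * voxelSize[3], 4 * sigmaUm[2]))
  pos <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(pos) < nBeads) {
    if (tries > 20000)
      wvtStop("cannot place beads at the requested separation",
              "wvtPlacementError")
    p <- c(stats::runif(1, marg[1], ext[1] - marg[1]),
           stats::runif(1, marg[2], ext[2] - marg[2]),
           stats::runif(1, marg[3], ext[3] - marg[3]))
    if (!jitter)
      p <- round(p / voxelSize) * voxelSize
    if (nrow(pos)) {
      d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
      if (min(d2) < minSeparationUm^2) { tries <- tries + 1; next }
    }
    pos <- rbind(pos, p)
    tries <- tries + 1
  }
  stack <- array(background, dim = dims)
  if (nBeads > 0) for (i in seq_len(nBeads)) {
    vx <- pos[i, 1] / voxelSize[1]; vy <- pos[i, 2] / voxelSize[2]
    vz <- pos[i, 3] / voxelSize[3]
    sl <- sigmaUm[1] / voxelSize[1]; sza <- sigmaUm[2] / voxelSize[3]
    rx <- ceiling(4 * sl) + 2; rz <- ceiling(4 * sza) + 2
    xs <- max(0, floor(vx) - rx):min(dims[2] - 1, floor(vx) + rx)
    ys <- max(0, floor(vy) - rx):min(dims[1] - 1, floor(vy) + rx)
    zs <- max(0, floor(vz) - rz):min(dims[3] - 1, floor(vz) + rz)
    gx <- exp(-(xs - vx)^2 / (2 * sl^2))
    gy <- exp(-(ys - vy)^2 / (2 * (sigmaUm[1] / voxelSize[2])^2))
    gz <- exp(-(zs - vz)^2 / (2 * sza^2))
    blob <- amplitude * outer(gy, gx) %o% gz
    stack[ys + 1, xs + 1, zs + 1] <- stack[ys + 1, xs + 1, zs + 1] + blob
  }
  if (shot) stack <- array(stats::rpois(length(stack), stack), dim = dims)
  if (readNoiseSd > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0, readNoiseSd),
                           dim = dims)
  list(stack = stack,
       truth = list(positionsUm = pos,
                    lateralFwhm = fwhm[1], axialFwhm = fwhm[2]))
}

#' Synthetic concentric-ring calibration target
#'
#' Deterministic stand-in for the multicolour calibration slide: concentric
#' sinusoidal rings under a smooth envelope, overlaid with a fixed asymmetric
#' spiral of Gaussian spots. The spots break the rotational symmetry of the
#' rings so that the rotation component of a similarity transform is
#' identifiable; pure rings would leave it unconstrained.
#'
#' @param sizePx image side, pixels.
#' @param pixelSize micrometres per pixel (0.32).
#' @param ringPeriodUm radial ring period, micrometres.
#' @param nSpots number of spiral spots.
#' @param spotSigmaPx spot Gaussian sigma, pixels.
#' @return Numeric matrix in roughly [0, 2].
#' @export
makeRingTarget <- function(sizePx = 256, pixelSize = 0.32, ringPeriodUm = 8,
                           nSpots = 30, spotSigmaPx = 2) {
  n <- sizePx
  ctr <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n, n) - ctr
  y <- matrix(rep(0:(n - 1), times = n), n, n) - ctr
  rUm <- sqrt(x^2 + y^2) * pixelSize
  env <- exp(-((sqrt(x^2 + y^2)) / (0.44 * n))^4)
  img <- env * (0.6 + 0.4 * cos(2 * pi * rUm / ringPeriodUm))
  i <- seq_len(nSpots)
  sr <- 0.40 * n * sqrt(i / nSpots)
  sa <- i * 2.399963  # golden angle: no rotational symmetry
  img <- .stampSpots(img, ctr + sr * cos(sa), ctr + sr * sin(sa),
                     rep(0.9, nSpots), spotSigmaPx)
  img
}

#' Render a soma population as a 3D intensity volume
#'
#' @param coords n x 3 matrix of (x, y, z) in micrometres.
#' @param dims volume size (y, x, z) in voxels.
#' @param voxelSize c(x, y, z) micrometres (1, 1, 2).
#' @param sigmaUm Gaussian soma radius scale (3 um).
#' @param amplitude peak soma intensity (counts).
#' @param noiseSd Gaussian noise s.d.; SNR = amplitude / noiseSd.
#' @return Numeric 3D array.
#' @export
renderSomaVolume <- function(coords, dims, voxelSize = c(1, 1, 2),
                             sigmaUm = 3, amplitude = 1000, noiseSd = 100) {
  v <- array(0, dim = dims)
  if (nrow(coords)) for (i in seq_len(nrow(coords))) {
    vx <- coords[i, 1] / voxelSize[1]; vy <- coords[i, 2] / voxelSize[2]
    vz <- coords[i, 3] / voxelSize[3]
    s <- sigmaUm / voxelSize
    r <- ceiling(3.5 * s)
    xs <- max(0, floor(vx) - r[1]):min(dims[2] - 1, floor(vx) + r[1])
    ys <- max(0, floor(vy) - r[2]):min(dims[1] - 1, floor(vy) + r[2])
    zs <- max(0, floor(vz) - r[3]):min(dims[3] - 1, floor(vz) + r[3])
    gx <- exp(-(xs - vx)^2 / (2 * s[1]^2))
    gy <- exp(-(ys - vy)^2 / (2 * s[2]^2))
    gz <- exp(-(zs - vz)^2 / (2 * s[3]^2))
    v[ys + 1, xs + 1, zs + 1] <- v[ys + 1, xs + 1, zs + 1] +
      amplitude * outer(gy, gx) %o% gz
  }
  if (noiseSd > 0)
    v <- v + array(stats::rnorm(length(v), 0, noiseSd), dim = dims)
  v
}
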