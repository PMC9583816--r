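#' Construct contour-recognition parameters
#'
#' Defaults reflect the recognition conditions: the coronal DAPI preview is
#' downsampled to 1.68 um/px, median-filtered, thresholded by Otsu's method
#' (the uniform real-time counterstain makes per-layer Otsu stable; a fixed
#' threshold is available as fallback), opened with a 3 px disc (removes
#' sectioning debris smaller than ~10 um while preserving the cortex
#' boundary), cleaned of far-off fragments, and hole-filled (ventricles of any
#' size).
#'
#' @param medianKernel odd full width of the median filter, pixels.
#' @param thresholdMethod "otsu" or "fixed".
#' @param fixedValue fixed threshold on the raw intensity scale.
#' @param openingRadius structuring-element radius, pixels.
#' @param openingShape "disc" or "box".
#' @param fragmentDistanceLimit micrometres from the image centre beyond which
#'   non-largest components are dropped; NA derives it per image as the
#'   largest component's bounding radius + 500 um.
#' @param minFragmentArea minimum surviving component area, squared pixels.
#' @param recognitionPixelSize micrometres per pixel (1.68).
#' @return A \linkS4class{ContourParams}.
#' @export
ContourParams <- function(medianKernel = 5L, thresholdMethod = "otsu",
                          fixedValue = NA_real_, openingRadius = 3L,
                          openingShape = "disc",
                          fragmentDistanceLimit = NA_real_,
                          minFragmentArea = 500,
                          recognitionPixelSize = 1.68) {
  new("ContourParams", medianKernel = as.integer(medianKernel),
      thresholdMethod = thresholdMethod, fixedValue = fixedValue,
      openingRadius = as.integer(openingRadius), openingShape = openingShape,
      fragmentDistanceLimit = fragmentDistanceLimit,
      minFragmentArea = minFragmentArea,
      recognitionPixelSize = recognitionPixelSize)
}

#' Construct the fixed mosaic lattice
#'
#' @param fovSide field-of-view side, micrometres (576 = 1800 px x 0.32 um).
#' @param overlap overlap between adjacent FOVs, micrometres (5).
#' @param originX,originY stage coordinates (micrometres) of the left/top edge
#'   of lattice column/row 0; fixed for the whole dataset so consecutive
#'   layers share one lattice and auto-register.
#' @return A \linkS4class{MosaicSpec}.
#' @export
MosaicSpec <- function(fovSide = 576, overlap = 5, originX = 0, originY = 0) {
  new("MosaicSpec", fovSide = fovSide, overlap = overlap,
      originX = originX, originY = originY)
}

#' @rdname MosaicSpec
#' @param spec a \code{MosaicSpec}.
#' @export
mosaicStride <- function(spec) spec@fovSide - spec@overlap

setMethod("show", "MosaicSpec", function(object) {
  cat(sprintf(
    "MosaicSpec: FOV %g um, overlap %g um (stride %g um), origin (%g, %g)\n",
    object@fovSide, object@overlap, mosaicStride(object),
    object@originX, object@originY))
})

#' @rdname recognizeContour
#' @export
contourMask <- function(contour) contour@mask

#' @rdname recognizeContour
#' @export
contourBBox <- function(contour) contour@bboxUm

#' @rdname recognizeContour
#' @export
isEmptyContour <- function(contour) isTRUE(contour@empty)

.emptyContour <- function(pixelSize) {
  new("BrainContour", mask = matrix(0, 0, 0),
      boundary = matrix(numeric(0), 0, 2),
      bboxUm = rep(NA_real_, 4), pixelSize = pixelSize, empty = TRUE)
}

#' Recognize the brain contour on a coronal DAPI image
#'
#' Sequential mathematical-morphology pipeline on the recognition-resolution
#' cytoarchitecture image: median filtering (noise), threshold segmentation
#' (foreground/background), morphological opening (sectioning debris,
#' embedding-agent boundary), connected-component analysis with removal of
#' components that are too small or whose centroid lies too far from the image
#' centre (large drifting fragments), and hole filling (ventricles). The
#' boundary of the largest surviving component is the brain contour.
#'
#' @param image numeric matrix, single-channel coronal image at the
#'   recognition pixel size.
#' @param params a \linkS4class{ContourParams}.
#' @return A \linkS4class{BrainContour}; when no component survives, an empty
#'   contour flagged via \code{\link{isEmptyContour}} (the caller should skip
#'   the layer and reuse the previous imaging region).
#' @export
recognizeContour <- function(image, params = ContourParams()) {
  px <- params@recognitionPixelSize
  rng <- range(image)
  if (diff(rng) <= 0) return(.emptyContour(px))
  norm <- (image - rng[1]) / diff(rng)
  r <- params@medianKernel %/% 2L
  med <- if (r >= 1L) EBImage::medianFilter(norm, r) else norm
  thr <- if (params@thresholdMethod == "otsu") {
    EBImage::otsu(EBImage::Image(med), range = c(0, 1), levels = 256)
  } else {
    (params@fixedValue - rng[1]) / diff(rng)
  }
  bin <- med > thr
  if (params@openingRadius > 0L) {
    brush <- EBImage::makeBrush(2L * params@openingRadius + 1L,
                                shape = params@openingShape)
    bin <- EBImage::opening(bin, brush)
  }
  lab <- EBImage::bwlabel(bin)
  nComp <- max(lab)
  if (nComp == 0) return(.emptyContour(px))
  areas <- tabulate(lab[lab > 0], nbins = nComp)
  nr <- nrow(image); nc <- ncol(image)
  ctrX <- (nc - 1) / 2; ctrY <- (nr - 1) / 2
  idx <- which(lab > 0, arr.ind = TRUE)
  compOf <- lab[lab > 0]
  cxs <- tapply((idx[, 2] - 1), compOf, mean)
  cys <- tapply((idx[, 1] - 1), compOf, mean)
  largest <- which.max(areas)
  # bounding radius of the largest component (half-diagonal of its bbox)
  li <- idx[compOf == largest, , drop = FALSE]
  bw <- (diff(range(li[, 2]))) * px
  bh <- (diff(range(li[, 1]))) * px
  boundRadius <- sqrt(bw^2 + bh^2) / 2
  limit <- params@fragmentDistanceLimit
  if (is.na(limit)) limit <- boundRadius + 500
  distCtr <- sqrt((cxs - ctrX)^2 + (cys - ctrY)^2) * px
  keep <- vapply(seq_len(nComp), function(k) {
    if (areas[k] == 0) return(FALSE)
    if (k == largest) return(TRUE)
    areas[k] >= params@minFragmentArea &&
      distCtr[[as.character(k)]] <= limit
  }, logical(1))
  if (areas[largest] < params@minFragmentArea)
    return(.emptyContour(px))
  mask <- matrix(0, nr, nc)
  mask[lab %in% which(keep)] <- 1
  mask <- EBImage::fillHull(mask)
  # contour of the largest surviving component
  lab2 <- EBImage::bwlabel(mask)
  a2 <- tabulate(lab2[lab2 > 0], nbins = max(lab2))
  big <- which.max(a2)
  oc <- EBImage::ocontour(lab2 == big)
  boundary <- oc[[1]]  # 0-based (x, y)
  on <- which(mask > 0, arr.ind = TRUE)
  bbox <- c(xmin = (min(on[, 2]) - 1) * px, xmax = (max(on[, 2]) - 1) * px,
            ymin = (min(on[, 1]) - 1) * px, ymax = (max(on[, 1]) - 1) * px)
  new("BrainContour", mask = mask, boundary = boundary,
      bboxUm = unname(bbox), pixelSize = px, empty = FALSE)
}

setMethod("show", "BrainContour", function(object) {
  if (object@empty) {
    cat("BrainContour: <empty> (no tissue component survived)\n")
  } else {
    cat(sprintf(
      "BrainContour: %d x %d px mask at %g um/px, bbox [%.0f, %.0f] x [%.0f, %.0f] um\n",
      nrow(object@mask), ncol(object@mask), object@pixelSize,
      object@bboxUm[1], object@bboxUm[2], object@bboxUm[3], object@bboxUm[4]))
  }
})

# Smallest run of lattice indices covering [lo, hi] (1D).
.latticeSpan <- function(lo, hi, origin, fov, stride) {
  i0 <- floor((lo - origin) / stride)
  i1 <- ceiling((hi - origin - fov) / stride)
  i1 <- max(i1, i0)
  c(i0, i1)
}

#' Plan the minimum rectangular imaging region for a contour
#'
#' Expands the contour's circumscribed rectangle by \code{margin} on all four
#' sides (288 um = half the FOV by default, guaranteeing that the planned
#' region covers the true tissue even where the recognized boundary is
#' slightly tight), then rounds the rectangle up to the smallest run of
#' mosaic lattice columns and rows whose union of FOVs covers it. The lattice
#' never re-anchors between layers.
#'
#' @param contour a \linkS4class{BrainContour} (or a numeric length-4 rect
#'   c(xmin, xmax, ymin, ymax) in micrometres).
#' @param spec a \linkS4class{MosaicSpec}.
#' @param margin micrometres added on each side (default \code{fovSide / 2}).
#' @param stageLimits optional c(xmin, xmax, ymin, ymax) stage travel limits.
#' @param onLimit "error" raises a planning error when the planned rectangle
#'   exceeds the stage limits, "clip" clips it with a warning.
#' @return An \linkS4class{ImagingRegion}.
#' @examples
#' sp <- MosaicSpec()
#' r <- planRegion(c(0, 1144, 0, 1144), sp, margin = 288)
#' nMosaics(r)  # 16: the 1720 um planned extent needs 4 columns and 4 rows
#' @export
planRegion <- function(contour, spec = MosaicSpec(), margin = spec@fovSide / 2,
                       stageLimits = NULL, onLimit = c("error", "clip")) {
  onLimit <- match.arg(onLimit)
  stopifnot(margin >= 0)
  rect <- if (is(contour, "BrainContour")) {
    if (isEmptyContour(contour))
      wvtStop("cannot plan from an empty contour", "wvtPlanningError")
    contour@bboxUm
  } else as.numeric(contour)
  rect <- rect + c(-margin, margin, -margin, margin)
  if (!is.null(stageLimits)) {
    outside <- rect[1] < stageLimits[1] || rect[2] > stageLimits[2] ||
      rect[3] < stageLimits[3] || rect[4] > stageLimits[4]
    if (outside) {
      if (onLimit == "error")
        wvtStop("planned rectangle exceeds stage travel limits",
                "wvtPlanningError")
      warning("planned rectangle clipped to stage travel limits")
      rect <- c(max(rect[1], stageLimits[1]), min(rect[2], stageLimits[2]),
                max(rect[3], stageLimits[3]), min(rect[4], stageLimits[4]))
    }
  }
  stride <- mosaicStride(spec)
  cs <- .latticeSpan(rect[1], rect[2], spec@originX, spec@fovSide, stride)
  rs <- .latticeSpan(rect[3], rect[4], spec@originY, spec@fovSide, stride)
  n <- (cs[2] - cs[1] + 1L) * (rs[2] - rs[1] + 1L)
  new("ImagingRegion", rectUm = rect, col0 = as.integer(cs[1]),
      col1 = as.integer(cs[2]), row0 = as.integer(rs[1]),
      row1 = as.integer(rs[2]), nMosaics = as.integer(n))
}

#' @rdname planRegion
#' @param region an \code{ImagingRegion}.
#' @export
nMosaics <- function(region) region@nMosaics

setMethod("show", "ImagingRegion", function(object) {
  cat(sprintf(
    "ImagingRegion: rect [%.0f, %.0f] x [%.0f, %.0f] um, cols %d..%d, rows %d..%d (%d mosaics)\n",
    object@rectUm[1], object@rectUm[2], object@rectUm[3], object@rectUm[4],
    object@col0, object@col1, object@row0, object@row1, object@nMosaics))
})

#' Plan imaging regions for a whole brain, layer by layer
#'
#' The imaging region of layer k+1 is predicted in real time from the contour
#' recognized on layer k (the recognition runs during the microtome's
#' sectioning of the next face). Layer 1 uses a configured full-coverage
#' region. Layers whose contour recognition comes back empty reuse the
#' previous region and are flagged. For comparison, the fixed-region mosaic
#' count (no recognition: every layer imaged at the maximum cross-section of
#' the whole brain) is also reported.
#'
#' @param layers list of coronal DAPI images (numeric matrices), ordered
#'   anterior to posterior.
#' @param spec a \linkS4class{MosaicSpec}.
#' @param params a \linkS4class{ContourParams}.
#' @param margin micrometres (default \code{fovSide / 2}).
#' @param firstRegion optional \linkS4class{ImagingRegion} for layer 1 (the
#'   region the operator configures around the first block face before any
#'   recognition has run). By default it is planned from layer 1's own
#'   contour; if that comes back empty, the full image extent is used.
#' @param stageLimits optional stage travel limits (clipping with warning).
#' @return A list with \code{regions} (one \linkS4class{ImagingRegion} per
#'   layer), \code{perLayer} data.frame (layer, n_mosaics, n_fixed,
#'   empty_contour), \code{fixedRegion}, and \code{contours}.
#' @export
planWholeBrain <- function(layers, spec = MosaicSpec(),
                           params = ContourParams(),
                           margin = spec@fovSide / 2, firstRegion = NULL,
                           stageLimits = NULL) {
  nL <- length(layers)
  stopifnot(nL >= 1)
  px <- params@recognitionPixelSize
  fullRect <- function(img) c(0, (ncol(img) - 1) * px, 0, (nrow(img) - 1) * px)
  regions <- vector("list", nL)
  contours <- vector("list", nL)
  empty <- logical(nL)
  contours[[1]] <- recognizeContour(layers[[1]], params)
  if (is.null(firstRegion)) {
    firstRegion <- if (isEmptyContour(contours[[1]]))
      planRegion(fullRect(layers[[1]]), spec, margin = 0,
                 stageLimits = stageLimits, onLimit = "clip")
    else planRegion(contours[[1]], spec, margin = margin,
                    stageLimits = stageLimits, onLimit = "clip")
  }
  regions[[1]] <- firstRegion
  for (k in seq_len(nL)) {
    if (k > 1) contours[[k]] <- recognizeContour(layers[[k]], params)
    if (k == nL) break
    if (isEmptyContour(contours[[k]])) {
      empty[k + 1] <- TRUE
      regions[[k + 1]] <- regions[[k]]
    } else {
      regions[[k + 1]] <- planRegion(contours[[k]], spec, margin = margin,
                                     stageLimits = stageLimits,
                                     onLimit = "clip")
    }
  }
  # fixed maximal region: union of all recognized bboxes (max cross-section)
  bbs <- Filter(function(ct) !isEmptyContour(ct), contours)
  fixedRegion <- if (length(bbs)) {
    u <- c(min(vapply(bbs, function(ct) ct@bboxUm[1], 0)),
           max(vapply(bbs, function(ct) ct@bboxUm[2], 0)),
           min(vapply(bbs, function(ct) ct@bboxUm[3], 0)),
           max(vapply(bbs, function(ct) ct@bboxUm[4], 0)))
    planRegion(u, spec, margin = margin, stageLimits = stageLimits,
               onLimit = "clip")
  } else firstRegion
  perLayer <- data.frame(
    layer = seq_len(nL),
    n_mosaics = vapply(regions, nMosaics, integer(1)),
    n_fixed = rep(nMosaics(fixedRegion), nL),
    empty_contour = empty
  )
  list(regions = regions, perLayer = perLayer, fixedRegion = fixedRegion,
       contours = contours)
}

#' Stitch a grid of reconstructed tiles into one coronal image
#'
#' Places each tile at its lattice position and blends the 5 um overlap
#' strips with linear feathering (weights ramp across the overlap, so
#' constant images stitch to the same constant and no double edge appears at
#' the seams). Missing tiles are filled with zeros and masked.
#'
#' @param tiles list of \linkS4class{ReconstructedTile} (grid position taken
#'   from \code{fovIndex}) or of lists \code{(pixels, col, row)}.
#' @param spec a \linkS4class{MosaicSpec}.
#' @param pixelSize micrometres per pixel of the tiles.
#' @return The stitched matrix with attribute \code{"coverage"} (logical,
#'   FALSE where no tile contributed).
#' @export
stitchLayer <- function(tiles, spec = MosaicSpec(), pixelSize = 0.32) {
  stopifnot(length(tiles) >= 1)
  getTile <- function(tl) {
    if (is(tl, "ReconstructedTile"))
      list(pixels = tl@pixels, col = tl@fovIndex[1], row = tl@fovIndex[2])
    else tl
  }
  tl <- lapply(tiles, getTile)
  cols <- vapply(tl, function(x) x$col, numeric(1))
  rows <- vapply(tl, function(x) x$row, numeric(1))
  tilePx <- dim(tl[[1]]$pixels)
  stridePx <- round(mosaicStride(spec) / pixelSize)
  overlapPx <- tilePx[1] - stridePx
  nc <- (max(cols) - min(cols)) * stridePx + tilePx[2]
  nr <- (max(rows) - min(rows)) * stridePx + tilePx[1]
  acc <- matrix(0, nr, nc)
  wacc <- matrix(0, nr, nc)
  ramp <- function(n, ov) {
    w <- rep(1, n)
    if (ov > 0) {
      e <- seq_len(ov) / (ov + 1)
      w[seq_len(ov)] <- e
      w[(n - ov + 1):n] <- rev(e)
    }
    w
  }
  wy <- ramp(tilePx[1], max(overlapPx, 0))
  wx <- ramp(tilePx[2], max(overlapPx, 0))
  wTile <- outer(wy, wx)
  for (i in seq_along(tl)) {
    r0 <- (rows[i] - min(rows)) * stridePx
    c0 <- (cols[i] - min(cols)) * stridePx
    ri <- (r0 + 1):(r0 + tilePx[1]); ci <- (c0 + 1):(c0 + tilePx[2])
    acc[ri, ci] <- acc[ri, ci] + tl[[i]]$pixels * wTile
    wacc[ri, ci] <- wacc[ri, ci] + wTile
  }
  out <- acc
  pos <- wacc > 0
  out[pos] <- acc[pos] / wacc[pos]
  attr(out, "coverage") <- pos
  out
}
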