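#' Construct a lateral similarity transform
#'
#' The forward map acts on pixel positions relative to the image centre:
#' \code{T(p) = scale * R(rotation) p + (dx, dy)/pixelSize}. The rotation and
#' scale pivot is fixed at the image centre because the instrument's channels
#' share one optical axis.
#'
#' @param dx,dy translation in micrometres.
#' @param rotation rotation in degrees, counter-clockwise.
#' @param scale isotropic scale (> 0).
#' @param channel,referenceChannel channel labels (reference is green).
#' @param correlation achieved normalized cross-correlation (NA if not
#'   estimated).
#' @return A \linkS4class{SimilarityTransform2D}.
#' @export
SimilarityTransform2D <- function(dx = 0, dy = 0, rotation = 0, scale = 1,
                                  channel = "blue",
                                  referenceChannel = "green",
                                  correlation = NA_real_) {
  new("SimilarityTransform2D", dx = dx, dy = dy, rotation = rotation,
      scale = scale, channel = channel, referenceChannel = referenceChannel,
      correlation = correlation)
}

#' @rdname SimilarityTransform2D
#' @param t a \code{SimilarityTransform2D}.
#' @export
isIdentityTransform <- function(t, tol = 1e-12) {
  abs(t@dx) < tol && abs(t@dy) < tol && abs(t@rotation) < tol &&
    abs(t@scale - 1) < tol
}

#' @rdname SimilarityTransform2D
#' @export
invertTransform <- function(t) {
  th <- -t@rotation * pi / 180
  s <- 1 / t@scale
  dxy <- -s * c(cos(th) * t@dx - sin(th) * t@dy,
                sin(th) * t@dx + cos(th) * t@dy)
  SimilarityTransform2D(dx = dxy[1], dy = dxy[2], rotation = -t@rotation,
                        scale = s, channel = t@channel,
                        referenceChannel = t@referenceChannel)
}

#' @rdname SimilarityTransform2D
#' @param t2,t1 transforms; the composition applies \code{t1} first.
#' @export
composeTransforms <- function(t2, t1) {
  th2 <- t2@rotation * pi / 180
  d1 <- c(t1@dx, t1@dy)
  d <- t2@scale * c(cos(th2) * d1[1] - sin(th2) * d1[2],
                    sin(th2) * d1[1] + cos(th2) * d1[2]) + c(t2@dx, t2@dy)
  SimilarityTransform2D(dx = d[1], dy = d[2],
                        rotation = t1@rotation + t2@rotation,
                        scale = t1@scale * t2@scale, channel = t2@channel,
                        referenceChannel = t2@referenceChannel)
}

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(sprintf(
    "SimilarityTransform2D [%s -> %s]: dx %.4f um, dy %.4f um, rot %.5f deg, scale %.6f%s\n",
    object@channel, object@referenceChannel, object@dx, object@dy,
    object@rotation, object@scale,
    if (is.na(object@correlation)) ""
    else sprintf(" (corr %.4f)", object@correlation)))
})

#' Resample an image under a similarity transform
#'
#' Warps \code{image} so that the output at position \code{q} (relative to the
#' image centre) samples the input at \code{T^{-1}(q)}, i.e. the transform
#' moves image content forward by \code{t}. Interpolation is bilinear
#' (bicubic is not provided; bilinear error is negligible at the smooth scales
#' involved). Out-of-bounds samples are filled with 0 and flagged in the
#' attribute \code{"oob"} mask. The identity transform bypasses interpolation
#' and returns the input bitwise.
#'
#' @param image numeric matrix.
#' @param t a \linkS4class{SimilarityTransform2D}.
#' @param pixelSize micrometres per pixel (converts the transform's dx/dy).
#' @return The warped matrix, with logical attribute \code{"oob"}.
#' @export
applyTransform <- function(image, t, pixelSize = 0.32) {
  stopifnot(is(t, "SimilarityTransform2D"),
            all(is.finite(c(t@dx, t@dy, t@rotation, t@scale))))
  if (isIdentityTransform(t)) {
    attr(image, "oob") <- matrix(FALSE, nrow(image), ncol(image))
    return(image)
  }
  nr <- nrow(image); nc <- ncol(image)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  gx <- rep(0:(nc - 1), each = nr) - cx
  gy <- rep(0:(nr - 1), times = nc) - cy
  th <- -t@rotation * pi / 180  # inverse rotation
  s <- 1 / t@scale
  dxp <- t@dx / pixelSize; dyp <- t@dy / pixelSize
  ux <- gx - dxp; uy <- gy - dyp
  sx <- s * (cos(th) * ux - sin(th) * uy) + cx
  sy <- s * (sin(th) * ux + cos(th) * uy) + cy
  vals <- bilinearSample(image, sx, sy, fill = 0)
  oob <- sx < 0 | sx > nc - 1 | sy < 0 | sy > nr - 1
  out <- matrix(vals, nr, nc)
  attr(out, "oob") <- matrix(oob, nr, nc)
  out
}

# NCC between two matrices over an interior crop (borders excluded so that
# zero-filled warp edges do not bias the score).
.nccInterior <- function(a, b, margin) {
  nr <- nrow(a); nc <- ncol(a)
  r <- (margin + 1):(nr - margin); cl <- (margin + 1):(nc - margin)
  av <- as.vector(a[r, cl]); bv <- as.vector(b[r, cl])
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Estimate the similarity transform registering a moving channel to a fixed
#' one
#'
#' Finds the transform maximizing the normalized cross-correlation between
#' \code{fixed} and the warped \code{moving} image, following the
#' instrument's calibration procedure: the green channel is fixed and the
#' blue/red images are shifted, rotated and scaled until the correlation
#' coefficient peaks. The search is a coarse grid over rotation and scale --
#' with the best translation per candidate obtained from the FFT
#' cross-correlation peak -- followed by derivative-free (Nelder-Mead) local
#' refinement of all four parameters to sub-pixel precision.
#'
#' @param fixed,moving numeric matrices of identical shape sharing structure
#'   (e.g. a concentric-ring calibration target).
#' @param pixelSize micrometres per pixel.
#' @param maxShiftPx,maxRotDeg,maxScaleDev search envelope: translation
#'   (pixels), rotation (degrees) and |scale - 1|.
#' @param corrFloor registration fails (error of class
#'   \code{wvtRegistrationError}) when the achieved correlation is below this
#'   floor (default 0.2).
#' @param channel,referenceChannel labels recorded on the result.
#' @param details also return the coarse-grid candidates.
#' @return A \linkS4class{SimilarityTransform2D} whose application to
#'   \code{moving} registers it onto \code{fixed}; its \code{correlation}
#'   slot holds the achieved NCC. With \code{details = TRUE}, a list
#'   \code{(transform, grid)}.
#' @export
estimateTransform <- function(fixed, moving, pixelSize = 0.32,
                              maxShiftPx = 12, maxRotDeg = 1.2,
                              maxScaleDev = 0.012, corrFloor = 0.2,
                              channel = "blue", referenceChannel = "green",
                              details = FALSE) {
  if (!identical(dim(fixed), dim(moving)))
    wvtStop("fixed and moving images must share shape", "wvtInputError")
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    wvtStop("image without structure: registration impossible",
            "wvtRegistrationError")
  margin <- ceiling(maxShiftPx) + 4
  rotGrid <- seq(-maxRotDeg, maxRotDeg, length.out = 7)
  scaleGrid <- seq(1 - maxScaleDev, 1 + maxScaleDev, length.out = 7)
  cand <- expand.grid(rot = rotGrid, scale = scaleGrid)
  cand$dx <- NA_real_; cand$dy <- NA_real_; cand$ncc <- NA_real_
  for (i in seq_len(nrow(cand))) {
    tRS <- SimilarityTransform2D(rotation = cand$rot[i],
                                 scale = cand$scale[i])
    w <- applyTransform(moving, tRS, pixelSize)
    surf <- fftXcorrSurface(fixed, w)
    pk <- xcorrPeak(surf, maxShift = ceiling(maxShiftPx))
    tFull <- SimilarityTransform2D(dx = pk$dx * pixelSize,
                                   dy = pk$dy * pixelSize,
                                   rotation = cand$rot[i],
                                   scale = cand$scale[i])
    wf <- applyTransform(moving, tFull, pixelSize)
    cand$dx[i] <- pk$dx; cand$dy[i] <- pk$dy
    cand$ncc[i] <- .nccInterior(fixed, wf, margin)
  }
  best <- which.max(cand$ncc)
  obj <- function(p) {
    tt <- SimilarityTransform2D(dx = p[1] * pixelSize, dy = p[2] * pixelSize,
                                rotation = p[3], scale = p[4])
    w <- applyTransform(moving, tt, pixelSize)
    v <- .nccInterior(fixed, w, margin)
    if (is.na(v)) 1 else -v
  }
  p0 <- c(cand$dx[best], cand$dy[best], cand$rot[best], cand$scale[best])
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-12,
                                     parscale = c(0.5, 0.5, 0.05, 5e-4)))
  corr <- -opt$value
  if (!is.finite(corr) || corr < corrFloor)
    wvtStop(sprintf(
      "registration failed: correlation %.3f below floor %.3f",
      corr, corrFloor), "wvtRegistrationError")
  tr <- SimilarityTransform2D(dx = opt$par[1] * pixelSize,
                              dy = opt$par[2] * pixelSize,
                              rotation = opt$par[3], scale = opt$par[4],
                              channel = channel,
                              referenceChannel = referenceChannel,
                              correlation = corr)
  if (details) list(transform = tr, grid = cand) else tr
}

#' Measure residual co-location error at probe points
#'
#' At each probe the local displacement between the two channels is estimated
#' as the peak offset of the windowed cross-correlation of the two probe
#' windows (sub-pixel via separable quadratic interpolation of the peak), and
#' converted to micrometres. The default probes are the FOV centre and the
#' four corners, mirroring the instrument's calibration readout.
#'
#' @param imgA,imgB numeric matrices of identical shape.
#' @param probePoints numeric matrix (n x 2) of 0-based (x, y) window-centre
#'   coordinates; default centre + 4 corners (inset so windows fit).
#' @param window window side in pixels (default 128; the window is clipped to
#'   the image).
#' @param pixelSize micrometres per pixel.
#' @param maxShiftPx largest displacement searched, pixels (default 8).
#' @param borderPx extra inset (pixels) of the default corner/centre probes
#'   from the image border, e.g. to keep windows clear of the zero-filled
#'   dead zone that resampling leaves along warped-image edges.
#' @return A \linkS4class{ColocationErrorReport}. Flat windows are skipped
#'   with a warning and reported as NA.
#' @export
measureColocationError <- function(imgA, imgB, probePoints = NULL,
                                   window = 128, pixelSize = 0.32,
                                   maxShiftPx = 8, borderPx = 0) {
  if (!identical(dim(imgA), dim(imgB)))
    wvtStop("images must share shape", "wvtInputError")
  nr <- nrow(imgA); nc <- ncol(imgA)
  window <- min(window, 2 * floor(min(nr, nc) / 2.5))
  h <- floor(window / 2)
  if (is.null(probePoints)) {
    cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
    inset <- h + borderPx
    probePoints <- rbind(
      center = c(cx, cy),
      corner1 = c(inset, inset),
      corner2 = c(nc - 1 - inset, inset),
      corner3 = c(inset, nr - 1 - inset),
      corner4 = c(nc - 1 - inset, nr - 1 - inset))
  }
  labels <- rownames(probePoints)
  if (is.null(labels)) labels <- paste0("probe", seq_len(nrow(probePoints)))
  res <- rep(NA_real_, nrow(probePoints))
  for (i in seq_len(nrow(probePoints))) {
    px <- round(probePoints[i, 1]); py <- round(probePoints[i, 2])
    c0 <- max(0, min(px - h, nc - window)); r0 <- max(0, min(py - h, nr - window))
    rows <- (r0 + 1):(r0 + window); cols <- (c0 + 1):(c0 + window)
    wa <- imgA[rows, cols]; wb <- imgB[rows, cols]
    if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
      warning(sprintf("flat window at probe %s: skipped", labels[i]))
      next
    }
    # direct NCC over integer shifts on the valid overlap (no circular
    # wrap-around bias), then separable quadratic sub-pixel refinement
    maxSh <- min(maxShiftPx, floor(window / 4))
    core <- (maxSh + 1):(window - maxSh)
    a0 <- wa[core, core]
    nccAt <- function(dyi, dxi) {
      b <- wb[core - dyi, core - dxi]
      if (stats::sd(b) == 0) return(NA_real_)
      stats::cor(as.vector(a0), as.vector(b))
    }
    sh <- -maxSh:maxSh
    surf <- outer(seq_along(sh), seq_along(sh),
                  Vectorize(function(ii, jj) nccAt(sh[ii], sh[jj])))
    if (all(is.na(surf))) {
      warning(sprintf("flat window at probe %s: skipped", labels[i]))
      next
    }
    k <- arrayInd(which.max(surf), dim(surf))
    ki <- k[1]; kj <- k[2]
    if (surf[ki, kj] > 1 - 1e-12) {
      # exact match at an integer shift: skip sub-pixel refinement
      res[i] <- sqrt(sh[ki]^2 + sh[kj]^2) * pixelSize
      next
    }
    ddy <- if (ki > 1 && ki < nrow(surf) && !anyNA(surf[(ki - 1):(ki + 1), kj]))
      quadSubpixel(surf[ki - 1, kj], surf[ki, kj], surf[ki + 1, kj]) else 0
    ddx <- if (kj > 1 && kj < ncol(surf) && !anyNA(surf[ki, (kj - 1):(kj + 1)]))
      quadSubpixel(surf[ki, kj - 1], surf[ki, kj], surf[ki, kj + 1]) else 0
    dx <- sh[kj] + ddx; dy <- sh[ki] + ddy
    res[i] <- sqrt(dx^2 + dy^2) * pixelSize
  }
  isCorner <- grepl("corner", labels)
  maxOr0 <- function(v) if (any(is.finite(v))) max(v, na.rm = TRUE) else NA_real_
  new("ColocationErrorReport", residuals = res,
      probePoints = probePoints, probeLabels = labels,
      maxCenter = maxOr0(res[!isCorner]), maxCorner = maxOr0(res[isCorner]),
      pixelSize = pixelSize)
}

setMethod("show", "ColocationErrorReport", function(object) {
  cat("ColocationErrorReport\n")
  for (i in seq_along(object@residuals))
    cat(sprintf("  %-8s %s um\n", object@probeLabels[i],
                ifelse(is.na(object@residuals[i]), "skipped",
                       sprintf("%.4f", object@residuals[i]))))
  cat(sprintf("  max center %.4f um, max corner %.4f um\n",
              object@maxCenter, object@maxCorner))
})

#' Serialize / read a similarity transform as JSON
#'
#' Registration parameters are estimated once on the calibration target and
#' reused for a whole dataset; they are re-estimated only after any adjustment
#' of the optical configuration.
#'
#' @param t a \linkS4class{SimilarityTransform2D}.
#' @param path JSON file path.
#' @export
writeTransform <- function(t, path) {
  jsonlite::write_json(list(
    channel = t@channel, reference_channel = t@referenceChannel,
    dx_um = t@dx, dy_um = t@dy, rotation_deg = t@rotation, scale = t@scale,
    correlation = t@correlation, fitted_on = format(Sys.Date())),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  SimilarityTransform2D(dx = j$dx_um, dy = j$dy_um,
                        rotation = j$rotation_deg, scale = j$scale,
                        channel = j$channel,
                        referenceChannel = j$reference_channel,
                        correlation = if (is.null(j$correlation)) NA_real_
                        else j$correlation)
}
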