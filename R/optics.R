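#' Construct the imaging-plane geometry of the three channels
#'
#' The illumination path carries axial chromatic aberration: the blue
#' illumination plane sits below the green/red one (10 um on the instrument by
#' direct measurement). Because real-time nuclear counterstain only penetrates
#' the top few micrometres of the block face, the green/red detection planes
#' are kept just below the crosstalk-free depth (4 um) while the blue
#' detection plane is placed per the chosen imaging scheme (see
#' \code{\link{computeDetectionPlanes}}).
#'
#' @param axialChromaticSeparation blue vs green/red illumination-plane
#'   separation, micrometres.
#' @param gdpOffset depth of the green/red detection plane below the sample
#'   surface, micrometres.
#' @param bdpOffset optional blue detection-plane depth; usually left \code{NA}
#'   and filled by \code{computeDetectionPlanes}.
#' @param crosstalkFreeDepth depth below which counterstain crosstalk reaches
#'   the noise floor, micrometres.
#' @param imageWidthPx tile width in pixels.
#' @param pixelSizeLateral lateral pixel size, micrometres.
#' @param zStep axial step, micrometres.
#' @return An \linkS4class{OpticalGeometry} object. The field-of-view side is
#'   derived as \code{imageWidthPx * pixelSizeLateral}.
#' @examples
#' g <- OpticalGeometry(axialChromaticSeparation = 10, gdpOffset = 4)
#' fovSide(g)  # 576 um
#' @export
OpticalGeometry <- function(axialChromaticSeparation = 10, gdpOffset = 4,
                            bdpOffset = NA_real_, crosstalkFreeDepth = 4,
                            imageWidthPx = 1800, pixelSizeLateral = 0.32,
                            zStep = 2) {
  new("OpticalGeometry",
      axialChromaticSeparation = axialChromaticSeparation,
      gdpOffset = gdpOffset, bdpOffset = bdpOffset,
      crosstalkFreeDepth = crosstalkFreeDepth,
      fovSide = imageWidthPx * pixelSizeLateral,
      pixelSizeLateral = pixelSizeLateral, zStep = zStep,
      imageWidthPx = imageWidthPx)
}

#' @rdname OpticalGeometry
#' @param object,geometry an \code{OpticalGeometry}.
#' @export
fovSide <- function(geometry) geometry@fovSide

#' @rdname OpticalGeometry
#' @export
bdpOffset <- function(geometry) geometry@bdpOffset

setMethod("show", "OpticalGeometry", function(object) {
  cat("OpticalGeometry\n")
  cat(sprintf("  axial chromatic separation: %g um\n",
              object@axialChromaticSeparation))
  cat(sprintf("  GDP/RDP offset below SS:    %g um\n", object@gdpOffset))
  cat(sprintf("  BDP offset below SS:        %s um%s\n",
              ifelse(is.na(object@bdpOffset), "<unset>",
                     format(object@bdpOffset)),
              if (isTRUE(object@bdpOutOfSample)) " [above block face]" else ""))
  cat(sprintf("  FOV %g um (%g px at %g um/px), z step %g um\n",
              object@fovSide, object@imageWidthPx, object@pixelSizeLateral,
              object@zStep))
})

#' Place the blue detection plane for a given imaging scheme
#'
#' In the \emph{conjugated} scheme each channel's detection plane is conjugate
#' to its illumination plane, so the blue detection plane sits at
#' \code{gdpOffset + axialChromaticSeparation} below the sample surface (14 um
#' for the instrument's 10 um separation and 4 um green offset) -- too deep
#' for the surface-confined nuclear counterstain. The \emph{optimized} scheme
#' breaks the blue conjugation and raises the blue detection plane by the
#' crosstalk-free depth above the green one, putting it at the sample surface
#' (depth 0) where the counterstain is strongest.
#'
#' @param geometry an \linkS4class{OpticalGeometry} with separation and green
#'   offset set.
#' @param mode "conjugated" or "optimized".
#' @return The geometry with \code{bdpOffset} filled. A negative resulting
#'   offset (plane above the block face) is flagged via the
#'   \code{bdpOutOfSample} slot, not raised.
#' @examples
#' g <- OpticalGeometry(axialChromaticSeparation = 10, gdpOffset = 4)
#' bdpOffset(computeDetectionPlanes(g, "conjugated"))  # 14
#' bdpOffset(computeDetectionPlanes(g, "optimized"))   # 0
#' @export
computeDetectionPlanes <- function(geometry,
                                   mode = c("conjugated", "optimized")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(geometry@axialChromaticSeparation),
            is.finite(geometry@gdpOffset))
  bdp <- switch(mode,
    conjugated = geometry@gdpOffset + geometry@axialChromaticSeparation,
    optimized = geometry@gdpOffset - geometry@crosstalkFreeDepth
  )
  geometry@bdpOffset <- bdp
  geometry@bdpOutOfSample <- bdp < 0
  geometry
}

#' Fit a Gaussian to a 1D intensity profile and return its FWHM
#'
#' Least-squares fit of \code{A * exp(-(x - mu)^2 / (2 sigma^2)) + c}; the
#' constant offset absorbs the nonzero background of real images, making the
#' estimate invariant under additive background and multiplicative scaling.
#' FWHM = 2 sqrt(2 ln 2) sigma ~ 2.3548 sigma.
#'
#' @param x coordinates in micrometres (>= 5 samples).
#' @param y intensities at \code{x}.
#' @return FWHM in micrometres, with the fit stored in attribute "fit"
#'   (A, mu, sigma, offset).
#' @examples
#' x <- seq(-2, 2, by = 0.05)
#' fitFwhm(x, exp(-x^2 / (2 * 0.2^2)))  # 2.3548 * 0.2
#' @export
fitFwhm <- function(x, y) {
  if (length(x) < 5 || length(x) != length(y))
    wvtStop("profile needs >= 5 (x, y) samples", "wvtMeasurementError")
  if (stats::sd(y) < .Machine$double.eps * max(1, abs(mean(y))))
    wvtStop("flat profile: no peak to fit", "wvtMeasurementError")
  off0 <- min(y)
  amp0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  # half-max-truncated moment: robust width start even when background noise
  # spans the whole profile
  w <- pmax(y - (off0 + amp0 / 2), 0)
  sig0 <- 2 * sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- diff(range(x)) / 6
  resid <- function(p) y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(amp0, mu0, sig0, off0), fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      wvtStop(paste0("Gaussian fit did not converge: ",
                     conditionMessage(e)), "wvtMeasurementError")
  )
  p <- fit$par
  if (!(fit$info %in% 1:4) || !all(is.finite(p)) || abs(p[3]) <= 0 ||
      p[1] <= 0)
    wvtStop("degenerate or non-convergent Gaussian fit",
            "wvtMeasurementError")
  fwhm <- 2 * sqrt(2 * log(2)) * abs(p[3])
  attr(fwhm, "fit") <- c(A = p[1], mu = p[2], sigma = abs(p[3]),
                         offset = p[4])
  fwhm
}

#' Measure lateral and axial resolution from a sub-diffraction bead stack
#'
#' Finds isolated beads (local maxima above background), extracts the X line
#' profile through each bead's maximum for the lateral direction and the Z
#' profile along the stack at the lateral maximum for the axial direction,
#' fits each with \code{\link{fitFwhm}}, and aggregates mean and standard
#' error of the mean. A bead is used only if no other local maximum lies
#' within \code{isolationFactor} times the nominal FWHM (merged bead pairs are
#' excluded).
#'
#' @param stack 3D numeric array (x index = dim 1 column direction? no:
#'   \code{stack[row, col, z]} with row = y, col = x).
#' @param voxelSize numeric length 3, (x, y, z) micrometres per voxel
#'   (defaults 0.32, 0.32, 0.2 as in the bead calibration protocol).
#' @param channel channel label carried into the result.
#' @param isolationFactor multiple of the nominal FWHM within which no other
#'   maximum may lie (default 3).
#' @param nominalFwhmUm nominal lateral FWHM used for the isolation radius
#'   (default 0.5 um).
#' @param minRelIntensity maxima below background + minRelIntensity * (peak -
#'   background) are not treated as beads.
#' @return A \linkS4class{ResolutionMeasurement}.
#' @export
measureBeadResolution <- function(stack, voxelSize = c(0.32, 0.32, 0.2),
                                  channel = "green", isolationFactor = 3,
                                  nominalFwhmUm = 0.5,
                                  minRelIntensity = 0.25) {
  stopifnot(length(dim(stack)) == 3)
  bg <- stats::median(stack)
  peak <- max(stack)
  if (peak <= bg)
    wvtStop("no bead found above background", "wvtEmptyMeasurementError")
  thr <- bg + minRelIntensity * (peak - bg)
  lm <- localMaxima3d(stack, thr)
  idx <- which(lm, arr.ind = TRUE)
  if (nrow(idx) == 0)
    wvtStop("no bead found above background", "wvtEmptyMeasurementError")
  # positions in um: (x, y, z) = ((col-1)*vx, (row-1)*vy, (z-1)*vz)
  pos <- cbind((idx[, 2] - 1) * voxelSize[1],
               (idx[, 1] - 1) * voxelSize[2],
               (idx[, 3] - 1) * voxelSize[3])
  # collapse plateau ties (maxima within ~2 voxels are one bead)
  vals <- stack[idx]
  ord <- dedupPoints(pos, vals, radius = 2 * max(voxelSize))
  idx <- idx[ord, , drop = FALSE]
  pos <- pos[ord, , drop = FALSE]
  isoR <- isolationFactor * nominalFwhmUm
  keep <- vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
      (pos[, 3] - pos[i, 3])^2
    sum(d2 < isoR^2) == 1  # only itself
  }, logical(1))
  idx <- idx[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  if (nrow(idx) == 0)
    wvtStop("no isolated bead available", "wvtEmptyMeasurementError")
  rows <- vector("list", nrow(idx))
  d <- dim(stack)
  # profile windows around the bead keep the fit local: 4 nominal FWHMs,
  # at least 8 voxels, on each side
  winL <- max(8L, ceiling(4 * nominalFwhmUm / voxelSize[1]))
  winZ <- max(12L, ceiling(8 * nominalFwhmUm / voxelSize[3]))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cl <- idx[i, 2]; z <- idx[i, 3]
    lat <- tryCatch({
      cs <- max(1L, cl - winL):min(d[2], cl + winL)
      fitFwhm((cs - 1) * voxelSize[1], stack[r, cs, z])
    }, wvtError = function(e) NA_real_)
    axl <- tryCatch({
      zs <- max(1L, z - winZ):min(d[3], z + winZ)
      fitFwhm((zs - 1) * voxelSize[3], stack[r, cl, zs])
    }, wvtError = function(e) NA_real_)
    rows[[i]] <- data.frame(x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
                            lateral_fwhm = as.numeric(lat),
                            axial_fwhm = as.numeric(axl))
  }
  per <- do.call(rbind, rows)
  per <- per[stats::complete.cases(per), , drop = FALSE]
  if (nrow(per) == 0)
    wvtStop("all bead fits failed", "wvtEmptyMeasurementError")
  semOf <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  new("ResolutionMeasurement", channel = channel,
      lateralFwhm = mean(per$lateral_fwhm), axialFwhm = mean(per$axial_fwhm),
      nBeads = nrow(per), semLateral = semOf(per$lateral_fwhm),
      semAxial = semOf(per$axial_fwhm), perBead = per)
}

setMethod("show", "ResolutionMeasurement", function(object) {
  cat(sprintf(
    "ResolutionMeasurement [%s]: lateral %.3f +/- %.3f um, axial %.3f +/- %.3f um (n = %d beads)\n",
    object@channel, object@lateralFwhm, object@semLateral,
    object@axialFwhm, object@semAxial, object@nBeads))
})
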