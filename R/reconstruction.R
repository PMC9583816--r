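#' Construct a three-phase raw triplet for one field of view
#'
#' @param raw0,raw1,raw2 numeric matrices of identical shape: the raw camera
#'   frames acquired under fringe phases 0, pi/2 and pi.
#' @param channel "blue", "green" or "red".
#' @param fovIndex integer (column, row) grid coordinates of the tile.
#' @return A \linkS4class{PhaseTriplet}.
#' @export
PhaseTriplet <- function(raw0, raw1, raw2, channel = "green",
                         fovIndex = c(0L, 0L)) {
  if (!identical(dim(raw0), dim(raw1)) || !identical(dim(raw0), dim(raw2)))
    wvtStop("the three raw images must share the same shape", "wvtInputError")
  new("PhaseTriplet", raw0 = raw0, raw1 = raw1, raw2 = raw2,
      channel = channel, fovIndex = as.integer(fovIndex))
}

setMethod("show", "PhaseTriplet", function(object) {
  cat(sprintf("PhaseTriplet [%s] %d x %d px, fov (%d, %d)\n",
              object@channel, nrow(object@raw0), ncol(object@raw0),
              object@fovIndex[1], object@fovIndex[2]))
})

#' @rdname reconstructSim
#' @export
tilePixels <- function(tile) tile@pixels

#' @rdname reconstructSim
#' @export
tileMode <- function(tile) tile@mode

.saturationMask <- function(t, saturation = 65535) {
  sat <- t@raw0 >= saturation | t@raw1 >= saturation | t@raw2 >= saturation
  if (any(sat)) sat else matrix(logical(0), 0, 0)
}

#' Optically sectioned (SIM) reconstruction of a phase triplet
#'
#' Demodulates the three raw frames acquired at fringe phases 0, pi/2 and pi
#' pixelwise as
#' \deqn{I_{SIM} = \frac{1}{2}\sqrt{(I_0 - I_2)^2 + (2 I_1 - I_0 - I_2)^2}.}
#' For raws \eqn{I_k = S (1 + m\cos(\theta + k\pi/2))/2} this recovers the
#' in-focus modulated amplitude \eqn{m S / 2} exactly, independent of the
#' local fringe phase \eqn{\theta}, and rejects any unmodulated (out-of-focus
#' or constant) contribution: adding a constant to all three raws leaves the
#' output unchanged. The instrument's binary DMD fringes act as sinusoids at
#' the sample because the objective passes only the fundamental. Output is
#' non-negative by construction, so no clipping is applied. Saturated raw
#' pixels are propagated and flagged in the tile's saturation mask, not
#' repaired.
#'
#' @param t a \linkS4class{PhaseTriplet}.
#' @param pixelSize lateral pixel size of the tile, micrometres.
#' @return A \linkS4class{ReconstructedTile} with \code{mode = "SIM"}.
#' @examples
#' t <- PhaseTriplet(matrix(150, 2, 2), matrix(100, 2, 2), matrix(50, 2, 2))
#' tilePixels(reconstructSim(t))[1, 1]  # 50
#' @export
reconstructSim <- function(t, pixelSize = 0.32) {
  stopifnot(is(t, "PhaseTriplet"))
  a <- t@raw0 - t@raw2
  b <- 2 * t@raw1 - t@raw0 - t@raw2
  px <- 0.5 * sqrt(a * a + b * b)
  new("ReconstructedTile", pixels = px, mode = "SIM", channel = t@channel,
      fovIndex = t@fovIndex, pixelSize = pixelSize,
      saturationMask = .saturationMask(t), scaleFactor = 1)
}

#' Wide-field (WF) reconstruction of a phase triplet
#'
#' Superposes the three raw frames as a pixelwise sum, preserving photon-count
#' semantics (a mean is available for display via \code{average = TRUE}). For
#' fringe phases stepped by pi/2 the fringes do not cancel identically in
#' the sum -- the residual modulation is \eqn{B(\cos\theta - \sin\theta -
#' \cos\theta)} terms evaluated per pixel -- but for the surface-detected blue
#' channel of the optimized scheme the modulation depth at the detection plane
#' is small and the WF image is competent for cytoarchitectural analysis.
#'
#' @param t a \linkS4class{PhaseTriplet}.
#' @param pixelSize lateral pixel size, micrometres.
#' @param average return the mean instead of the sum.
#' @param rescale16 rescale the output into 0..65535 and record the scale
#'   factor in the tile.
#' @return A \linkS4class{ReconstructedTile} with \code{mode = "WF"}.
#' @export
reconstructWf <- function(t, pixelSize = 0.32, average = FALSE,
                          rescale16 = FALSE) {
  stopifnot(is(t, "PhaseTriplet"))
  px <- t@raw0 + t@raw1 + t@raw2
  if (average) px <- px / 3
  sc <- 1
  if (rescale16 && max(px) > 65535) {
    sc <- 65535 / max(px)
    px <- px * sc
  }
  new("ReconstructedTile", pixels = px, mode = "WF", channel = t@channel,
      fovIndex = t@fovIndex, pixelSize = pixelSize,
      saturationMask = .saturationMask(t), scaleFactor = sc)
}

#' Default per-channel reconstruction scheme of the optimized imaging mode
#'
#' SIM (optical sectioning) for the green and red channels, whose detection
#' planes are conjugate to their illumination planes; WF for the blue channel,
#' whose detection plane is raised to the sample surface and therefore only
#' weakly modulated.
#' @export
defaultScheme <- function() c(blue = "WF", green = "SIM", red = "SIM")

#' Reconstruct a field of view according to a per-channel mode map
#'
#' @param t a \linkS4class{PhaseTriplet}.
#' @param scheme named character vector mapping channels to "SIM"/"WF"
#'   (default \code{\link{defaultScheme}}).
#' @param pixelSize lateral pixel size, micrometres.
#' @return A \linkS4class{ReconstructedTile} reconstructed in the mode the
#'   scheme assigns to the tile's channel. Overriding the blue channel to SIM
#'   is honoured with a warning (its detection plane is unmodulated in the
#'   optimized scheme, so SIM output there has very low SNR).
#' @export
reconstructFov <- function(t, scheme = defaultScheme(), pixelSize = 0.32) {
  stopifnot(is(t, "PhaseTriplet"))
  if (!t@channel %in% names(scheme))
    wvtStop(sprintf("scheme does not assign a mode to channel '%s'",
                    t@channel), "wvtConfigError")
  mode <- scheme[[t@channel]]
  if (!mode %in% c("SIM", "WF"))
    wvtStop(sprintf("unknown reconstruction mode '%s'", mode),
            "wvtConfigError")
  if (t@channel == "blue" && mode == "SIM")
    warning("SIM reconstruction requested for the blue channel; ",
            "its surface detection plane is only weakly modulated")
  if (mode == "SIM") reconstructSim(t, pixelSize)
  else reconstructWf(t, pixelSize)
}

setMethod("show", "ReconstructedTile", function(object) {
  cat(sprintf("ReconstructedTile [%s/%s] %d x %d px at %g um/px%s\n",
              object@channel, object@mode, nrow(object@pixels),
              ncol(object@pixels), object@pixelSize,
              if (length(object@saturationMask)) " (saturation flagged)"
              else ""))
})
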