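#' @import methods
NULL

#' Imaging-plane geometry of the three-channel system
#'
#' Captures the axial arrangement of the illumination and detection planes of
#' the blue, green and red channels relative to the sample surface (SS) of the
#' block face. The axial chromatic aberration of the illumination path
#' separates the blue illumination plane from the green/red ones; the
#' crosstalk-free depth is the depth below SS at which nuclear counterstain
#' signal has decayed to the noise floor, which dictates where the green/red
#' detection planes must sit.
#'
#' @slot axialChromaticSeparation numeric, blue vs green/red illumination-plane
#'   separation in micrometres.
#' @slot gdpOffset numeric, depth of the green/red detection plane below SS
#'   (micrometres).
#' @slot bdpOffset numeric, depth of the blue detection plane below SS
#'   (micrometres); \code{NA} until computed by
#'   \code{\link{computeDetectionPlanes}}. Negative values mean the plane sits
#'   above the block face and are flagged, not rejected.
#' @slot crosstalkFreeDepth numeric, depth (micrometres) beyond which nuclear
#'   counterstain crosstalk is at the noise floor (default 4).
#' @slot fovSide numeric, side of one field of view in micrometres.
#' @slot pixelSizeLateral numeric, lateral pixel size in micrometres.
#' @slot zStep numeric, axial step in micrometres.
#' @slot imageWidthPx numeric, tile width in pixels.
#' @slot bdpOutOfSample logical, TRUE when the computed blue detection plane
#'   lies above the block face.
#' @seealso \code{\link{OpticalGeometry}}, \code{\link{computeDetectionPlanes}}
#' @exportClass OpticalGeometry
setClass("OpticalGeometry",
  representation(
    axialChromaticSeparation = "numeric",
    gdpOffset = "numeric",
    bdpOffset = "numeric",
    crosstalkFreeDepth = "numeric",
    fovSide = "numeric",
    pixelSizeLateral = "numeric",
    zStep = "numeric",
    imageWidthPx = "numeric",
    bdpOutOfSample = "logical"
  ),
  prototype(
    bdpOffset = NA_real_,
    crosstalkFreeDepth = 4,
    fovSide = 576,
    pixelSizeLateral = 0.32,
    zStep = 2,
    imageWidthPx = 1800,
    bdpOutOfSample = FALSE
  ),
  validity = function(object) {
    msg <- character()
    nn <- c(
      axialChromaticSeparation = object@axialChromaticSeparation,
      gdpOffset = object@gdpOffset,
      crosstalkFreeDepth = object@crosstalkFreeDepth,
      fovSide = object@fovSide,
      pixelSizeLateral = object@pixelSizeLateral,
      zStep = object@zStep,
      imageWidthPx = object@imageWidthPx
    )
    if (any(!is.finite(nn)))
      msg <- c(msg, "all geometry fields must be finite")
    else if (any(nn < 0))
      msg <- c(msg, "geometry fields must be non-negative")
    if (all(is.finite(c(object@fovSide, object@pixelSizeLateral,
                        object@imageWidthPx))) &&
        abs(object@fovSide -
            object@imageWidthPx * object@pixelSizeLateral) > 1e-6)
      msg <- c(msg, "fovSide must equal imageWidthPx * pixelSizeLateral")
    if (length(msg)) msg else TRUE
  }
)

#' Per-bead resolution measurement aggregated per channel
#'
#' @slot channel character, one of "blue", "green", "red".
#' @slot lateralFwhm numeric, mean lateral FWHM in micrometres.
#' @slot axialFwhm numeric, mean axial FWHM in micrometres.
#' @slot nBeads integer, number of isolated beads aggregated.
#' @slot semLateral numeric, standard error of the mean lateral FWHM.
#' @slot semAxial numeric, standard error of the mean axial FWHM.
#' @slot perBead data.frame with one row per accepted bead
#'   (columns x, y, z, lateral_fwhm, axial_fwhm).
#' @exportClass ResolutionMeasurement
setClass("ResolutionMeasurement",
  representation(
    channel = "character", lateralFwhm = "numeric", axialFwhm = "numeric",
    nBeads = "integer", semLateral = "numeric", semAxial = "numeric",
    perBead = "data.frame"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nBeads < 1L) msg <- c(msg, "nBeads must be >= 1")
    if (any(c(object@lateralFwhm, object@axialFwhm) <= 0))
      msg <- c(msg, "FWHM values must be positive")
    if (any(c(object@semLateral, object@semAxial) < 0))
      msg <- c(msg, "s.e.m. values must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Three phase-shifted raw images of one field of view
#'
#' One structured-illumination acquisition: the fringe pattern is projected at
#' nominal phases 0, pi/2 and pi and one raw camera frame is recorded per
#' phase.
#'
#' @slot raw0,raw1,raw2 numeric matrices of identical shape, intensities >= 0.
#' @slot channel character, "blue", "green" or "red".
#' @slot fovIndex integer of length 2, (column, row) grid coordinates.
#' @exportClass PhaseTriplet
setClass("PhaseTriplet",
  representation(
    raw0 = "matrix", raw1 = "matrix", raw2 = "matrix",
    channel = "character", fovIndex = "integer"
  ),
  prototype(channel = "green", fovIndex = c(0L, 0L)),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@raw0), dim(object@raw1)) ||
        !identical(dim(object@raw0), dim(object@raw2)))
      msg <- c(msg, "the three raw images must share the same shape")
    if (min(object@raw0, object@raw1, object@raw2) < 0)
      msg <- c(msg, "raw intensities must be non-negative")
    if (!object@channel %in% c("blue", "green", "red"))
      msg <- c(msg, "channel must be blue, green or red")
    if (length(msg)) msg else TRUE
  }
)

#' A reconstructed (SIM or WF) single-FOV tile
#'
#' @slot pixels numeric matrix, same shape as the raw images.
#' @slot mode character, "SIM" (optically sectioned) or "WF" (wide field).
#' @slot channel character.
#' @slot fovIndex integer of length 2.
#' @slot pixelSize numeric, lateral pixel size in micrometres.
#' @slot saturationMask logical matrix marking pixels where any raw frame was
#'   saturated (65535); empty matrix when no saturation.
#' @slot scaleFactor numeric, multiplicative factor applied when rescaling for
#'   16-bit storage (1 when none).
#' @exportClass ReconstructedTile
setClass("ReconstructedTile",
  representation(
    pixels = "matrix", mode = "character", channel = "character",
    fovIndex = "integer", pixelSize = "numeric",
    saturationMask = "matrix", scaleFactor = "numeric"
  ),
  prototype(pixelSize = 0.32, saturationMask = matrix(logical(0), 0, 0),
            scaleFactor = 1),
  validity = function(object) {
    if (!object@mode %in% c("SIM", "WF"))
      return("mode must be SIM or WF")
    TRUE
  }
)

#' Lateral similarity transform correcting one channel onto the reference
#'
#' Describes the rigid-plus-scale lateral correction (translation, rotation
#' about the image centre, isotropic scale) that brings a moving channel into
#' register with the fixed (green) reference channel.
#'
#' @slot dx,dy numeric, translation in micrometres.
#' @slot rotation numeric, rotation in degrees (counter-clockwise).
#' @slot scale numeric, isotropic scale factor (> 0).
#' @slot channel character, the channel this transform corrects.
#' @slot referenceChannel character, the fixed channel (green).
#' @slot correlation numeric, normalized cross-correlation achieved at these
#'   parameters (NA when not estimated from data).
#' @exportClass SimilarityTransform2D
setClass("SimilarityTransform2D",
  representation(
    dx = "numeric", dy = "numeric", rotation = "numeric", scale = "numeric",
    channel = "character", referenceChannel = "character",
    correlation = "numeric"
  ),
  prototype(dx = 0, dy = 0, rotation = 0, scale = 1, channel = "blue",
            referenceChannel = "green", correlation = NA_real_),
  validity = function(object) {
    if (!is.finite(object@scale) || object@scale <= 0)
      return("scale must be positive and finite")
    if (!all(is.finite(c(object@dx, object@dy, object@rotation))))
      return("dx, dy and rotation must be finite")
    TRUE
  }
)

#' Per-probe residual co-location error between two channels
#'
#' @slot residuals numeric vector of per-probe displacement magnitudes in
#'   micrometres (NA where the probe window was flat and skipped).
#' @slot probePoints numeric matrix (n x 2) of 0-based pixel coordinates
#'   (x, y) of the probe centres.
#' @slot probeLabels character vector, e.g. "center", "corner1"...
#' @slot maxCenter numeric, largest residual over centre probes (micrometres).
#' @slot maxCorner numeric, largest residual over corner probes.
#' @slot pixelSize numeric, micrometres per pixel.
#' @exportClass ColocationErrorReport
setClass("ColocationErrorReport",
  representation(
    residuals = "numeric", probePoints = "matrix", probeLabels = "character",
    maxCenter = "numeric", maxCorner = "numeric", pixelSize = "numeric"
  )
)

#' Parameters of the DAPI contour-recognition pipeline
#'
#' @slot medianKernel integer, full width (odd, pixels) of the median filter.
#' @slot thresholdMethod character, "otsu" or "fixed".
#' @slot fixedValue numeric, threshold on the raw intensity scale when
#'   \code{thresholdMethod = "fixed"}.
#' @slot openingRadius integer, radius (pixels) of the structuring element for
#'   the morphological opening.
#' @slot openingShape character, "disc" (default) or "box".
#' @slot fragmentDistanceLimit numeric, micrometres: components (other than the
#'   largest) whose centroid lies farther than this from the image centre are
#'   dropped; \code{NA} derives the limit per image as the largest component's
#'   bounding radius + 500 um.
#' @slot minFragmentArea numeric, minimum component area in squared pixels.
#' @slot recognitionPixelSize numeric, micrometres per pixel of the
#'   downsampled recognition image (default 1.68).
#' @exportClass ContourParams
setClass("ContourParams",
  representation(
    medianKernel = "integer", thresholdMethod = "character",
    fixedValue = "numeric", openingRadius = "integer",
    openingShape = "character", fragmentDistanceLimit = "numeric",
    minFragmentArea = "numeric", recognitionPixelSize = "numeric"
  ),
  prototype(
    medianKernel = 5L, thresholdMethod = "otsu", fixedValue = NA_real_,
    openingRadius = 3L, openingShape = "disc",
    fragmentDistanceLimit = NA_real_, minFragmentArea = 500,
    recognitionPixelSize = 1.68
  ),
  validity = function(object) {
    msg <- character()
    if (object@medianKernel < 1L || object@medianKernel %% 2L == 0L)
      msg <- c(msg, "medianKernel must be odd and >= 1")
    if (object@openingRadius < 0L)
      msg <- c(msg, "openingRadius must be >= 0")
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
      msg <- c(msg, "thresholdMethod must be otsu or fixed")
    if (!object@openingShape %in% c("disc", "box"))
      msg <- c(msg, "openingShape must be disc or box")
    if (!is.na(object@recognitionPixelSize) &&
        object@recognitionPixelSize <= 0)
      msg <- c(msg, "recognitionPixelSize must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Recognized brain contour of one coronal layer
#'
#' @slot mask binary matrix (0/1) at recognition resolution, hole-filled.
#' @slot boundary numeric matrix (n x 2) of 0-based (x, y) boundary pixel
#'   coordinates of the largest component (closed polygon).
#' @slot bboxUm numeric length 4, (xmin, xmax, ymin, ymax) of the circumscribed
#'   rectangle in micrometres (sample frame, pixel-centre convention).
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot empty logical, TRUE when no tissue component survived (layer skipped,
#'   previous imaging region should be reused).
#' @exportClass BrainContour
setClass("BrainContour",
  representation(
    mask = "matrix", boundary = "matrix", bboxUm = "numeric",
    pixelSize = "numeric", empty = "logical"
  ),
  prototype(empty = FALSE)
)

#' Fixed mosaic lattice of the stage scan
#'
#' The lattice is anchored at fixed stage coordinates for the whole dataset so
#' that every layer's tiles auto-register; planned regions are index ranges on
#' this one lattice.
#'
#' @slot fovSide numeric, field-of-view side in micrometres (default 576).
#' @slot overlap numeric, overlap between adjacent FOVs in micrometres
#'   (default 5).
#' @slot originX,originY numeric, stage coordinate (micrometres) of the left/
#'   top edge of lattice column/row 0.
#' @exportClass MosaicSpec
setClass("MosaicSpec",
  representation(fovSide = "numeric", overlap = "numeric",
                 originX = "numeric", originY = "numeric"),
  prototype(fovSide = 576, overlap = 5, originX = 0, originY = 0),
  validity = function(object) {
    if (object@overlap < 0 || object@overlap >= object@fovSide)
      return("overlap must satisfy 0 <= overlap < fovSide")
    TRUE
  }
)

#' Planned rectangular imaging region as a mosaic-grid span
#'
#' @slot rectUm numeric length 4, (xmin, xmax, ymin, ymax) of the requested
#'   rectangle (circumscribed rectangle expanded by the margin).
#' @slot col0,col1,row0,row1 integer lattice indices of the covering grid span.
#' @slot nMosaics integer, cols x rows.
#' @exportClass ImagingRegion
setClass("ImagingRegion",
  representation(rectUm = "numeric", col0 = "integer", col1 = "integer",
                 row0 = "integer", row1 = "integer", nMosaics = "integer")
)

#' A set of detected somas of one channel in one brain
#'
#' @slot coords numeric matrix (n x 3), (x, y, z) in micrometres.
#' @slot intensity numeric vector, detection intensity (a.u.).
#' @slot ids integer vector, unique within the set, sorted.
#' @slot channel character.
#' @slot brainId character.
#' @slot voxelSize numeric length 3, voxel size used for detection
#'   (default 1 x 1 x 2 um).
#' @exportClass SomaSet
setClass("SomaSet",
  representation(coords = "matrix", intensity = "numeric", ids = "integer",
                 channel = "character", brainId = "character",
                 voxelSize = "numeric"),
  prototype(channel = "green", brainId = "brain", voxelSize = c(1, 1, 2)),
  validity = function(object) {
    n <- nrow(object@coords)
    msg <- character()
    if (ncol(object@coords) != 3 && n > 0)
      msg <- c(msg, "coords must have 3 columns")
    if (length(object@ids) != n)
      msg <- c(msg, "ids length must match coords rows")
    if (anyDuplicated(object@ids))
      msg <- c(msg, "ids must be unique")
    if (is.unsorted(object@ids))
      msg <- c(msg, "somas must be sorted by id")
    if (length(msg)) msg else TRUE
  }
)

#' Co-located soma pairs between the green and red channels
#'
#' @slot pairs data.frame with columns green_id, red_id, distance (micrometres).
#' @slot threshold numeric, pairing distance threshold (strict less-than),
#'   default 1 micrometre.
#' @exportClass ColocatedPairs
setClass("ColocatedPairs",
  representation(pairs = "data.frame", threshold = "numeric"),
  prototype(threshold = 1.0),
  validity = function(object) {
    p <- object@pairs
    msg <- character()
    if (nrow(p)) {
      if (anyDuplicated(p$green_id) || anyDuplicated(p$red_id))
        msg <- c(msg, "each soma id may appear in at most one pair")
      if (any(p$distance >= object@threshold))
        msg <- c(msg, "all pair distances must be strictly below threshold")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Integer-labelled atlas volume with region hierarchy
#'
#' @slot labels integer 3D array; 0 is background.
#' @slot voxelSize numeric length 3, micrometres.
#' @slot origin numeric length 3, micrometre coordinate of the low corner of
#'   voxel (1,1,1).
#' @slot hierarchy data.frame with columns id, name, parent_id, parent_name
#'   mapping every nonzero label to its parent region.
#' @exportClass AtlasVolume
setClass("AtlasVolume",
  representation(labels = "array", voxelSize = "numeric", origin = "numeric",
                 hierarchy = "data.frame"),
  prototype(origin = c(0, 0, 0)),
  validity = function(object) {
    lab <- unique(as.integer(object@labels))
    lab <- lab[lab != 0L]
    if (!all(lab %in% object@hierarchy$id))
      return("every nonzero label needs a hierarchy entry")
    TRUE
  }
)

#' Per-region soma counts and proportions
#'
#' @slot table data.frame with columns region_id, region_name, level, count,
#'   proportion_pct and, after cross-brain aggregation, mean_pct and sem_pct.
#' @slot level character, "region" or "subregion".
#' @slot nBrains integer, number of brains aggregated (1 for a single report).
#' @slot totalSomas integer, total somas in the set (single-brain report).
#' @slot flags character, e.g. "unassigned-somas", "n=1-sem-zero".
#' @exportClass RegionReport
setClass("RegionReport",
  representation(table = "data.frame", level = "character",
                 nBrains = "integer", totalSomas = "integer",
                 flags = "character"),
  prototype(nBrains = 1L, flags = character())
)

#' Acquisition accounting constants
#'
#' @slot tileShape integer length 2, tile size in pixels (1800 x 1800).
#' @slot bitDepth integer, bits per pixel (16).
#' @slot nChannels integer (3).
#' @slot phasesPerMosaic integer (3).
#' @slot perMosaicTimeMs numeric, all-inclusive imaging time per mosaic (342.5).
#' @slot layers integer, number of coronal layers (NA when not applicable).
#' @exportClass AcquisitionAccounting
setClass("AcquisitionAccounting",
  representation(tileShape = "integer", bitDepth = "integer",
                 nChannels = "integer", phasesPerMosaic = "integer",
                 perMosaicTimeMs = "numeric", layers = "integer"),
  prototype(tileShape = c(1800L, 1800L), bitDepth = 16L, nChannels = 3L,
            phasesPerMosaic = 3L, perMosaicTimeMs = 342.5,
            layers = NA_integer_),
  validity = function(object) {
    if (any(c(object@tileShape, object@bitDepth, object@nChannels,
              object@phasesPerMosaic, object@perMosaicTimeMs) <= 0))
      return("all accounting constants must be positive")
    TRUE
  }
)

#' Specification of a synthetic phantom brain
#'
#' The generator's defaults emulate the instrument's study conditions: coronal
#' sections with irregular superellipse outlines tapering along the
#' anterior-posterior axis, a ventricle-like interior hole, peripheral
#' sectioning fragments, DAPI-like nuclear speckle confined to the block
#' surface, and sparse green/red soma populations with a small planted
#' co-location fraction.
#'
#' @slot nLayers integer, number of coronal layers.
#' @slot imageSizePx integer, side of the square recognition-resolution image.
#' @slot pixelSize numeric, micrometres per pixel (1.68 at recognition
#'   resolution).
#' @slot exponent numeric, superellipse exponent of the tissue outline.
#' @slot semiAxes numeric matrix (nLayers x 2), per-layer semi-axes in
#'   micrometres.
#' @slot ventricleFrac numeric, ventricle semi-axes as a fraction of the tissue
#'   semi-axes (0 disables the hole).
#' @slot nucleiDensityMm2 numeric, nuclei per square millimetre.
#' @slot nGreen,nRed integer, soma counts per channel.
#' @slot colocFraction numeric in [0, 1], expected fraction of green somas
#'   duplicated in red within 0.8 um.
#' @slot nFragments integer, peripheral sectioning fragments per layer.
#' @slot fragmentSizeRange numeric length 2, fragment diameter range in
#'   micrometres.
#' @slot noiseSd numeric, Gaussian read-noise s.d. in intensity counts.
#' @slot poisson logical, add Poisson shot noise.
#' @slot zExtentUm numeric, axial extent of the soma volume in micrometres.
#' @slot regionWeights numeric, planted soma distribution across the parent
#'   regions of the synthetic atlas (sums to 1).
#' @slot seed integer, fixes all randomness of the generator.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    nLayers = "integer", imageSizePx = "integer", pixelSize = "numeric",
    exponent = "numeric", semiAxes = "matrix", ventricleFrac = "numeric",
    nucleiDensityMm2 = "numeric", nGreen = "integer", nRed = "integer",
    colocFraction = "numeric", nFragments = "integer",
    fragmentSizeRange = "numeric", noiseSd = "numeric", poisson = "logical",
    zExtentUm = "numeric", regionWeights = "numeric", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@colocFraction < 0 || object@colocFraction > 1)
      msg <- c(msg, "colocFraction must be in [0, 1]")
    if (any(c(object@nucleiDensityMm2, object@nGreen, object@nRed,
              object@nFragments) < 0))
      msg <- c(msg, "densities and counts must be non-negative")
    if (nrow(object@semiAxes) != object@nLayers)
      msg <- c(msg, "semiAxes must have one row per layer")
    if (abs(sum(object@regionWeights) - 1) > 1e-8)
      msg <- c(msg, "regionWeights must sum to 1")
    if (length(msg)) msg else TRUE
  }
)
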