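#' Acquisition accounting constants
#'
#' @param tileShape tile size in pixels (default 1800 x 1800, the imaging
#'   format fitting the DMD-modulated field).
#' @param bitDepth bits per pixel (16).
#' @param nChannels simultaneously acquired channels (3).
#' @param phasesPerMosaic structured-illumination phases per mosaic (3).
#' @param perMosaicTimeMs all-inclusive imaging time per mosaic in
#'   milliseconds: camera exposures, DMD flips, stage settling, SIM
#'   reconstruction and saving (342.5 ms at 50 ms exposure).
#' @param layers number of coronal layers (optional).
#' @return An \linkS4class{AcquisitionAccounting}.
#' @export
AcquisitionAccounting <- function(tileShape = c(1800L, 1800L), bitDepth = 16L,
                                  nChannels = 3L, phasesPerMosaic = 3L,
                                  perMosaicTimeMs = 342.5,
                                  layers = NA_integer_) {
  new("AcquisitionAccounting", tileShape = as.integer(tileShape),
      bitDepth = as.integer(bitDepth), nChannels = as.integer(nChannels),
      phasesPerMosaic = as.integer(phasesPerMosaic),
      perMosaicTimeMs = perMosaicTimeMs, layers = as.integer(layers))
}

#' Size of one mosaic tile in megabytes
#'
#' Binary units (1 MB = 2^20 bytes) are used throughout the accounting: they
#' are the units under which the printed tile and dataset sizes are internally
#' consistent with the printed pixel dimensions. Decimal units are available
#' via \code{binary = FALSE}.
#'
#' @param tileShape integer length 2, pixels.
#' @param bitDepth bits per pixel.
#' @param binary use 2^20-byte megabytes (default) or 10^6-byte.
#' @return Size in MB (full precision; report rounded to 2 decimals).
#' @examples
#' round(tileSizeMb(c(1800, 1800), 16), 2)  # 6.18
#' @export
tileSizeMb <- function(tileShape = c(1800, 1800), bitDepth = 16,
                       binary = TRUE) {
  stopifnot(all(tileShape > 0), bitDepth > 0)
  bytes <- prod(tileShape) * bitDepth / 8
  bytes / (if (binary) 2^20 else 1e6)
}

#' Raw dataset size in terabytes
#'
#' One reconstructed image per mosaic per channel is stored (the three phase
#' raws are consumed by the reconstruction and not archived), so the dataset
#' holds \code{mosaicsPerChannel * nChannels} tiles.
#'
#' @param mosaicsPerChannel mosaic count in each channel.
#' @param nChannels number of channels (3).
#' @param tileShape,bitDepth tile format.
#' @param binary use 2^40-byte terabytes (default).
#' @return Size in TB (full precision).
#' @examples
#' round(datasetSizeTb(858701), 1)  # 15.2
#' round(datasetSizeTb(546310), 1)  # 9.7
#' @export
datasetSizeTb <- function(mosaicsPerChannel, nChannels = 3,
                          tileShape = c(1800, 1800), bitDepth = 16,
                          binary = TRUE) {
  stopifnot(mosaicsPerChannel >= 0, nChannels > 0)
  bytes <- mosaicsPerChannel * nChannels * prod(tileShape) * bitDepth / 8
  bytes / (if (binary) 2^40 else 1e12)
}

#' Whole-brain imaging time in hours
#'
#' The three channels are acquired simultaneously, so the per-channel mosaic
#' count (not the channel-summed count) multiplies the per-mosaic time.
#' Sectioning time is not included.
#'
#' @param mosaicsPerChannel mosaic count in each channel.
#' @param perMosaicTimeMs per-mosaic imaging time, milliseconds (342.5).
#' @return Hours (full precision).
#' @examples
#' round(imagingTimeH(858701), 1)  # 81.7
#' round(imagingTimeH(546310), 1)  # 52.0
#' @export
imagingTimeH <- function(mosaicsPerChannel, perMosaicTimeMs = 342.5) {
  stopifnot(mosaicsPerChannel >= 0, perMosaicTimeMs > 0)
  mosaicsPerChannel * perMosaicTimeMs / 3.6e6
}

#' Camera-exposure and DMD-flip reduction from contour recognition
#'
#' Each mosaic costs one camera exposure and one DMD flip per phase, so the
#' per-camera saving is \code{phases x (mosaics_without - mosaics_with)}.
#'
#' @param mosaicsWithout,mosaicsWith per-channel mosaic counts without/with
#'   automatic contour recognition.
#' @param phasesPerMosaic phases per mosaic (3).
#' @return Count of exposures (= DMD flips) saved per camera.
#' @examples
#' exposureReduction(858701, 546310)  # 937173
#' @export
exposureReduction <- function(mosaicsWithout, mosaicsWith,
                              phasesPerMosaic = 3) {
  if (mosaicsWithout < mosaicsWith)
    wvtStop("mosaicsWithout must be >= mosaicsWith", "wvtInputError")
  phasesPerMosaic * (mosaicsWithout - mosaicsWith)
}

#' Summarize a whole-brain acquisition plan
#'
#' Combines the per-layer planned regions with the accounting constants into
#' totals: mosaics with and without recognition, tile/dataset sizes, imaging
#' times, exposure savings. The reduction percentage is reported under both
#' aggregation modes -- the ratio of the totals and the mean of the per-layer
#' ratios -- because the two differ whenever layer sizes vary.
#'
#' @param plan result of \code{\link{planWholeBrain}}, or a data.frame with
#'   columns n_mosaics and n_fixed.
#' @param acct an \linkS4class{AcquisitionAccounting}.
#' @return A list report (counts, sizes in MB/TB, times in h, reductions in
#'   percent, and the per-layer table).
#' @export
summarizePlan <- function(plan, acct = AcquisitionAccounting()) {
  perLayer <- if (is.data.frame(plan)) plan else plan$perLayer
  withN <- sum(perLayer$n_mosaics)
  withoutN <- sum(perLayer$n_fixed)
  perLayerRatio <- 100 * (1 - perLayer$n_mosaics / perLayer$n_fixed)
  list(
    layers = nrow(perLayer),
    mosaics_with = withN,
    mosaics_without = withoutN,
    reduction_pct_totals = 100 * (1 - withN / withoutN),
    reduction_pct_mean_per_layer = mean(perLayerRatio),
    tile_size_mb = tileSizeMb(acct@tileShape, acct@bitDepth),
    dataset_tb_with = datasetSizeTb(withN, acct@nChannels, acct@tileShape,
                                    acct@bitDepth),
    dataset_tb_without = datasetSizeTb(withoutN, acct@nChannels,
                                       acct@tileShape, acct@bitDepth),
    imaging_h_with = imagingTimeH(withN, acct@perMosaicTimeMs),
    imaging_h_without = imagingTimeH(withoutN, acct@perMosaicTimeMs),
    exposure_reduction = exposureReduction(withoutN, withN,
                                           acct@phasesPerMosaic),
    per_layer = perLayer
  )
}
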