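#' Run the full pipeline end to end on a synthetic phantom
#'
#' Demonstration orchestration over the package's modules: generates a
#' phantom brain, round-trips one field of view through structured-
#' illumination modulation and SIM/WF reconstruction, estimates and applies
#' the chromatic registration on a ring target with an injected misalignment,
#' recognizes contours and plans the per-layer imaging regions, produces the
#' acquisition accounting, and runs soma co-location plus atlas-region
#' quantification against the generator's ground truth. Intended for a small
#' desk-scale configuration; all stages log start/end with timestamps.
#'
#' @param config a \code{\link{wvtConfig}}.
#' @param outDir optional directory: stage outputs (TIFF, JSON, SWC, CSV) are
#'   written there.
#' @param phantom optional \linkS4class{PhantomSpec} (default: a reduced
#'   3-layer phantom derived from \code{config$seed}).
#' @param dryRun print the stage plan and return it without computing.
#' @param verbose emit per-stage log messages.
#' @return Invisible list of per-stage reports.
#' @export
runPipeline <- function(config = wvtConfig(), outDir = NULL, phantom = NULL,
                        dryRun = FALSE, verbose = TRUE) {
  stages <- c("simulate", "reconstruct", "register", "contour+plan",
              "account", "coloc+quantify")
  if (dryRun) {
    message("pipeline plan: ", paste(stages, collapse = " -> "),
            " (dry run, nothing written)")
    return(invisible(list(plan = stages)))
  }
  log <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%OS1 "), sprintf(...))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  seed <- as.integer(config$seed)
  if (is.null(phantom))
    phantom <- phantomSpec(nLayers = 3L, imageSizePx = 768L,
                           nGreen = 2000L, nRed = 1800L, seed = seed)
  log("simulate: phantom brain (%d layers, seed %d)", phantom@nLayers, seed)
  ph <- generatePhantom(phantom)

  log("reconstruct: SIM/WF round trip on one synthetic FOV")
  scene <- withSeed(seed, matrix(stats::runif(128 * 128, 50, 500), 128, 128))
  trip <- modulateTriplet(scene, periodUm = 4, phase0 = 0.3,
                          modulationDepth = 0.8,
                          pixelSize = config$voxel_size_um[1])
  simTile <- reconstructFov(trip, scheme = unlist(config$channel_modes))
  maxRel <- max(abs(tilePixels(simTile) - 0.8 * scene / 2) /
                  (0.8 * scene / 2))
  recon <- list(mode = tileMode(simTile), max_rel_error = maxRel)
  log("reconstruct: %s amplitude recovery max rel err %.2e", recon$mode,
      maxRel)

  log("register: ring target with injected misalignment")
  px <- config$voxel_size_um[1]
  ring <- makeRingTarget(sizePx = 192, pixelSize = px)
  inj <- withSeed(seed + 1, SimilarityTransform2D(
    dx = stats::runif(1, -2, 2) * px, dy = stats::runif(1, -2, 2) * px,
    rotation = stats::runif(1, -0.3, 0.3),
    scale = 1 + stats::runif(1, -0.004, 0.004)))
  moved <- applyTransform(ring, inj, px)
  est <- estimateTransform(ring, moved, pixelSize = px, maxShiftPx = 5,
                           maxRotDeg = 0.5, maxScaleDev = 0.006)
  corrected <- applyTransform(moved, est, px)
  err <- measureColocationError(ring, corrected, window = 64, pixelSize = px)
  reg <- list(injected = inj, estimated = est,
              max_residual_um = max(err@residuals, na.rm = TRUE))
  log("register: max residual %.3f um (1 px = %.2f um)",
      reg$max_residual_um, px)
  if (!is.null(outDir)) writeTransform(est, file.path(outDir,
                                                      "transform_demo.json"))

  log("contour+plan: %d layers", phantom@nLayers)
  spec <- MosaicSpec(fovSide = config$fov_side_um,
                     overlap = config$overlap_um)
  params <- ContourParams(
    recognitionPixelSize = config$recognition_pixel_size_um)
  plan <- planWholeBrain(lapply(ph$layers, `[[`, "dapi"), spec, params,
                         margin = config$margin_um)
  log("contour+plan: %d mosaics with recognition, %d fixed",
      sum(plan$perLayer$n_mosaics), sum(plan$perLayer$n_fixed))

  acct <- AcquisitionAccounting(
    tileShape = config$tile_shape_px, bitDepth = config$bit_depth,
    nChannels = config$n_channels,
    phasesPerMosaic = config$phases_per_mosaic,
    perMosaicTimeMs = config$per_mosaic_time_ms)
  account <- summarizePlan(plan, acct)
  log("account: reduction %.1f%% (ratio of totals)",
      account$reduction_pct_totals)

  log("coloc+quantify: %d green, %d red somas", nSomas(ph$truth$green),
      nSomas(ph$truth$red))
  pairs <- colocate(ph$truth$green, ph$truth$red,
                    threshold = config$coloc_threshold_um)
  props <- colocProportions(pairs, ph$truth$green, ph$truth$red)
  report <- countByRegion(ph$truth$green, ph$truth$atlas, level = "region")
  if (!is.null(outDir)) {
    writeSwc(ph$truth$green, file.path(outDir, "somas_green.swc"))
    writeSwc(ph$truth$red, file.path(outDir, "somas_red.swc"))
    writeRegionReport(report, file.path(outDir, "regions_green.csv"))
    exportReviewCandidates(pairs, ph$truth$green, ph$truth$red,
                           file.path(outDir, "coloc_review.csv"))
  }
  log("coloc+quantify: %d pairs (%.3f%% of green)", nrow(colocPairs(pairs)),
      props[["pct_of_green"]])
  invisible(list(phantom = ph$truth, reconstruction = recon,
                 registration = reg, plan = plan, accounting = account,
                 coloc = list(pairs = pairs, proportions = props),
                 regions = report))
}
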