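#' Pipeline configuration with the instrument's defaults
#'
#' Every constant of the acquisition lives here, never hard-coded in module
#' logic: voxel size 0.32 x 0.32 x 2 um, 576 um FOV with 5 um overlap, 288 um
#' planning margin (half the FOV), 1.68 um/px recognition resolution, 1 um
#' co-location threshold, 342.5 ms per mosaic, and the optimized per-channel
#' reconstruction scheme (SIM for green/red, WF for blue). Units are
#' micrometres and milliseconds throughout.
#'
#' @param ... overrides of the defaults (unknown names raise a config error).
#' @return A named list of class \code{wvtConfig}.
#' @export
wvtConfig <- function(...) {
  cfg <- list(
    voxel_size_um = c(0.32, 0.32, 2),
    fov_side_um = 576,
    overlap_um = 5,
    margin_um = 288,
    recognition_pixel_size_um = 1.68,
    coloc_threshold_um = 1.0,
    per_mosaic_time_ms = 342.5,
    tile_shape_px = c(1800, 1800),
    bit_depth = 16,
    n_channels = 3,
    phases_per_mosaic = 3,
    channel_modes = list(blue = "WF", green = "SIM", red = "SIM"),
    detection_voxel_um = c(1, 1, 2),
    axial_chromatic_separation_um = 10,
    gdp_offset_um = 4,
    crosstalk_free_depth_um = 4,
    paths = list(),
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    wvtStop(paste("unknown configuration field(s):",
                  paste(bad, collapse = ", ")), "wvtConfigError")
  cfg[names(over)] <- over
  structure(cfg, class = "wvtConfig")
}

#' @rdname wvtConfig
#' @param config a \code{wvtConfig}.
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname wvtConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(wvtConfig, raw)
  validateConfig(cfg)
  cfg
}

#' @rdname wvtConfig
#' @export
validateConfig <- function(config) {
  with(config, {
    if (any(voxel_size_um <= 0) || fov_side_um <= 0 ||
        recognition_pixel_size_um <= 0)
      wvtStop("sizes must be positive", "wvtConfigError")
    if (overlap_um < 0 || overlap_um >= fov_side_um)
      wvtStop("overlap must satisfy 0 <= overlap < fov side",
              "wvtConfigError")
    if (margin_um < 0)
      wvtStop("margin must be non-negative", "wvtConfigError")
    if (!all(unlist(channel_modes) %in% c("SIM", "WF")))
      wvtStop("channel modes must be SIM or WF", "wvtConfigError")
  })
  invisible(config)
}
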