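# Shared fixture builders; everything is generated in code at test time.

# n random 3D points in [lo, hi]^3 (um) with a minimum mutual separation
placeSeparatedPoints <- function(n, lo, hi, minSep) {
  pts <- matrix(NA_real_, 0, 3)
  guard <- 0
  while (nrow(pts) < n) {
    p <- stats::runif(3, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((t(t(pts)) - matrix(p, nrow(pts), 3,
                                             byrow = TRUE))^2))) >= minSep)
      pts <- rbind(pts, p)
    guard <- guard + 1
    if (guard > 50000) stop("fixture placement failed")
  }
  pts
}

# Minimal hand-built atlas: 3 parent bands along x, each split in y into two
# sub-regions; cube of `nv` voxels per side at voxel `vox` um.
tinyAtlas <- function(nv = 30, vox = 10) {
  lab <- array(0L, dim = c(nv, nv, nv))
  xIdx <- slice.index(lab, 2)  # column = x
  yIdx <- slice.index(lab, 1)
  par <- 1L + (xIdx > nv / 3) + (xIdx > 2 * nv / 3)
  lab[] <- par * 10L + ifelse(yIdx <= nv / 2, 1L, 2L)
  hier <- do.call(rbind, lapply(1:3, function(p)
    data.frame(id = p * 10L + 1:2, name = paste0("R", p, c("a", "b")),
               parent_id = p, parent_name = paste0("R", p))))
  AtlasVolume(lab, voxelSize = rep(vox, 3), hierarchy = hier)
}

# Independent 1D covering oracle: smallest contiguous run of lattice cells
# (cell i covers [i*stride, i*stride + fov]) containing [lo, hi], found by
# exhaustive enumeration of candidate runs.
bruteSpan1d <- function(lo, hi, fov, stride, origin = 0) {
  cand <- -50:100
  best <- NULL
  for (i0 in cand) for (i1 in i0:(i0 + 60)) {
    if (origin + i0 * stride <= lo && origin + i1 * stride + fov >= hi) {
      if (is.null(best) || (i1 - i0) < (best[2] - best[1])) best <- c(i0, i1)
      break
    }
  }
  best
}

# Lattice coverage interval of an ImagingRegion along x / y
regionCoverage <- function(region, spec) {
  stride <- mosaicStride(spec)
  list(x = c(spec@originX + region@col0 * stride,
             spec@originX + region@col1 * stride + spec@fovSide),
       y = c(spec@originY + region@row0 * stride,
             spec@originY + region@row1 * stride + spec@fovSide))
}
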