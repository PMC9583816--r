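#' Construct a soma set
#'
#' @param coords numeric matrix (n x 3) of (x, y, z) in micrometres.
#' @param intensity optional detection intensities.
#' @param ids integer ids, unique; default 1..n.
#' @param channel,brainId labels.
#' @param voxelSize voxel size used for detection (1 x 1 x 2 um).
#' @return A \linkS4class{SomaSet} sorted by id.
#' @export
SomaSet <- function(coords, intensity = NULL, ids = NULL, channel = "green",
                    brainId = "brain", voxelSize = c(1, 1, 2)) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (is.null(ids)) ids <- seq_len(n)
  if (is.null(intensity)) intensity <- rep(NA_real_, n)
  ord <- order(ids)
  new("SomaSet", coords = coords[ord, , drop = FALSE],
      intensity = intensity[ord], ids = as.integer(ids[ord]),
      channel = channel, brainId = brainId, voxelSize = voxelSize)
}

#' @rdname SomaSet
#' @param set a \code{SomaSet}.
#' @export
somaCoords <- function(set) set@coords

#' @rdname SomaSet
#' @export
nSomas <- function(set) nrow(set@coords)

setMethod("show", "SomaSet", function(object) {
  cat(sprintf("SomaSet [%s/%s]: %d somas\n", object@brainId, object@channel,
              nSomas(object)))
})

#' Construct an atlas volume
#'
#' @param labels integer 3D array of region labels (0 = background).
#' @param voxelSize numeric length 3, micrometres.
#' @param hierarchy data.frame with columns id, name, parent_id, parent_name.
#' @param origin micrometre coordinate of the low corner of voxel (1,1,1)
#'   (voxel i spans \code{[origin + (i-1) vx, origin + i vx)}).
#' @return An \linkS4class{AtlasVolume}.
#' @export
AtlasVolume <- function(labels, voxelSize, hierarchy, origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("AtlasVolume", labels = labels, voxelSize = voxelSize,
      hierarchy = hierarchy, origin = origin)
}

setMethod("show", "AtlasVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "AtlasVolume: %d x %d x %d voxels at %g x %g x %g um, %d sub-regions in %d regions\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], nrow(object@hierarchy),
    length(unique(object@hierarchy$parent_id))))
})

#' Detect somas in a 3D volume by block-wise blob detection
#'
#' Plumbing stand-in for an external soma-localization tool: the volume is
#' processed in blocks (default 512 x 512 x 512 voxels at 1 x 1 x 2 um) with a
#' halo, each block is Gaussian-smoothed at the soma scale and strict local
#' maxima above an adaptive threshold are taken as soma centres; duplicate
#' detections inside halos are merged within a 3 um radius (brightest kept).
#'
#' @param volume numeric 3D array \code{[y, x, z]}.
#' @param voxelSize numeric length 3, (x, y, z) micrometres (1, 1, 2).
#' @param blockShape block size in voxels (512^3).
#' @param haloVox halo width in voxels (16).
#' @param sigmaUm Gaussian scale of the detector, micrometres (soma scale, 4).
#' @param thresholdK maxima must exceed median + thresholdK * mad of their
#'   block (default 6).
#' @param mergeRadiusUm duplicate-merge radius, micrometres (3).
#' @param channel,brainId labels for the result.
#' @return A \linkS4class{SomaSet} (empty for an empty volume).
#' @export
detectSomas <- function(volume, voxelSize = c(1, 1, 2),
                        blockShape = c(512L, 512L, 512L), haloVox = 16L,
                        sigmaUm = 4, thresholdK = 6, mergeRadiusUm = 3,
                        channel = "green", brainId = "brain") {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  sigmaVox <- sigmaUm / voxelSize[c(2, 1, 3)]  # dims are (y, x, z)
  starts <- function(n, b) if (n <= b) 1L else seq(1L, n, by = b)
  coords <- matrix(numeric(0), 0, 3)
  intens <- numeric(0)
  for (z0 in starts(d[3], blockShape[3]))
    for (x0 in starts(d[2], blockShape[1]))
      for (y0 in starts(d[1], blockShape[2])) {
        y1 <- min(y0 + blockShape[2] - 1L, d[1])
        x1 <- min(x0 + blockShape[1] - 1L, d[2])
        z1 <- min(z0 + blockShape[3] - 1L, d[3])
        ys <- max(1L, y0 - haloVox):min(d[1], y1 + haloVox)
        xs <- max(1L, x0 - haloVox):min(d[2], x1 + haloVox)
        zs <- max(1L, z0 - haloVox):min(d[3], z1 + haloVox)
        blk <- volume[ys, xs, zs, drop = FALSE]
        if (all(blk == 0)) next
        sm <- gaussSmooth3d(blk, sigmaVox)
        thr <- stats::median(sm) + thresholdK * stats::mad(sm)
        lm <- localMaxima3d(sm, thr)
        if (!any(lm)) next
        idx <- which(lm, arr.ind = TRUE)
        # global voxel indices -> um (0-based voxel centres)
        gx <- (xs[idx[, 2]] - 1) * voxelSize[1]
        gy <- (ys[idx[, 1]] - 1) * voxelSize[2]
        gz <- (zs[idx[, 3]] - 1) * voxelSize[3]
        coords <- rbind(coords, cbind(gx, gy, gz))
        intens <- c(intens, sm[lm])
      }
  if (nrow(coords) == 0)
    return(SomaSet(matrix(numeric(0), 0, 3), channel = channel,
                   brainId = brainId, voxelSize = voxelSize))
  keep <- dedupPoints(coords, intens, mergeRadiusUm)
  SomaSet(coords[keep, , drop = FALSE], intensity = intens[keep],
          channel = channel, brainId = brainId, voxelSize = voxelSize)
}

# All green-red index pairs with 3D distance strictly below `threshold`,
# found via uniform-cell hashing (cell side = threshold). Vectorized over the
# 27 neighbouring-cell offsets: red points are grouped by integer cell key,
# each offset joins every green point against one red group at once.
.crossPairsWithin <- function(g, r, threshold) {
  if (nrow(g) == 0 || nrow(r) == 0)
    return(data.frame(gi = integer(), ri = integer(), d = numeric()))
  cellOf <- function(m) cbind(floor(m[, 1] / threshold),
                              floor(m[, 2] / threshold),
                              floor(m[, 3] / threshold))
  rc <- cellOf(r); gc <- cellOf(g)
  lo <- pmin(apply(rc, 2, min), apply(gc, 2, min)) - 1
  spanY <- max(rc[, 2], gc[, 2]) - lo[2] + 3
  spanZ <- max(rc[, 3], gc[, 3]) - lo[3] + 3
  keyOf <- function(cc) (cc[, 1] - lo[1]) * spanY * spanZ +
    (cc[, 2] - lo[2]) * spanZ + (cc[, 3] - lo[3])
  rkey <- keyOf(rc)
  rord <- order(rkey)
  rs <- rkey[rord]
  uk <- unique(rs)
  grpStart <- match(uk, rs)
  grpLen <- c(diff(grpStart), length(rs) - grpStart[length(uk)] + 1L)
  gkey0 <- keyOf(gc)
  res <- vector("list", 27)
  ii <- 0
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    ii <- ii + 1
    gk <- gkey0 + ox * spanY * spanZ + oy * spanZ + oz
    gidx <- match(gk, uk)
    hit <- which(!is.na(gidx))
    if (!length(hit)) next
    gg <- gidx[hit]
    gi <- rep(hit, grpLen[gg])
    ri <- rord[sequence(grpLen[gg], from = grpStart[gg])]
    d <- sqrt((r[ri, 1] - g[gi, 1])^2 + (r[ri, 2] - g[gi, 2])^2 +
              (r[ri, 3] - g[gi, 3])^2)
    sel <- d < threshold
    if (any(sel))
      res[[ii]] <- data.frame(gi = gi[sel], ri = ri[sel], d = d[sel])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    data.frame(gi = integer(), ri = integer(), d = numeric())
  else out
}

#' Identify co-located somas between the green and red channels
#'
#' A green and a red soma are one co-located (doubly labelled) neuron when
#' their 3D Euclidean distance is strictly below the threshold (1 um) and the
#' match is mutual-nearest-neighbour: each soma is the other's nearest
#' counterpart. The mutuality requirement keeps the pairing one-to-one (no
#' soma can be claimed by two partners), which a manual proofread would also
#' enforce. Distances are computed in micrometres, so voxel anisotropy is
#' absorbed upstream at detection.
#'
#' @param green,red \linkS4class{SomaSet}s of the same brain in the same
#'   coordinate frame.
#' @param threshold pairing threshold, micrometres (strict less-than, 1.0).
#' @return A \linkS4class{ColocatedPairs}.
#' @examples
#' g <- SomaSet(rbind(c(0, 0, 0)))
#' r <- SomaSet(rbind(c(0.5, 0, 0)), channel = "red")
#' nrow(colocPairs(colocate(g, r)))  # 1
#' @export
colocate <- function(green, red, threshold = 1.0) {
  cand <- .crossPairsWithin(green@coords, red@coords, threshold)
  if (nrow(cand) == 0)
    return(new("ColocatedPairs",
               pairs = data.frame(green_id = integer(), red_id = integer(),
                                  distance = numeric()),
               threshold = threshold))
  # nearest red per green and nearest green per red (within threshold; any
  # partner at or beyond threshold can never pair, and any nearer partner
  # below threshold is in `cand`)
  bestR <- tapply(seq_len(nrow(cand)), cand$gi, function(ix)
    ix[which.min(cand$d[ix])])
  bestG <- tapply(seq_len(nrow(cand)), cand$ri, function(ix)
    ix[which.min(cand$d[ix])])
  mutual <- intersect(unlist(bestR), unlist(bestG))
  p <- cand[mutual, , drop = FALSE]
  p <- p[order(p$gi), , drop = FALSE]
  new("ColocatedPairs",
      pairs = data.frame(green_id = green@ids[p$gi],
                         red_id = red@ids[p$ri], distance = p$d),
      threshold = threshold)
}

#' @rdname colocate
#' @param pairs a \code{ColocatedPairs}.
#' @export
colocPairs <- function(pairs) pairs@pairs

setMethod("show", "ColocatedPairs", function(object) {
  cat(sprintf("ColocatedPairs: %d pairs (distance < %g um)\n",
              nrow(object@pairs), object@threshold))
})

#' Count somas per atlas region
#'
#' Each soma is assigned the label of its containing voxel
#' (floor-to-voxel convention: a coordinate exactly on a voxel boundary
#' belongs to the higher voxel, deterministically), optionally rolled up from
#' sub-regions to their parent regions. Somas landing on label 0 are counted
#' in an "unassigned" bin with a warning. Proportions are percentages of the
#' total soma count, so they sum to 100 over the (exhaustive, disjoint)
#' report rows.
#'
#' @param somas a \linkS4class{SomaSet}.
#' @param atlas an \linkS4class{AtlasVolume}.
#' @param level "subregion" counts per label, "region" rolls labels up to
#'   parents.
#' @return A \linkS4class{RegionReport}.
#' @export
countByRegion <- function(somas, atlas, level = c("region", "subregion")) {
  level <- match.arg(level)
  co <- somas@coords
  n <- nrow(co)
  d <- dim(atlas@labels)
  vx <- atlas@voxelSize
  # voxel i spans [origin + (i-1) vx, origin + i vx): floor-to-voxel
  ix <- floor((co[, 1] - atlas@origin[1]) / vx[1]) + 1L
  iy <- floor((co[, 2] - atlas@origin[2]) / vx[2]) + 1L
  iz <- floor((co[, 3] - atlas@origin[3]) / vx[3]) + 1L
  inb <- ix >= 1 & ix <= d[2] & iy >= 1 & iy <= d[1] & iz >= 1 & iz <= d[3]
  lab <- rep(0L, n)
  lab[inb] <- atlas@labels[cbind(iy[inb], ix[inb], iz[inb])]
  if (any(lab == 0L))
    warning(sprintf("%d soma(s) outside any labelled region: %s",
                    sum(lab == 0L), "counted as unassigned"))
  hier <- atlas@hierarchy
  if (level == "region") {
    map <- stats::setNames(hier$parent_id, hier$id)
    nameOf <- stats::setNames(hier$parent_name, hier$parent_id)
    rlab <- ifelse(lab == 0L, 0L, unname(map[as.character(lab)]))
    allIds <- sort(unique(hier$parent_id))
  } else {
    nameOf <- stats::setNames(hier$name, hier$id)
    rlab <- lab
    allIds <- sort(unique(hier$id))
  }
  counts <- vapply(allIds, function(id) sum(rlab == id), integer(1))
  tab <- data.frame(
    region_id = allIds,
    region_name = unname(nameOf[as.character(allIds)]),
    level = level,
    count = counts,
    proportion_pct = if (n > 0) 100 * counts / n else rep(NA_real_,
                                                          length(counts))
  )
  flags <- character()
  if (any(rlab == 0L)) {
    tab <- rbind(tab, data.frame(
      region_id = 0L, region_name = "unassigned", level = level,
      count = sum(rlab == 0L),
      proportion_pct = 100 * sum(rlab == 0L) / n))
    flags <- "unassigned-somas"
  }
  new("RegionReport", table = tab, level = level, nBrains = 1L,
      totalSomas = as.integer(n), flags = flags)
}

#' @rdname countByRegion
#' @param report a \code{RegionReport}.
#' @export
regionTable <- function(report) report@table

setMethod("show", "RegionReport", function(object) {
  cat(sprintf("RegionReport (%s level, %d brain%s):\n", object@level,
              object@nBrains, ifelse(object@nBrains > 1, "s", "")))
  print(object@table, row.names = FALSE)
})

#' Aggregate per-brain region reports into mean +/- s.e.m.
#'
#' @param reports list of single-brain \linkS4class{RegionReport}s at the same
#'   level. A region missing from one brain is treated as 0\% for that brain.
#' @return A \linkS4class{RegionReport} whose table carries mean_pct and
#'   sem_pct (s.e.m. = sd / sqrt(n)); with a single brain the s.e.m. is 0 and
#'   flagged.
#' @export
aggregateBrains <- function(reports) {
  stopifnot(length(reports) >= 1)
  lev <- unique(vapply(reports, function(r) r@level, character(1)))
  if (length(lev) != 1)
    wvtStop("reports must share the hierarchy level", "wvtInputError")
  ids <- sort(unique(unlist(lapply(reports, function(r) r@table$region_id))))
  nameOf <- do.call(rbind, lapply(reports, function(r)
    r@table[, c("region_id", "region_name")]))
  nameOf <- nameOf[!duplicated(nameOf$region_id), ]
  nm <- stats::setNames(nameOf$region_name, nameOf$region_id)
  n <- length(reports)
  mat <- vapply(reports, function(r) {
    v <- stats::setNames(r@table$proportion_pct, r@table$region_id)
    out <- rep(0, length(ids))
    hit <- as.character(ids) %in% names(v)
    out[hit] <- v[as.character(ids)[hit]]
    out
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  meanP <- rowMeans(mat)
  semP <- if (n > 1) apply(mat, 1, stats::sd) / sqrt(n) else rep(0, length(ids))
  tab <- data.frame(
    region_id = ids, region_name = unname(nm[as.character(ids)]),
    level = lev, count = NA_integer_, proportion_pct = meanP,
    mean_pct = meanP, sem_pct = semP)
  flags <- if (n == 1) "n=1-sem-zero" else character()
  new("RegionReport", table = tab, level = lev, nBrains = as.integer(n),
      totalSomas = NA_integer_, flags = flags)
}

#' Proportion of co-located somas relative to each channel
#'
#' @param pairs a \linkS4class{ColocatedPairs} derived from the given sets.
#' @param green,red the \linkS4class{SomaSet}s used for pairing.
#' @return Named numeric: \code{pct_of_green} and \code{pct_of_red}, each
#'   100 x n_pairs / n_channel. An empty channel yields NaN with a warning.
#' @export
colocProportions <- function(pairs, green, red) {
  np <- nrow(pairs@pairs)
  ng <- nSomas(green); nr <- nSomas(red)
  if (ng == 0 || nr == 0)
    warning("empty soma set: co-location proportion undefined (NaN)")
  c(pct_of_green = if (ng > 0) 100 * np / ng else NaN,
    pct_of_red = if (nr > 0) 100 * np / nr else NaN)
}

#' Export co-location candidates for manual review
#'
#' The instrument workflow proofreads all automatic co-location calls; this
#' writes the candidate list as CSV (one row per pair with both coordinates
#' and the distance) for external review.
#'
#' @param pairs a \linkS4class{ColocatedPairs}.
#' @param green,red the soma sets.
#' @param path CSV output path.
#' @export
exportReviewCandidates <- function(pairs, green, red, path) {
  p <- pairs@pairs
  gi <- match(p$green_id, green@ids)
  ri <- match(p$red_id, red@ids)
  df <- data.frame(
    green_id = p$green_id, red_id = p$red_id,
    gx = green@coords[gi, 1], gy = green@coords[gi, 2],
    gz = green@coords[gi, 3],
    rx = red@coords[ri, 1], ry = red@coords[ri, 2], rz = red@coords[ri, 3],
    distance_um = p$distance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a region report as CSV
#'
#' @param report a \linkS4class{RegionReport}.
#' @param path CSV output path.
#' @export
writeRegionReport <- function(report, path) {
  utils::write.csv(report@table, path, row.names = FALSE)
  invisible(path)
}
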