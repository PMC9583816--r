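#' Read / write 16-bit grayscale TIFF images
#'
#' Images travel the pipeline as integer matrices in 0..65535. Multi-page
#' stacks are lists of matrices (read) or written page by page, order
#' preserved. Pixel size and other acquisition metadata live in a JSON
#' sidecar (\code{<path>.json}) because baseline TIFF has no reliable slot
#' for them; the write-then-read round trip is bit-identical.
#'
#' @param path TIFF file path.
#' @param all read all pages (returns a list) or only the first.
#' @return Integer matrix (or list of matrices), with the sidecar metadata
#'   attached as attribute \code{"meta"} when present.
#' @export
readTiff16 <- function(path, all = FALSE) {
  img <- tiff::readTIFF(path, all = all, as.is = TRUE)
  checkOne <- function(m) {
    if (length(dim(m)) != 2)
      wvtStop("only single-channel grayscale TIFF is supported",
              "wvtFormatError")
    m
  }
  out <- if (all) lapply(img, checkOne) else checkOne(img)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(out, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  out
}

#' @rdname readTiff16
#' @param image integer matrix in 0..65535, or a list of such matrices for a
#'   multi-page stack.
#' @param meta optional named list written to the JSON sidecar (e.g.
#'   pixel_size_um, channel, mode, scale).
#' @export
writeTiff16 <- function(image, path, meta = NULL) {
  pages <- if (is.list(image)) image else list(image)
  for (m in pages) {
    if (length(dim(m)) != 2)
      wvtStop("only single-channel grayscale images can be written",
              "wvtFormatError")
    if (min(m) < 0 || max(m) > 65535)
      wvtStop("pixel values must lie in 0..65535 for 16-bit storage",
              "wvtFormatError")
  }
  norm <- lapply(pages, function(m) round(m) / 65535)
  tiff::writeTIFF(if (is.list(image)) norm else norm[[1]], path,
                  bits.per.sample = 16L, compression = "none")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read an SWC soma file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent); somas carry
#' parent -1. Comment lines (#) are tolerated and returned in the
#' \code{"comments"} attribute. A malformed row raises a parse error naming
#' the line.
#'
#' @param path SWC file path.
#' @param channel,brainId labels for the resulting set.
#' @return A \linkS4class{SomaSet} (radius preserved in attribute
#'   \code{"radius"}).
#' @export
readSwc <- function(path, channel = "green", brainId = "brain") {
  lines <- readLines(path)
  isComment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  comments <- lines[grepl("^\\s*#", lines)]
  rows <- which(!isComment)
  if (length(rows) == 0) {
    out <- SomaSet(matrix(numeric(0), 0, 3), channel = channel,
                   brainId = brainId)
    attr(out, "comments") <- comments
    return(out)
  }
  parsed <- matrix(NA_real_, length(rows), 7)
  for (i in seq_along(rows)) {
    f <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 7 || anyNA(v))
      wvtStop(sprintf("malformed SWC row at line %d: expected 7 numeric %s",
                      rows[i], "columns"), "wvtParseError")
    parsed[i, ] <- v
  }
  out <- SomaSet(parsed[, 3:5, drop = FALSE], ids = as.integer(parsed[, 1]),
                 channel = channel, brainId = brainId)
  ord <- order(as.integer(parsed[, 1]))
  attr(out, "radius") <- parsed[ord, 6]
  attr(out, "comments") <- comments
  out
}

#' @rdname readSwc
#' @param set a \linkS4class{SomaSet}.
#' @param radius soma radius column (micrometres), recycled.
#' @param comments extra comment lines (without the leading #).
#' @export
writeSwc <- function(set, path, radius = 5, comments = character()) {
  n <- nSomas(set)
  hdr <- c(
    sprintf("# SWC soma export (%s channel, %s)", set@channel, set@brainId),
    "# columns: id type x y z radius parent (um; parent -1 = soma point)",
    paste0("# ", comments)[length(comments) > 0]
  )
  radius <- rep(radius, length.out = n)
  body <- sprintf("%d 1 %.6f %.6f %.6f %.6f -1", set@ids,
                  set@coords[, 1], set@coords[, 2], set@coords[, 3], radius)
  writeLines(c(hdr, body), path)
  invisible(path)
}
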