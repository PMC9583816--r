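# Internal helpers shared across modules. Image matrices follow the
# convention img[row, col] with row <-> y and col <-> x; pixel centres sit at
# 0-based coordinates (x, y) = (col - 1, row - 1) in pixels, times the pixel
# size in micrometres.

wvtStop <- function(msg, class) {
  stop(structure(
    class = c(class, "wvtError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate expr with a locally fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear sampling of img at 0-based pixel coordinates (x, y); out-of-bounds
# samples return `fill`. x and y are equal-length vectors.
bilinearSample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp corner indices; validity tracked separately
  inb <- x0 >= -1 & x0 <= nc - 1 & y0 >= -1 & y0 <= nr - 1
  gx0 <- pmin(pmax(x0, 0), nc - 1); gx1 <- pmin(pmax(x0 + 1, 0), nc - 1)
  gy0 <- pmin(pmax(y0, 0), nr - 1); gy1 <- pmin(pmax(y0 + 1, 0), nr - 1)
  idx <- function(r, c) img[cbind(r + 1, c + 1)]
  v00 <- idx(gy0, gx0); v01 <- idx(gy0, gx1)
  v10 <- idx(gy1, gx0); v11 <- idx(gy1, gx1)
  # zero weight for corners outside the image
  w00 <- (1 - fx) * (1 - fy) * (x0 >= 0) * (y0 >= 0)
  w01 <- fx * (1 - fy) * (x0 + 1 <= nc - 1) * (y0 >= 0)
  w10 <- (1 - fx) * fy * (x0 >= 0) * (y0 + 1 <= nr - 1)
  w11 <- fx * fy * (x0 + 1 <= nc - 1) * (y0 + 1 <= nr - 1)
  out <- v00 * w00 + v01 * w01 + v10 * w10 + v11 * w11
  wsum <- w00 + w01 + w10 + w11
  out[!inb | wsum <= 0] <- fill
  out
}

# Circular cross-correlation of two mean-subtracted matrices via FFT.
# Returns the raw correlation surface with shift (0,0) at [1,1]; surface[i,j]
# is the correlation of b shifted by (dx = j-1, dy = i-1) (modulo size).
fftXcorrSurface <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  fa <- stats::fft(a); fb <- stats::fft(b)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
}

# Integer peak of a circular correlation surface restricted to |shift| <=
# maxShift; returns list(dx, dy, value). Positive dx means b must move right
# to match a.
xcorrPeak <- function(surface, maxShift) {
  nr <- nrow(surface); nc <- ncol(surface)
  sh <- -maxShift:maxShift
  rows <- ((sh) %% nr) + 1
  cols <- ((sh) %% nc) + 1
  sub <- surface[rows, cols, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  list(dy = sh[k[1]], dx = sh[k[2]], value = sub[k[1], k[2]], sub = sub,
       idx = k, shifts = sh)
}

# Sub-pixel refinement of a peak by separable quadratic interpolation.
quadSubpixel <- function(m1, m0, p1) {
  denom <- (m1 - 2 * m0 + p1)
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  d <- 0.5 * (m1 - p1) / denom
  max(min(d, 0.5), -0.5)
}

# Separable Gaussian smoothing of a 3D array (sigma per axis, in voxels),
# replicate padding at the edges. Kernel truncated at 3 sigma.
gaussSmooth3d <- function(v, sigma) {
  d <- dim(v)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    v <- smoothAlong(v, k, ax)
  }
  v
}

smoothAlong <- function(v, k, ax) {
  d <- dim(v)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  vp <- aperm(v, perm)
  dp <- dim(vp)
  n <- dp[1]
  r <- (length(k) - 1L) / 2L
  m <- matrix(vp, nrow = n)
  # replicate-pad along the filtered axis
  padTop <- m[rep(1L, r), , drop = FALSE]
  padBot <- m[rep(n, r), , drop = FALSE]
  mp <- rbind(padTop, m, padBot)
  f <- stats::filter(mp, k, sides = 2)
  f <- f[(r + 1L):(r + n), , drop = FALSE]
  out <- array(as.numeric(f), dim = dp)
  aperm(out, order(perm))
}

# Logical array marking strict-or-tie local maxima of a 3D array over the 26-
# neighbourhood, above a threshold. Border voxels are excluded.
localMaxima3d <- function(v, threshold) {
  d <- dim(v)
  if (any(d < 3)) return(array(FALSE, d))
  core <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  ok <- core > threshold
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- v[(2 + di):(d[1] - 1 + di), (2 + dj):(d[2] - 1 + dj),
            (2 + dk):(d[3] - 1 + dk)]
    ok <- ok & (core >= nb)
    if (!any(ok)) break
  }
  out <- array(FALSE, d)
  out[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- ok
  out
}

# Greedy deduplication of 3D points (um): sort by intensity descending, drop
# any point within `radius` of an already accepted one.
dedupPoints <- function(coords, intensity, radius) {
  n <- nrow(coords)
  if (n <= 1) return(seq_len(n))
  ord <- order(intensity, decreasing = TRUE)
  keep <- logical(n)
  acc <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- coords[i, , drop = FALSE]
    if (nrow(acc)) {
      d2 <- (acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 + (acc[, 3] - p[3])^2
      if (min(d2) < radius^2) next
    }
    keep[i] <- TRUE
    acc <- rbind(acc, p)
  }
  which(keep)
}

fmtNum <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
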