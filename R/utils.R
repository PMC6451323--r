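# Internal array helpers shared across modules. All volumes are numeric
# arrays indexed [z, y, x] with voxel spacing given as (z, y, x) in um.

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# replicating the edge plane. Used by gradients and binary morphology.
.shiftReplicate <- function(x, axis, dir) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + dir
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Shift with constant fill (objects end at the volume border).
.shiftFill <- function(x, axis, dir, fill = 0) {
  d <- dim(x)
  out <- array(fill, dim = d)
  n <- d[axis]
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  if (dir > 0) {
    src[[axis]] <- seq_len(n - 1) + 1L
    dst[[axis]] <- seq_len(n - 1)
  } else {
    src[[axis]] <- seq_len(n - 1)
    dst[[axis]] <- seq_len(n - 1) + 1L
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(x), src, list(drop = FALSE))))))
  out
}

# Central difference along `axis` in voxel units with replicate edges.
.centralDiff <- function(x, axis) {
  (.shiftReplicate(x, axis, +1) - .shiftReplicate(x, axis, -1)) / 2
}

# Separable Gaussian blur of a 3D array; sigma in voxels, scalar or
# per-axis (z, y, x). sigma = 0 along an axis skips that axis.
gaussianBlur3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim = dim(x))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      acc <- acc + k[j] * .shiftN(x, axis, off)
    }
    x <- acc
  }
  x
}

# n-voxel replicate shift (composition of single shifts done directly).
.shiftN <- function(x, axis, n) {
  if (n == 0) return(x)
  d <- dim(x)
  i <- seq_len(d[axis]) + n
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx <- lapply(d, seq_len)
  idx[[axis]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Global Otsu threshold of a numeric vector/array over a 256-level
# histogram of its full range. Returns the threshold value; NA if flat.
otsuThresholdValue <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(NA_real_)
  img <- EBImage::Image(v, dim = c(length(v), 1L))
  EBImage::otsu(img, range = rng, levels = levels)
}

# Binary erosion/dilation with the 6-connected 3D cross (centre + one
# voxel along each axis). Outside the volume counts as background.
binaryErode6 <- function(x) {
  out <- x
  for (axis in 1:3) for (dir in c(-1, 1)) {
    out <- out & .shiftFill(x, axis, dir, fill = FALSE)
  }
  out
}

binaryDilate6 <- function(x) {
  out <- x
  for (axis in 1:3) for (dir in c(-1, 1)) {
    out <- out | .shiftFill(x, axis, dir, fill = FALSE)
  }
  out
}

# Nearest-neighbour index map for resampling one axis of extent n*sp
# to isotropic spacing iso: returns source index per target voxel.
.nnIndexMap <- function(n, sp, iso) {
  extent <- n * sp
  nNew <- max(1L, round(extent / iso))
  centres <- (seq_len(nNew) - 0.5) * extent / nNew
  pmin(pmax(ceiling(centres / sp), 1L), n)
}

# 2D integral-image local sums over all h x w windows (valid placements).
.localWindowSums <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum) # transposed cumulative sum
  cs <- t(cs)
  P <- matrix(0, H + 1, W + 1)
  P[2:(H + 1), 2:(W + 1)] <- cs
  i <- seq_len(H - h + 1)
  j <- seq_len(W - w + 1)
  P[i + h, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
    P[i + h, j, drop = FALSE] + P[i, j, drop = FALSE]
}

.stopIfNot3d <- function(x, what = "volume") {
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stop(what, " must be a 3D array", call. = FALSE)
  invisible(x)
}
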