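# Shared fixtures and independent oracles, all built in code.

# small standard phantom, cached per test run
.phantomCache <- new.env(parent = emptyenv())
smallPhantom <- function(seed = 3, noiseSigma = 0, shape = c(64, 64, 64)) {
  key <- paste(seed, noiseSigma, paste(shape, collapse = "x"), sep = "_")
  if (is.null(.phantomCache[[key]])) {
    .phantomCache[[key]] <- generateVesselPhantom(phantomSpec(
      shape = shape, nVessels = 2, radiusRange = c(6, 9),
      noiseSigma = noiseSigma, seed = seed))
  }
  .phantomCache[[key]]
}

# independent Triangle-threshold oracle: true perpendicular point-to-line
# distance, explicit loops, same long-tail/mirroring convention
triangleOracle <- function(counts) {
  counts <- as.numeric(counts)
  nz <- which(counts > 0)
  if (length(nz) == 1) return(nz[1] - 1L)
  peak <- which.max(counts)
  if ((peak - nz[1]) > (nz[length(nz)] - peak)) {
    return(length(counts) - 1L - triangleOracle(rev(counts)))
  }
  end <- max(nz)
  if (end == peak) return(peak - 1L)
  x1 <- peak; y1 <- counts[peak]
  x2 <- end; y2 <- counts[end]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  bestB <- peak; bestD <- -Inf
  for (b in peak:end) {
    dPerp <- abs((y2 - y1) * b - (x2 - x1) * counts[b] + x2 * y1 - y2 * x1) / len
    if (counts[b] > (y1 + (y2 - y1) * (b - x1) / (x2 - x1)))
      dPerp <- -dPerp # only bins below the line count
    if (dPerp > bestD) { bestD <- dPerp; bestB <- b }
  }
  bestB - 1L
}

# dense minimum-norm least-squares oracle via MASS::ginv
pinvOracle <- function(X, y) {
  as.numeric(MASS::ginv(X) %*% y)
}

# textured frame series translated rigidly by `step` px per frame
rigidSeries <- function(nFrames = 10, step = 3, size = 200, seed = 7) {
  set.seed(seed)
  by <- (size %/% 2):(size %/% 2 + 40)
  tex <- matrix(runif(length(by)^2, 0.5, 1), length(by))
  bg <- matrix(runif(size^2, 0, 0.05), size, size)
  lapply(seq_len(nFrames), function(t) {
    f <- bg
    sh <- step * (t - 1) - step * (nFrames - 1) %/% 2
    f[by + sh, by + sh] <- tex
    f
  })
}

# square polygonal ROI around a bounding box (corners not duplicated)
squareRoi <- function(yRange, xRange, margin = 3, spacing = 5, timepoint = 1L) {
  y0 <- yRange[1] - margin; y1 <- yRange[2] + margin
  x0 <- xRange[1] - margin; x1 <- xRange[2] + margin
  dropLast <- function(m) m[-nrow(m), , drop = FALSE]
  pts <- rbind(
    dropLast(cbind(y0, seq(x0, x1, by = spacing))),
    dropLast(cbind(seq(y0, y1, by = spacing), x1)),
    dropLast(cbind(y1, seq(x1, x0, by = -spacing))),
    dropLast(cbind(seq(y1, y0, by = -spacing), x0)))
  BoundaryRoi(pts, timepoint)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
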