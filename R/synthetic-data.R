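# Synthetic fixtures: tubular two-channel vascular phantoms with ground
# truth, mosaic tile sets with known offsets, and noisy growth series.
# The phantoms emulate the two transgenic markers of the study system:
# an endothelial wall marker producing hollow-tube signal with
# heterogeneous wall intensity (bright nuclei), and a red-blood-cell
# marker producing speckles strictly inside vessel lumina. Image
# formation adds a small point-spread blur and a scattered/out-of-focus
# component, as in real light-sheet data, plus Gaussian read-out noise.

#' Specification of a synthetic vascular phantom
#'
#' @param shape volume shape in voxels (z, y, x).
#' @param voxelSpacing voxel spacing (z, y, x) in micrometres.
#' @param nVessels number of tubular vessels.
#' @param radiusRange (min, max) vessel radius in micrometres.
#' @param wallThickness endothelial wall thickness in micrometres; must be
#'   smaller than the minimal radius.
#' @param wallIntensityRange (lo, hi) per-vessel wall signal amplitude
#'   (arbitrary units).
#' @param nucleusDensity endothelial nuclei per micrometre of centreline.
#' @param rbcDensity red blood cells per cubic micrometre of lumen.
#' @param noiseSigma additive Gaussian noise level (arbitrary units).
#' @param curvature maximal centreline direction change (radians per
#'   micrometre); 0 gives straight tubes.
#' @param psfSigma point-spread blur applied to both channels (um).
#' @param lumenFill luminal background signal (circulating plasma and
#'   out-of-focus blood cells confined to the vessel interior) as a
#'   fraction of the vessel's wall amplitude.
#' @param scatterFraction amplitude of the diffuse scattered-light
#'   component added to the endothelial channel.
#' @param scatterSigma width of the scatter blur (um).
#' @param seed integer seed; all randomness in the generator derives
#'   from it.
#' @return classed list of validated parameters.
#' @export
phantomSpec <- function(shape = c(96, 96, 96), voxelSpacing = c(1, 1, 1),
                        nVessels = 3, radiusRange = c(6, 11),
                        wallThickness = 3, wallIntensityRange = c(120, 240),
                        nucleusDensity = 0.08, rbcDensity = 0.004,
                        noiseSigma = 4, curvature = 0.02,
                        psfSigma = 0.8, lumenFill = 0.35,
                        scatterFraction = 0.1, scatterSigma = 6,
                        seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(voxelSpacing) == 3, all(voxelSpacing > 0),
            nVessels >= 0, length(radiusRange) == 2,
            radiusRange[1] > 0, radiusRange[2] >= radiusRange[1],
            wallThickness > 0, length(wallIntensityRange) == 2,
            nucleusDensity >= 0, rbcDensity >= 0, noiseSigma >= 0,
            curvature >= 0, psfSigma >= 0, lumenFill >= 0,
            scatterFraction >= 0)
  if (wallThickness >= radiusRange[1])
    stop("wallThickness must be smaller than the minimal radius")
  if (radiusRange[2] >= min(shape * voxelSpacing) / 4)
    stop("vessels of the requested radius cannot fit in the volume")
  structure(list(shape = as.integer(shape), voxelSpacing = as.numeric(voxelSpacing),
                 nVessels = as.integer(nVessels), radiusRange = radiusRange,
                 wallThickness = wallThickness,
                 wallIntensityRange = wallIntensityRange,
                 nucleusDensity = nucleusDensity, rbcDensity = rbcDensity,
                 noiseSigma = noiseSigma, curvature = curvature,
                 psfSigma = psfSigma, lumenFill = lumenFill,
                 scatterFraction = scatterFraction,
                 scatterSigma = scatterSigma, seed = as.integer(seed)),
            class = "phantomSpec")
}

# random-walk centreline in physical (z, y, x) um coordinates
.growCenterline <- function(extent, margin, curvature, stepUm) {
  start <- runif(3, margin, extent - margin)
  # random unit direction
  d <- rnorm(3); d <- d / sqrt(sum(d^2))
  pts <- matrix(NA_real_, nrow = 4096, ncol = 3)
  pts[1, ] <- start
  n <- 1L
  maxTurn <- curvature * stepUm
  repeat {
    if (maxTurn > 0) {
      perturb <- rnorm(3, 0, maxTurn)
      d <- d + perturb
      d <- d / sqrt(sum(d^2))
    }
    nxt <- pts[n, ] + d * stepUm
    if (any(nxt < margin) || any(nxt > extent - margin) || n >= nrow(pts)) break
    n <- n + 1L
    pts[n, ] <- nxt
  }
  pts[seq_len(n), , drop = FALSE]
}

# accumulate min distance-to-centreline over local windows around each
# centreline sample; dist and the voxel coordinate grids are in um
.updateDistance <- function(dist, centre, reachUm, spacing) {
  d <- dim(dist)
  lo <- pmax(1L, floor((centre - reachUm) / spacing) + 1L)
  hi <- pmin(d, ceiling((centre + reachUm) / spacing))
  if (any(lo > hi)) return(dist)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  zc <- (zi - 0.5) * spacing[1] - centre[1]
  yc <- (yi - 0.5) * spacing[2] - centre[2]
  xc <- (xi - 0.5) * spacing[3] - centre[3]
  block <- sqrt(outer(outer(zc^2, yc^2, `+`), xc^2, `+`))
  dist[zi, yi, xi] <- pmin(dist[zi, yi, xi], block)
  dist
}

# add an isotropic Gaussian blob (amplitude amp, width sigmaUm) into acc
.addBlob <- function(acc, centre, amp, sigmaUm, spacing) {
  d <- dim(acc)
  reach <- 3 * sigmaUm
  lo <- pmax(1L, floor((centre - reach) / spacing) + 1L)
  hi <- pmin(d, ceiling((centre + reach) / spacing))
  if (any(lo > hi)) return(acc)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  zc <- (zi - 0.5) * spacing[1] - centre[1]
  yc <- (yi - 0.5) * spacing[2] - centre[2]
  xc <- (xi - 0.5) * spacing[3] - centre[3]
  q <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) / (2 * sigmaUm^2)
  acc[zi, yi, xi] <- acc[zi, yi, xi] + amp * exp(-q)
  acc
}

#' Generate a two-channel vascular phantom with ground truth
#'
#' Vessels are tubes around random-walk centrelines with bounded
#' curvature. The endothelial channel is a Gaussian shell of the wall
#' thickness centred at the vessel radius, modulated multiplicatively by
#' bright nucleus blobs along the wall; the RBC channel contains
#' ellipsoidal speckles whose centres lie strictly inside the lumen.
#' Both channels receive a point-spread blur; the endothelial channel
#' additionally a scattered/out-of-focus component; Gaussian noise of
#' \code{noiseSigma} is added last and intensities are clipped at zero.
#' The generator is deterministic for a fixed seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A \linkS4class{PhantomVolume} with truth masks for wall,
#'   lumen and vessel (wall plus lumen).
#' @examples
#' ph <- generateVesselPhantom(phantomSpec(shape = c(32, 32, 32),
#'   nVessels = 1, radiusRange = c(5, 6), seed = 7))
#' ph
#' @export
generateVesselPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$voxelSpacing
  extent <- d * sp
  wt <- spec$wallThickness
  sigmaWall <- wt / 2.355 # shell FWHM equals the wall thickness

  endo <- array(0, dim = d)
  nucField <- array(0, dim = d)
  rbc <- array(0, dim = d)
  wallMask <- array(FALSE, dim = d)
  lumenMask <- array(FALSE, dim = d)
  stepUm <- 0.5 * min(sp)

  for (v in seq_len(spec$nVessels)) {
    r <- runif(1, spec$radiusRange[1], spec$radiusRange[2])
    amp <- runif(1, spec$wallIntensityRange[1], spec$wallIntensityRange[2])
    margin <- r + wt
    line <- NULL
    for (try in 1:25) {
      cand <- .growCenterline(extent, margin, spec$curvature, stepUm)
      if (nrow(cand) * stepUm >= 0.3 * min(extent)) { line <- cand; break }
      if (is.null(line) || nrow(cand) > nrow(line)) line <- cand
    }
    lengthUm <- nrow(line) * stepUm

    # distance to this vessel's centreline in a band around the wall
    dist <- array(Inf, dim = d)
    reach <- r + wt / 2 + 3 * sigmaWall
    for (i in seq_len(nrow(line)))
      dist <- .updateDistance(dist, line[i, ], reach, sp)

    # Gaussian shell truncated at one wall thickness from the centre
    # radius; the point-spread blur restores a smooth edge afterwards
    shell <- exp(-(dist - r)^2 / (2 * sigmaWall^2))
    shell[!is.finite(dist) | abs(dist - r) > wt / 2] <- 0
    endo <- endo + amp * shell
    if (spec$lumenFill > 0) {
      # plasma / out-of-focus luminal glow, confined to the interior
      fill <- 1 / (1 + exp(-((r - wt / 2) - dist) / 0.8))
      fill[!is.finite(dist)] <- 0
      endo <- endo + amp * spec$lumenFill * fill
    }
    wallMask <- wallMask | (abs(dist - r) <= wt / 2)
    lumenMask <- lumenMask | (dist < r - wt / 2)

    # endothelial nuclei: bright blobs on the wall
    nNuc <- rpois(1, spec$nucleusDensity * lengthUm)
    if (nNuc > 0) {
      at <- sample(nrow(line), nNuc, replace = TRUE)
      for (i in at) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        centre <- line[i, ] + u * r
        nucField <- .addBlob(nucField, centre, runif(1, 0.6, 1.2), 1.5, sp)
      }
    }

    # RBC speckles strictly inside the lumen of this vessel
    lumenR <- r - wt / 2
    lumenVol <- pi * lumenR^2 * lengthUm
    nRbc <- rpois(1, spec$rbcDensity * lumenVol)
    if (nRbc > 0) {
      at <- sample(nrow(line), nRbc, replace = TRUE)
      for (i in at) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        # keep speckle cores (and their smoothed proxy) off the wall
        rad <- runif(1, 0, max(lumenR - 3, 0.2))
        centre <- line[i, ] + u * rad
        ax <- runif(3, 1.2, 2.4) # ellipsoidal semi-axes, um
        rbc <- .addRbcBlob(rbc, centre, runif(1, 140, 260), ax, sp)
      }
    }
  }

  # wall and lumen are made disjoint by construction; enforce exactly
  lumenMask <- lumenMask & !wallMask
  endo <- endo * (1 + nucField)

  if (spec$scatterFraction > 0 && spec$nVessels > 0)
    endo <- endo + spec$scatterFraction *
      gaussianBlur3d(endo, spec$scatterSigma / sp)
  if (spec$psfSigma > 0 && spec$nVessels > 0) {
    endo <- gaussianBlur3d(endo, spec$psfSigma / sp)
    rbc <- gaussianBlur3d(rbc, spec$psfSigma / sp)
  }
  if (spec$noiseSigma > 0) {
    endo <- endo + rnorm(length(endo), 0, spec$noiseSigma)
    rbc <- rbc + rnorm(length(rbc), 0, spec$noiseSigma)
  }
  endo <- array(pmax(endo, 0), dim = d)
  rbc <- array(pmax(rbc, 0), dim = d)

  new("PhantomVolume",
      endothelial = ChannelVolume(endo, sp, "endothelial"),
      rbc = ChannelVolume(rbc, sp, "rbc"),
      truthWall = wallMask, truthLumen = lumenMask,
      truthVessel = wallMask | lumenMask,
      spec = unclass(spec))
}

# anisotropic Gaussian blob for RBC speckles
.addRbcBlob <- function(acc, centre, amp, semiAxes, spacing) {
  d <- dim(acc)
  reach <- 2.2 * max(semiAxes)
  lo <- pmax(1L, floor((centre - reach) / spacing) + 1L)
  hi <- pmin(d, ceiling((centre + reach) / spacing))
  if (any(lo > hi)) return(acc)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  zc <- ((zi - 0.5) * spacing[1] - centre[1]) / semiAxes[1]
  yc <- ((yi - 0.5) * spacing[2] - centre[2]) / semiAxes[2]
  xc <- ((xi - 0.5) * spacing[3] - centre[3]) / semiAxes[3]
  q <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`)
  acc[zi, yi, xi] <- acc[zi, yi, xi] + amp * exp(-q * 2)
  acc
}

#' Cut a volume into overlapping tiles with known offsets
#'
#' Tiles are cut along one axis with a nominal spacing implying the
#' requested overlap; the true offsets add an integer stage jitter drawn
#' uniformly in [-jitterPx, +jitterPx]. Tile content is taken at the
#' true offsets, so reassembly at the true offsets reproduces the source
#' exactly.
#'
#' @param volume 2D or 3D numeric array.
#' @param nTiles number of tiles.
#' @param overlapFraction fractional overlap of consecutive tiles (0, 1).
#' @param jitterPx maximal absolute integer jitter in pixels.
#' @param seed integer seed for the jitter draws.
#' @param axis axis along which to tile (default: the last).
#' @return A \linkS4class{TileSet} with both nominal and true positions.
#' @export
generateTileSet <- function(volume, nTiles, overlapFraction, jitterPx = 0,
                            seed = 1, axis = length(dim(volume))) {
  d <- dim(volume)
  stopifnot(!is.null(d), nTiles >= 1,
            overlapFraction > 0, overlapFraction < 1)
  nd <- length(d)
  size <- d[axis]
  w <- if (nTiles == 1) size else
    floor(size / ((nTiles - 1) * (1 - overlapFraction) + 1))
  step <- (1 - overlapFraction) * w
  nominal <- round((seq_len(nTiles) - 1) * step)
  if (nTiles > 1 && any(diff(nominal) <= 0))
    stop("overlap too large to place ", nTiles, " distinct tiles")
  set.seed(as.integer(seed))
  jit <- if (jitterPx > 0)
    sample(seq(-jitterPx, jitterPx), nTiles, replace = TRUE) else rep(0L, nTiles)
  jit[1] <- 0L # first tile anchors the frame
  true <- pmin(pmax(nominal + jit, 0L), size - w)
  if (nTiles > 1 && any(diff(true) <= 0))
    stop("jitter collapsed tile order; reduce jitterPx or overlap")

  cut <- function(off) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- (off + 1):(off + w)
    do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
  }
  tiles <- lapply(true, cut)
  toMat <- function(off) {
    m <- matrix(0, nrow = nTiles, ncol = nd)
    m[, axis] <- off
    m
  }
  adj <- if (nTiles > 1) cbind(seq_len(nTiles - 1), 2:nTiles)
         else matrix(integer(0), ncol = 2)
  new("TileSet", tiles = tiles, nominalPositions = toMat(nominal),
      refinedPositions = matrix(numeric(0), ncol = nd, nrow = 0),
      truePositions = toMat(true), adjacency = adj)
}

#' Specification of a synthetic growth series
#'
#' Defaults mirror the study conditions: observation from 17 to 89
#' hours post fertilisation (3 days every ~45 min gives about 100
#' points).
#'
#' @param modelId one of \code{\link{growthModelIds}}.
#' @param params named model parameters (see \code{\link{modelValue}}).
#' @param tStart,tEnd observation window in hours post fertilisation.
#' @param nPoints number of equally spaced timepoints.
#' @param noiseSigma additive Gaussian noise on the volumes.
#' @param seed integer seed.
#' @return classed list of validated parameters.
#' @export
growthSeriesSpec <- function(modelId, params, tStart = 17, tEnd = 89,
                             nPoints = 100, noiseSigma = 0, seed = 1) {
  modelId <- match.arg(modelId, growthModelIds())
  p <- .checkGrowthParams(modelId, params)
  stopifnot(tStart > 0, tEnd > tStart, noiseSigma >= 0)
  if (nPoints < 4 + length(p))
    stop("nPoints must be at least 4 + number of free parameters")
  structure(list(modelId = modelId, params = p, tStart = tStart,
                 tEnd = tEnd, nPoints = as.integer(nPoints),
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "growthSeriesSpec")
}

#' Generate a noisy volume growth series
#'
#' \code{volume_i = model(t_i) + e_i} with \code{e_i ~ N(0, noiseSigma^2)}
#' at equally spaced times; deterministic for a fixed seed.
#'
#' @param spec a \code{\link{growthSeriesSpec}}.
#' @return A \linkS4class{VolumeSeries}.
#' @export
generateGrowthSeries <- function(spec) {
  stopifnot(inherits(spec, "growthSeriesSpec"))
  set.seed(spec$seed)
  t <- seq(spec$tStart, spec$tEnd, length.out = spec$nPoints)
  v <- modelValue(spec$modelId, spec$params, t)
  if (spec$noiseSigma > 0) v <- v + rnorm(length(t), 0, spec$noiseSigma)
  VolumeSeries(times = t, volumes = v, fishId = "synthetic",
               region = "whole")
}

#' Canonical example growth parameters
#'
#' Log-logistic and log-normal parameter sets whose growth-rate peak
#' lies near 26 hours post fertilisation, the time of maximal
#' whole-vasculature growth, with volumes on the cubic-micrometre scale
#' of a whole embryo.
#'
#' @param modelId \code{"log_logistic"} or \code{"log_normal"}.
#' @return named parameter vector.
#' @export
exampleGrowthParams <- function(modelId = c("log_logistic", "log_normal")) {
  modelId <- match.arg(modelId)
  if (modelId == "log_logistic")
    c(A = 2e6, V_L = 1.5e7, alpha = 33, beta = 3)
  else
    c(A = 2e6, V_L = 1.5e7, mu = log(26) + 0.6^2, sigma = 0.6)
}
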