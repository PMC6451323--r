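# Mosaic planning: how many overlapping acquisition volumes are needed to
# cover a growing embryo, and what data rate an experiment produces.

#' Plan mosaic tile positions along the sample axis
#'
#' Computes the minimal number of field-of-view tiles with a fixed
#' fractional overlap that covers the expected sample length, and their
#' start positions. With a 10x detection lens the field of view is
#' 1.097 mm, and a 30\% overlap is used for reliable stitching.
#'
#' @param sampleLength expected sample length (same unit as \code{fov}).
#' @param fov field-of-view extent of one tile.
#' @param overlapFraction fractional overlap of consecutive tiles, in (0, 1).
#' @param start position of the first tile (default 0).
#' @return list with \code{nTiles}, \code{positions}, \code{step} and
#'   \code{coverage}.
#' @examples
#' plan <- planTiles(4.0, 1.097, 0.30)  # whole 4 mm embryo, 10x lens
#' plan$nTiles                          # 5 acquisition volumes
#' @export
planTiles <- function(sampleLength, fov, overlapFraction, start = 0) {
  if (sampleLength <= 0) stop("sampleLength must be positive")
  if (fov <= 0) stop("fov must be positive")
  if (overlapFraction <= 0 || overlapFraction >= 1)
    stop("overlapFraction must be in (0, 1)")
  step <- (1 - overlapFraction) * fov
  extra <- max(0, sampleLength - fov)
  # tolerate exact ties so an exactly covered sample keeps the smaller count
  n <- 1L + as.integer(ceiling(extra / step - 1e-9))
  positions <- start + (seq_len(n) - 1) * step
  list(nTiles = n, positions = positions, step = step,
       coverage = fov + (n - 1) * step)
}

#' Total number of acquisition volumes in a multi-sample experiment
#'
#' @param nFish number of embryos imaged simultaneously.
#' @param nAngles number of viewing angles per embryo.
#' @param tilesPerFish mosaic tiles per embryo and angle.
#' @return integer product.
#' @examples
#' totalVolumes(5, 3, 5)  # 75
#' @export
totalVolumes <- function(nFish, nAngles, tilesPerFish) {
  stopifnot(nFish >= 1, nAngles >= 1, tilesPerFish >= 1)
  as.integer(nFish) * as.integer(nAngles) * as.integer(tilesPerFish)
}

#' Acquisition settings for data-rate estimation
#'
#' @param nVolumes acquisition volumes per timepoint.
#' @param nChannels channels recorded per volume.
#' @param planesPerVolume z-planes per acquisition volume.
#' @param framePixels camera frame size as c(height, width) pixels.
#' @param bytesPerPixel bytes per pixel (2 for 16-bit).
#' @param intervalMinutes time-lapse interval in minutes.
#' @return classed list of validated settings.
#' @export
acquisitionSettings <- function(nVolumes, nChannels, planesPerVolume,
                                framePixels, bytesPerPixel, intervalMinutes) {
  stopifnot(nVolumes > 0, nChannels > 0, planesPerVolume > 0,
            length(framePixels) == 2, all(framePixels > 0),
            bytesPerPixel > 0, intervalMinutes > 0)
  structure(list(nVolumes = nVolumes, nChannels = nChannels,
                 planesPerVolume = planesPerVolume,
                 framePixels = framePixels, bytesPerPixel = bytesPerPixel,
                 intervalMinutes = intervalMinutes),
            class = "acquisitionSettings")
}

#' Estimate the raw data generation rate of a time-lapse
#'
#' Bytes per timepoint are the product of volumes, channels, planes,
#' frame pixels and pixel depth; the daily rate scales by the number of
#' intervals per day.
#'
#' @param settings an \code{\link{acquisitionSettings}} list.
#' @param binary if TRUE report terabytes as 2^40 bytes instead of 10^12.
#' @return list with \code{bytesPerTimepoint}, \code{bytesPerDay} and
#'   \code{tbPerDay}.
#' @examples
#' s <- acquisitionSettings(75, 2, 200, c(960, 960), 2, 20)
#' estimateDataRate(s)$tbPerDay  # ~3.98 TB/day
#' @export
estimateDataRate <- function(settings, binary = FALSE) {
  stopifnot(inherits(settings, "acquisitionSettings"))
  perTimepoint <- settings$nVolumes * settings$nChannels *
    settings$planesPerVolume * prod(settings$framePixels) *
    settings$bytesPerPixel
  perDay <- perTimepoint * (1440 / settings$intervalMinutes)
  tb <- if (binary) 2^40 else 1e12
  list(bytesPerTimepoint = perTimepoint, bytesPerDay = perDay,
       tbPerDay = perDay / tb)
}
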