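# Readers and writers for the standard on-disk formats: multi-page TIFF
# volumes (z-planes as pages), sidecar JSON metadata, stage-position and
# offset CSV tables.

#' Write a 3D volume as a multi-page TIFF
#'
#' Planes are written as 32-bit float pages after scaling to [0, 1] by
#' the given \code{maxValue} (stored in the sidecar if one is written).
#'
#' @param volume 3D numeric array \code{[z, y, x]} or
#'   \linkS4class{ChannelVolume}.
#' @param path output .tif path.
#' @param maxValue intensity mapped to 1.0 (default: the volume maximum,
#'   or 1 for an all-zero volume).
#' @param bits bits per sample: 32 (float) or 16 (integer, camera-count
#'   style).
#' @return \code{maxValue} used, invisibly.
#' @export
writeVolumeTiff <- function(volume, path, maxValue = NULL, bits = 32L) {
  x <- if (is(volume, "ChannelVolume")) intensities(volume) else volume
  .stopIfNot3d(x)
  if (is.null(maxValue)) maxValue <- max(x, 1e-12)
  pages <- lapply(seq_len(dim(x)[1]), function(z)
    pmin(x[z, , ] / maxValue, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(maxValue)
}

#' Read a multi-page TIFF as a 3D volume
#'
#' @param path .tif path.
#' @param spacing voxel spacing (z, y, x) in micrometres.
#' @param channel channel tag for the returned volume.
#' @param maxValue intensity scale to undo \code{\link{writeVolumeTiff}}.
#' @return A \linkS4class{ChannelVolume}.
#' @export
readVolumeTiff <- function(path, spacing = c(1, 1, 1),
                           channel = "endothelial", maxValue = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  x <- array(0, d)
  for (z in seq_len(d[1])) x[z, , ] <- pages[[z]] * maxValue
  ChannelVolume(pmax(x, 0), spacing, channel)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output .tif path.
#' @export
writeMaskTiff <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  v <- maskVoxels(mask)
  pages <- lapply(seq_len(dim(v)[1]), function(z)
    (v[z, , ]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit mask TIFF
#' @param path .tif path.
#' @param spacing voxel spacing (z, y, x).
#' @return A \linkS4class{BinaryMask}.
#' @export
readMaskTiff <- function(path, spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  x <- array(FALSE, d)
  for (z in seq_len(d[1])) x[z, , ] <- pages[[z]] > 0.5
  BinaryMask(x, spacing)
}

#' Write a phantom to disk
#'
#' One multi-page float TIFF per channel plus a sidecar JSON carrying
#' the spacing, seed, intensity scales and the generating spec.
#'
#' @param phantom a \linkS4class{PhantomVolume}.
#' @param dir output directory (created if missing).
#' @return the sidecar path, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "PhantomVolume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mEndo <- writeVolumeTiff(phantom@endothelial, file.path(dir, "endothelial.tif"))
  mRbc <- writeVolumeTiff(phantom@rbc, file.path(dir, "rbc.tif"))
  writeMaskTiff(BinaryMask(phantom@truthVessel, voxelSpacing(phantom@endothelial)),
                file.path(dir, "truth_vessel.tif"))
  meta <- list(spacing = voxelSpacing(phantom@endothelial),
               seed = phantom@spec$seed,
               maxEndothelial = mEndo, maxRbc = mRbc,
               spec = phantom@spec)
  side <- file.path(dir, "phantom.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read stage positions and convert to voxel offsets
#'
#' The CSV has columns tile_id, z, y, x with positions in micrometres;
#' offsets are relative to the first tile, divided by the voxel spacing
#' and rounded to integer voxels.
#'
#' @param path positions CSV.
#' @param spacing voxel spacing (z, y, x) in micrometres.
#' @return integer matrix (n x 3) ordered by tile_id.
#' @export
readStagePositions <- function(path, spacing = c(1, 1, 1)) {
  df <- utils::read.csv(path)
  df <- df[order(df$tile_id), ]
  um <- as.matrix(df[, c("z", "y", "x")])
  um <- sweep(um, 2, um[1, ])
  matrix(as.integer(round(sweep(um, 2, spacing, `/`))), nrow(um), 3)
}

#' Write a tile-offset report
#'
#' @param tileSet a \linkS4class{TileSet} (after stitching, the refined
#'   positions are included).
#' @param path output CSV.
#' @export
writeOffsetsCsv <- function(tileSet, path) {
  stopifnot(is(tileSet, "TileSet"))
  n <- length(tileSet@tiles)
  nd <- ncol(tileSet@nominalPositions)
  cols <- c("z", "y", "x")[(3 - nd + 1):3]
  df <- data.frame(tile_id = seq_len(n))
  for (k in seq_len(nd)) df[[paste0("nominal_", cols[k])]] <- tileSet@nominalPositions[, k]
  if (nrow(tileSet@truePositions) == n)
    for (k in seq_len(nd)) df[[paste0("true_", cols[k])]] <- tileSet@truePositions[, k]
  if (nrow(tileSet@refinedPositions) == n)
    for (k in seq_len(nd)) df[[paste0("refined_", cols[k])]] <- tileSet@refinedPositions[, k]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a segmentation model as JSON
#' @param model a \linkS4class{SegmentationModel}.
#' @param path output .json path.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "SegmentationModel"))
  jsonlite::write_json(list(
    weights = model@weights, featureNames = c(featureNames(), "bias"),
    featureMeans = model@featureMeans, featureSds = model@featureSds,
    scoreThreshold = model@scoreThreshold,
    trainingSummary = model@trainingSummary), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segmentation model from JSON
#' @param path .json written by \code{\link{writeModelJson}}.
#' @return A \linkS4class{SegmentationModel}.
#' @export
readModelJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SegmentationModel", weights = as.numeric(j$weights),
      featureMeans = as.numeric(j$featureMeans),
      featureSds = as.numeric(j$featureSds),
      scoreThreshold = as.numeric(j$scoreThreshold),
      trainingSummary = as.list(j$trainingSummary))
}
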