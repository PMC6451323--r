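#' Voxel spacing accessor
#' @param x an object holding a voxel grid.
#' @return numeric(3) spacing (z, y, x) in micrometres.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
setMethod("voxelSpacing", "ChannelVolume", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' Raw intensity accessor
#' @param x a \linkS4class{ChannelVolume}.
#' @return the 3D intensity array.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname intensities
setMethod("intensities", "ChannelVolume", function(x) x@intensities)

#' Mask voxel accessor
#' @param x a \linkS4class{BinaryMask}.
#' @return the 3D logical array.
#' @export
setGeneric("maskVoxels", function(x) standardGeneric("maskVoxels"))
#' @rdname maskVoxels
setMethod("maskVoxels", "BinaryMask", function(x) x@voxels)

#' Model weights accessor
#' @param x a \linkS4class{SegmentationModel}.
#' @return named numeric(7): six feature weights and the bias.
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname modelWeights
setMethod("modelWeights", "SegmentationModel", function(x) x@weights)

#' Growth-fit parameter accessor
#' @param x a \linkS4class{GrowthFit}.
#' @return named numeric vector of parameters on the natural scale.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname fitParams
setMethod("fitParams", "GrowthFit", function(x) x@params)

#' Residual sum of squares accessor
#' @param x a \linkS4class{GrowthFit}.
#' @return numeric(1) RSS.
#' @export
setGeneric("fitRss", function(x) standardGeneric("fitRss"))
#' @rdname fitRss
setMethod("fitRss", "GrowthFit", function(x) x@rss)

#' @export
setMethod("dim", "ChannelVolume", function(x) dim(x@intensities))
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@voxels))

setMethod("show", "ChannelVolume", function(object) {
  d <- dim(object)
  cat(sprintf("ChannelVolume [%s] %d x %d x %d voxels (z,y,x), spacing %s um\n",
              object@channel, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object)
  cat(sprintf("BinaryMask %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@voxels),
              100 * mean(object@voxels)))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@features[[1]])
  cat(sprintf("FeatureStack: 6 features on %d x %d x %d grid (%s)\n",
              d[1], d[2], d[3],
              if (object@standardized) "standardized" else "raw scale"))
})

setMethod("show", "SegmentationModel", function(object) {
  cat("SegmentationModel\n  weights:\n")
  w <- object@weights
  names(w) <- c(featureNames(), "bias")
  print(signif(w, 4))
  cat(sprintf("  score threshold: %s\n",
              ifelse(is.na(object@scoreThreshold), "not set",
                     signif(object@scoreThreshold, 4))))
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet: %d tiles (%dD), %d adjacent pairs, %s\n",
              length(object@tiles), length(dim(object@tiles[[1]])),
              nrow(object@adjacency),
              if (nrow(object@refinedPositions)) "registered" else "unregistered"))
})

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@endothelial)
  cat(sprintf("PhantomVolume %d x %d x %d: vessel %.2f%%, lumen %.2f%% of voxels\n",
              d[1], d[2], d[3], 100 * mean(object@truthVessel),
              100 * mean(object@truthLumen)))
})

setMethod("show", "VolumeSeries", function(object) {
  cat(sprintf("VolumeSeries %s/%s: %d timepoints, %.1f-%.1f hpf\n",
              object@fishId, object@region, length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit [%s] rss = %.4g on %d points (%s)\n",
              object@modelId, object@rss, object@nObs,
              if (object@converged) "converged" else "NOT converged"))
  print(signif(object@params, 5))
})
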