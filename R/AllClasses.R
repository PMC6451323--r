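#' @import methods
NULL

#' ChannelVolume: a single-channel 3D intensity volume
#'
#' Container for one fluorescence channel of a 3D stack with anisotropic
#' voxel spacing. Channel tags distinguish the endothelial wall marker
#' from the circulating red-blood-cell (RBC) marker.
#'
#' @slot intensities 3D numeric array indexed \code{[z, y, x]}, non-negative.
#' @slot spacing numeric(3), voxel spacing (z, y, x) in micrometres.
#' @slot channel character, \code{"endothelial"} or \code{"rbc"}.
#' @exportClass ChannelVolume
setClass("ChannelVolume",
  representation(intensities = "array", spacing = "numeric", channel = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@intensities)) != 3) msg <- c(msg, "intensities must be 3D")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (length(object@intensities) == 0) msg <- c(msg, "volume is empty")
    if (min(object@intensities) < 0) msg <- c(msg, "intensities must be non-negative")
    if (!object@channel %in% c("endothelial", "rbc"))
      msg <- c(msg, "channel must be 'endothelial' or 'rbc'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ChannelVolume
#'
#' @param intensities 3D numeric array \code{[z, y, x]} of non-negative values.
#' @param spacing voxel spacing (z, y, x) in micrometres.
#' @param channel channel tag, \code{"endothelial"} or \code{"rbc"}.
#' @return A \linkS4class{ChannelVolume}.
#' @examples
#' v <- ChannelVolume(array(1, c(4, 4, 4)), c(4, 1, 1), "endothelial")
#' voxelSpacing(v)
#' @export
ChannelVolume <- function(intensities, spacing = c(1, 1, 1),
                          channel = c("endothelial", "rbc")) {
  channel <- match.arg(channel)
  new("ChannelVolume", intensities = intensities,
      spacing = as.numeric(spacing), channel = channel)
}

#' BinaryMask: a 3D segmentation mask
#'
#' @slot voxels 3D logical array, same grid as the source volume.
#' @slot spacing numeric(3), voxel spacing (z, y, x) in micrometres.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3) msg <- c(msg, "voxels must be 3D")
    if (!is.logical(object@voxels)) msg <- c(msg, "voxels must be logical")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BinaryMask
#' @param voxels 3D logical array.
#' @param spacing voxel spacing (z, y, x) in micrometres.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(voxels, spacing = c(1, 1, 1)) {
  new("BinaryMask", voxels = array(as.logical(voxels), dim(voxels)),
      spacing = as.numeric(spacing))
}

#' FeatureStack: six aligned per-voxel feature maps
#'
#' The per-voxel features of the endothelial channel weighed by the
#' segmentation model: raw signal, the three axis gradients, the total
#' gradient magnitude, and the inverse-gradient-weighted raw signal
#' raw / (1 + |grad|). Features are z-scored over the volume; the
#' pre-standardisation means and standard deviations are retained so a
#' fitted model can be applied to new volumes.
#'
#' @slot features named list of six 3D arrays (raw, gradX, gradY, gradZ,
#'   gradMag, invGradRaw).
#' @slot means,sds numeric(6) pre-standardisation statistics.
#' @slot standardized logical, whether the stored maps are z-scored.
#' @exportClass FeatureStack
setClass("FeatureStack",
  representation(features = "list", means = "numeric", sds = "numeric",
                 standardized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!identical(names(object@features), featureNames()))
      msg <- c(msg, "features must be the six canonical maps")
    dims <- lapply(object@features, dim)
    if (length(unique(dims)) != 1) msg <- c(msg, "feature maps must share one shape")
    if (length(object@means) != 6 || length(object@sds) != 6)
      msg <- c(msg, "means and sds must have length 6")
    if (is.null(msg)) TRUE else msg
  })

#' Canonical feature names
#' @return character(6) of feature map names in model order.
#' @export
featureNames <- function() c("raw", "gradX", "gradY", "gradZ", "gradMag", "invGradRaw")

#' SegmentationModel: linear per-voxel classifier
#'
#' Weight vector over the six features plus a bias, together with the
#' feature standardisation used at training time and the score threshold
#' applied to the score image.
#'
#' @slot weights numeric(7): six feature weights then the bias.
#' @slot featureMeans,featureSds numeric(6) training standardisation.
#' @slot scoreThreshold numeric(1); NA until a threshold has been chosen.
#' @slot trainingSummary list with N, seed, residual and shortfall flag.
#' @exportClass SegmentationModel
setClass("SegmentationModel",
  representation(weights = "numeric", featureMeans = "numeric",
                 featureSds = "numeric", scoreThreshold = "numeric",
                 trainingSummary = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@weights) != 7) msg <- c(msg, "weights must have length 7 (6 + bias)")
    if (length(object@featureMeans) != 6 || length(object@featureSds) != 6)
      msg <- c(msg, "feature statistics must have length 6")
    if (any(object@featureSds < 0)) msg <- c(msg, "feature sds must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' TrainingSet: labelled voxel coordinates for weight fitting
#'
#' @slot coords integer matrix (n x 3) of (z, y, x) voxel indices.
#' @slot labels integer vector of 1 (luminal) / 0 (non-luminal).
#' @slot nPerClass requested samples per class.
#' @slot shortfall logical, TRUE when a class ran out of candidates.
#' @slot seed integer seed used for sampling.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(coords = "matrix", labels = "integer", nPerClass = "integer",
                 shortfall = "logical", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@coords) != 3) msg <- c(msg, "coords must be n x 3")
    if (nrow(object@coords) != length(object@labels))
      msg <- c(msg, "coords and labels must be parallel")
    if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
    if (anyDuplicated(object@coords)) msg <- c(msg, "duplicate coordinates")
    if (is.null(msg)) TRUE else msg
  })

#' TileSet: overlapping mosaic tiles with stage positions
#'
#' @slot tiles list of arrays (all 2D or all 3D), one per tile.
#' @slot nominalPositions numeric matrix (n x d) of tile-origin offsets in
#'   voxels derived from stage positions.
#' @slot refinedPositions numeric matrix (n x d) after registration
#'   (0 rows until \code{stitchDataset} has run).
#' @slot truePositions numeric matrix; ground-truth offsets for synthetic
#'   tile sets (0 rows otherwise).
#' @slot adjacency integer matrix (m x 2) of tile-index pairs expected to
#'   overlap.
#' @exportClass TileSet
setClass("TileSet",
  representation(tiles = "list", nominalPositions = "matrix",
                 refinedPositions = "matrix", truePositions = "matrix",
                 adjacency = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@tiles)
    if (n == 0) msg <- c(msg, "tile list is empty")
    nd <- unique(vapply(object@tiles, function(t) length(dim(t)), integer(1)))
    if (length(nd) != 1) msg <- c(msg, "tiles must share dimensionality")
    if (nrow(object@nominalPositions) != n)
      msg <- c(msg, "one nominal position per tile required")
    if (any(!is.finite(object@nominalPositions))) msg <- c(msg, "positions must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' PhantomVolume: synthetic two-channel phantom with ground truth
#'
#' @slot endothelial,rbc \linkS4class{ChannelVolume}s of the two markers.
#' @slot truthWall,truthLumen,truthVessel logical arrays; lumen and wall
#'   are disjoint and vessel is their union.
#' @slot spec the \code{phantomSpec} the phantom was generated from.
#' @exportClass PhantomVolume
setClass("PhantomVolume",
  representation(endothelial = "ChannelVolume", rbc = "ChannelVolume",
                 truthWall = "array", truthLumen = "array",
                 truthVessel = "array", spec = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@endothelial@intensities)
    if (!identical(d, dim(object@rbc@intensities)) ||
        !identical(d, dim(object@truthWall)) ||
        !identical(d, dim(object@truthLumen)) ||
        !identical(d, dim(object@truthVessel)))
      msg <- c(msg, "all grids must share one shape")
    if (any(object@truthWall & object@truthLumen))
      msg <- c(msg, "wall and lumen must be disjoint")
    if (!identical(object@truthVessel, object@truthWall | object@truthLumen))
      msg <- c(msg, "vessel truth must be wall union lumen")
    if (is.null(msg)) TRUE else msg
  })

#' BoundaryRoi: closed polygonal region of interest on a projection
#'
#' @slot timepoint integer index of the frame the ROI belongs to.
#' @slot points numeric matrix (m x 2) of (y, x) pixel coordinates of the
#'   boundary, at least three.
#' @exportClass BoundaryRoi
setClass("BoundaryRoi",
  representation(timepoint = "integer", points = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@points) != 2) msg <- c(msg, "points must be m x 2 (y, x)")
    if (nrow(object@points) < 3) msg <- c(msg, "a closed boundary needs >= 3 points")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BoundaryRoi
#' @param points numeric matrix (m x 2) of (y, x) boundary coordinates.
#' @param timepoint frame index the ROI is drawn on.
#' @return A \linkS4class{BoundaryRoi}.
#' @export
BoundaryRoi <- function(points, timepoint = 1L) {
  new("BoundaryRoi", timepoint = as.integer(timepoint),
      points = as.matrix(points))
}

#' VolumeSeries: vascular volume over developmental time
#'
#' @slot fishId sample identifier.
#' @slot region annotated region tag (whole, head, tail, plexus, other).
#' @slot times hours post fertilisation, strictly increasing.
#' @slot volumes volumes in cubic micrometres, non-negative.
#' @slot angleIds identifiers of the viewing angles contributing.
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(fishId = "character", region = "character",
                 times = "numeric", volumes = "numeric", angleIds = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@volumes))
      msg <- c(msg, "times and volumes must be parallel")
    if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VolumeSeries
#' @param times hours post fertilisation, strictly increasing.
#' @param volumes volumes (um^3), parallel to \code{times}.
#' @param fishId,region,angleIds metadata tags.
#' @return A \linkS4class{VolumeSeries}.
#' @export
VolumeSeries <- function(times, volumes, fishId = "fish", region = "whole",
                         angleIds = character(0)) {
  new("VolumeSeries", fishId = fishId, region = region,
      times = as.numeric(times), volumes = as.numeric(volumes),
      angleIds = angleIds)
}

#' GrowthFit: a fitted growth model
#'
#' @slot modelId one of the supported model identifiers.
#' @slot params named numeric parameter vector on the natural scale.
#' @slot rss residual sum of squares of the fit.
#' @slot nObs number of observations fitted.
#' @slot converged logical convergence flag.
#' @slot nRestartsUsed restarts consumed by the multi-start search.
#' @slot boundary logical, TRUE when the fit collapsed to a parameter
#'   boundary (e.g. vanishing amplitude on constant data).
#' @exportClass GrowthFit
setClass("GrowthFit",
  representation(modelId = "character", params = "numeric", rss = "numeric",
                 nObs = "integer", converged = "logical",
                 nRestartsUsed = "integer", boundary = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@rss) != 1 || (is.finite(object@rss) && object@rss < 0))
      msg <- c(msg, "rss must be a single non-negative number")
    if (object@converged && any(!is.finite(object@params)))
      msg <- c(msg, "a converged fit must have finite parameters")
    if (is.null(msg)) TRUE else msg
  })
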