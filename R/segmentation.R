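# Self-supervised vessel segmentation. Circulating red blood cells are
# confined to vessel lumina, so a filtered and thresholded RBC channel
# is an inherent luminal proxy that supplies training labels for a
# linear per-voxel classifier over the endothelial-channel features.
# The fitted score image is thresholded with the Triangle algorithm and
# cleaned by a morphological opening.

#' Luminal proxy from the red-blood-cell channel
#'
#' Gaussian-filters the RBC channel and applies a global Otsu threshold
#' to the filtered intensities (256-level histogram over the full
#' range). The resulting mask marks luminal signal and serves as ground
#' truth for training the segmentation model.
#'
#' @param rbc a \linkS4class{ChannelVolume} with channel tag "rbc".
#' @param smoothingSigma Gaussian sigma in voxels (default 2).
#' @return A \linkS4class{BinaryMask}; a flat input yields an empty mask
#'   with a warning.
#' @export
luminalProxy <- function(rbc, smoothingSigma = 2) {
  stopifnot(is(rbc, "ChannelVolume"))
  if (rbc@channel != "rbc") stop("luminalProxy expects the rbc channel")
  x <- intensities(rbc)
  sm <- if (smoothingSigma > 0) gaussianBlur3d(x, smoothingSigma) else x
  thr <- otsuThresholdValue(sm)
  if (is.na(thr)) {
    warning("flat RBC volume: no threshold separable, returning empty mask")
    return(BinaryMask(array(FALSE, dim(x)), voxelSpacing(rbc)))
  }
  BinaryMask(sm > thr, voxelSpacing(rbc))
}

#' Sample training points for the segmentation model
#'
#' Candidate coordinates are sampled uniformly over the whole volume;
#' positives are candidates inside the luminal proxy, negatives the
#' rest. Both classes are drawn without replacement (a seeded shuffle,
#' then the first N of each class), so the negative class reflects the
#' true composition of non-luminal voxels -- mostly dark background
#' with a minority of bright wall voxels. This composition is what lets
#' a linear score place both lumen and wall above the background: with
#' negatives restricted to the vessel neighbourhood the fitted raw
#' weight turns negative and the (unseen) far background outscores the
#' lumen, inverting the segmentation. A class with fewer than N
#' available candidates returns all of them and sets the shortfall
#' flag.
#'
#' @param vessel endothelial \linkS4class{ChannelVolume}.
#' @param lumenMask luminal proxy \linkS4class{BinaryMask}.
#' @param N requested points per class (the study used 5000).
#' @param seed integer sampling seed.
#' @return A \linkS4class{TrainingSet}.
#' @export
sampleTrainingPoints <- function(vessel, lumenMask, N = 5000, seed = 0) {
  stopifnot(is(vessel, "ChannelVolume"), is(lumenMask, "BinaryMask"), N >= 1)
  if (!identical(dim(vessel), dim(lumenMask)))
    stop("vessel volume and lumen mask shapes differ")
  x <- intensities(vessel)
  lum <- maskVoxels(lumenMask)
  posIdx <- which(lum)
  negIdx <- which(!lum)
  set.seed(as.integer(seed))
  takePos <- if (length(posIdx)) sample(posIdx) else integer(0)
  takeNeg <- if (length(negIdx)) sample(negIdx) else integer(0)
  takePos <- takePos[seq_len(min(N, length(takePos)))]
  takeNeg <- takeNeg[seq_len(min(N, length(takeNeg)))]
  shortfall <- length(takePos) < N || length(takeNeg) < N
  lin <- c(takePos, takeNeg)
  coords <- arrayInd(lin, dim(x))
  colnames(coords) <- c("z", "y", "x")
  new("TrainingSet", coords = coords,
      labels = c(rep(1L, length(takePos)), rep(0L, length(takeNeg))),
      nPerClass = as.integer(N), shortfall = shortfall,
      seed = as.integer(seed))
}

#' Fit feature weights by singular value decomposition
#'
#' Builds the design matrix of standardized features (plus a constant
#' bias column) at the training coordinates and solves the linear
#' least-squares problem against the 0/1 labels with the SVD
#' pseudo-inverse (minimum-norm solution when the system is
#' rank-deficient). The fit residual is recorded in the model.
#'
#' @param features \linkS4class{FeatureStack} of the same volume the
#'   training points were sampled from.
#' @param training a \linkS4class{TrainingSet} containing both classes.
#' @return A \linkS4class{SegmentationModel} (score threshold unset).
#' @export
fitFeatureWeights <- function(features, training) {
  stopifnot(is(features, "FeatureStack"), is(training, "TrainingSet"))
  y <- as.numeric(training@labels)
  if (length(unique(y)) < 2)
    stop("training set contains a single class; cannot fit weights")
  d <- dim(features@features[[1]])
  lin <- (training@coords[, 1]) +
    (training@coords[, 2] - 1L) * d[1] +
    (training@coords[, 3] - 1L) * d[1] * d[2]
  X <- cbind(.featureMatrixAt(features, lin), bias = 1)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  dInv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  w <- sv$v %*% (dInv * crossprod(sv$u, y))
  w <- as.numeric(w)
  names(w) <- c(featureNames(), "bias")
  resid <- sum((X %*% w - y)^2)
  new("SegmentationModel", weights = w, featureMeans = features@means,
      featureSds = features@sds, scoreThreshold = NA_real_,
      trainingSummary = list(N = training@nPerClass, seed = training@seed,
                             residual = resid,
                             shortfall = training@shortfall))
}

#' Score a volume with a fitted segmentation model
#'
#' The score image is the linear combination of the six feature maps
#' with the model weights plus the bias, using the standardisation
#' statistics stored in the model.
#'
#' @param features \linkS4class{FeatureStack} of the volume to score.
#' @param model a fitted \linkS4class{SegmentationModel}.
#' @return 3D numeric array of segmentation scores.
#' @export
scoreVolume <- function(features, model) {
  stopifnot(is(features, "FeatureStack"), is(model, "SegmentationModel"))
  d <- dim(features@features[[1]])
  score <- array(model@weights[7], dim = d)
  for (j in 1:6) {
    f <- features@features[[j]]
    if (!features@standardized) {
      f <- if (model@featureSds[j] > 0)
        (f - model@featureMeans[j]) / model@featureSds[j]
      else array(0, d)
    }
    score <- score + model@weights[j] * f
  }
  score
}

#' Triangle threshold of a histogram
#'
#' Draws the line from the histogram peak to the far end of its longer
#' tail (the last non-zero bin on that side) and returns the bin
#' maximising the vertical distance between the line and the histogram.
#' When the long tail lies left of the peak the histogram is mirrored,
#' processed, and the result mirrored back.
#'
#' @param counts integer vector of histogram counts; bins are indexed
#'   from 0 in the returned value (image-histogram convention).
#' @return list with \code{bin} (0-based index) and \code{degenerate}
#'   flag (TRUE for a single-spike histogram).
#' @examples
#' triangleThreshold(c(100, 0, 0, 0, 10))$bin  # 1
#' @export
triangleThreshold <- function(counts) {
  counts <- as.numeric(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("empty histogram")
  if (length(nz) == 1)
    return(list(bin = nz[1] - 1L, degenerate = TRUE))
  peak <- which.max(counts)
  leftSpan <- peak - nz[1]
  rightSpan <- nz[length(nz)] - peak
  mirrored <- leftSpan > rightSpan
  h <- if (mirrored) rev(counts) else counts
  p <- which.max(h)
  end <- max(which(h > 0))
  if (end == p) {
    # all mass at the peak on this side; threshold at the peak
    bin <- p
  } else {
    b <- p:end
    line <- h[p] + (h[end] - h[p]) * (b - p) / (end - p)
    dist <- line - h[b]
    bin <- b[which.max(dist)]
  }
  if (mirrored) bin <- length(counts) + 1L - bin
  list(bin = as.integer(bin - 1L), degenerate = FALSE)
}

#' Morphological cleanup of a binary mask
#'
#' One erosion followed by one dilation (a morphological opening) with
#' the 6-connected 3D cross structuring element; isolated single-voxel
#' fragments are removed while large structures are preserved.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return the opened \linkS4class{BinaryMask}.
#' @export
morphologicalCleanup <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  BinaryMask(binaryDilate6(binaryErode6(maskVoxels(mask))), mask@spacing)
}

#' Segmentation pipeline configuration
#'
#' @param N training points per class.
#' @param seed sampling seed.
#' @param smoothingSigma Gaussian sigma (voxels) for the luminal proxy.
#' @param nBins score-histogram bins for the Triangle threshold.
#' @return classed list of parameters.
#' @export
segmentationConfig <- function(N = 5000, seed = 0, smoothingSigma = 2,
                               nBins = 256) {
  structure(list(N = N, seed = seed, smoothingSigma = smoothingSigma,
                 nBins = nBins), class = "segmentationConfig")
}

#' Segment a two-channel volume
#'
#' Composes the full self-supervised segmentation: luminal proxy from
#' the RBC channel, training-point sampling, feature extraction, SVD
#' weight fit, score image, Triangle threshold on a 256-bin score
#' histogram, and morphological opening. Errors from any stage are
#' re-raised with the stage name.
#'
#' @param vessel endothelial \linkS4class{ChannelVolume}.
#' @param rbc RBC \linkS4class{ChannelVolume}, same grid.
#' @param config a \code{\link{segmentationConfig}}.
#' @param model optional previously fitted \linkS4class{SegmentationModel}
#'   to reuse instead of fitting per stack.
#' @return list with \code{mask} (\linkS4class{BinaryMask}) and
#'   \code{model} (\linkS4class{SegmentationModel} with the score
#'   threshold filled in).
#' @export
segmentVolume <- function(vessel, rbc, config = segmentationConfig(),
                          model = NULL) {
  stopifnot(is(vessel, "ChannelVolume"), is(rbc, "ChannelVolume"))
  if (!identical(dim(vessel), dim(rbc)))
    stop("channels must share one shape")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("segmentation stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  features <- stage("features", computeFeatureStack(vessel))
  if (is.null(model)) {
    lumen <- stage("luminal_proxy", luminalProxy(rbc, config$smoothingSigma))
    training <- stage("sampling",
      sampleTrainingPoints(vessel, lumen, N = config$N, seed = config$seed))
    if (sum(training@labels == 1L) == 0)
      stop("segmentation stage 'sampling': no positive (luminal) candidates",
           call. = FALSE)
    model <- stage("weight_fit", fitFeatureWeights(features, training))
  }
  score <- stage("scoring", scoreVolume(features, model))
  rng <- range(score)
  if (diff(rng) == 0)
    stop("segmentation stage 'threshold': constant score image", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = config$nBins + 1)
  counts <- tabulate(findInterval(score, breaks, rightmost.closed = TRUE),
                     nbins = config$nBins)
  tri <- stage("threshold", triangleThreshold(counts))
  thr <- (breaks[tri$bin + 1] + breaks[tri$bin + 2]) / 2 # centre of the bin
  model@scoreThreshold <- thr
  mask <- BinaryMask(score > thr, voxelSpacing(vessel))
  mask <- stage("cleanup", morphologicalCleanup(mask))
  list(mask = mask, model = model)
}
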