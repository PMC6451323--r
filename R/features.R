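# Per-voxel features of the endothelial channel. The segmentation model
# weighs six maps: the raw signal, the three first-order axis gradients,
# the total gradient magnitude, and the inverse-gradient-weighted raw
# image raw / (1 + |grad|), which is large inside bright flat regions
# and suppressed at edges.

#' Compute the six-feature stack of an endothelial volume
#'
#' Gradients are central differences in voxel units with replicate-edge
#' handling. The gradient magnitude is the Euclidean norm of the three
#' axis gradients. After construction each feature is z-scored over the
#' whole volume (constant features map to all zeros); the
#' pre-standardisation means and standard deviations are stored so a
#' model fitted on one volume can score another.
#'
#' @param volume a \linkS4class{ChannelVolume} (or bare 3D array) with at
#'   least 3 voxels along each axis.
#' @param standardize z-score the features (default TRUE; FALSE keeps the
#'   raw feature scale, mainly for inspection and testing).
#' @return A \linkS4class{FeatureStack}.
#' @examples
#' v <- ChannelVolume(array(runif(125), c(5, 5, 5)), c(1, 1, 1))
#' computeFeatureStack(v)
#' @export
computeFeatureStack <- function(volume, standardize = TRUE) {
  x <- if (is(volume, "ChannelVolume")) intensities(volume) else volume
  .stopIfNot3d(x)
  if (any(dim(x) < 3))
    stop("volume must have at least 3 voxels along each axis")
  gz <- .centralDiff(x, 1)
  gy <- .centralDiff(x, 2)
  gx <- .centralDiff(x, 3)
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  f <- list(raw = x, gradX = gx, gradY = gy, gradZ = gz, gradMag = gm,
            invGradRaw = x / (1 + gm))
  means <- vapply(f, mean, numeric(1))
  sds <- vapply(f, stats::sd, numeric(1))
  if (standardize) {
    f <- mapply(function(m, mu, s) {
      if (s > 0) (m - mu) / s else array(0, dim(m))
    }, f, means, sds, SIMPLIFY = FALSE)
  }
  new("FeatureStack", features = f, means = unname(means),
      sds = unname(sds), standardized = standardize)
}

# features at linear voxel indices as an n x 6 matrix (standardized with
# the given statistics, which default to the stack's own)
.featureMatrixAt <- function(stack, linIdx, means = stack@means,
                             sds = stack@sds) {
  m <- vapply(seq_along(stack@features), function(j) {
    v <- stack@features[[j]][linIdx]
    if (!stack@standardized) {
      if (sds[j] > 0) v <- (v - means[j]) / sds[j] else v <- rep(0, length(v))
    }
    v
  }, numeric(length(linIdx)))
  if (length(linIdx) == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- featureNames()
  m
}
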