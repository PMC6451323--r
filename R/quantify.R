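# Volume quantification: isotropic resampling of segmentation masks,
# voxel counting, per-annotation-region counting, two-angle averaging
# and temporal alignment across fish.

# nearest-neighbour resample of an integer/logical array to isotropic
# spacing; returns list(array, iso). Shared by mask and label resampling
# so region counts partition the whole-mask count exactly.
.resampleIso <- function(x, spacing, iso = min(spacing)) {
  d <- dim(x)
  maps <- lapply(1:3, function(a) .nnIndexMap(d[a], spacing[a], iso))
  list(array = x[maps[[1]], maps[[2]], maps[[3]], drop = FALSE], iso = iso)
}

#' Measure the physical volume of a binary mask
#'
#' The mask is resampled to isotropic resolution (nearest neighbour, at
#' the finest existing spacing) and the segmented voxels are counted;
#' the volume is the count times the isotropic voxel volume.
#'
#' @param mask a \linkS4class{BinaryMask} with spacing metadata.
#' @return list with \code{volumeUm3}, \code{voxelCount} (isotropic) and
#'   \code{isoSpacing}.
#' @examples
#' m <- BinaryMask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
#' measureVolume(m)$volumeUm3  # 1000
#' @export
measureVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  rs <- .resampleIso(mask@voxels, mask@spacing)
  n <- sum(rs$array)
  list(volumeUm3 = n * rs$iso^3, voxelCount = n, isoSpacing = rs$iso)
}

#' Per-region volumes of a mask under an annotation labelling
#'
#' Counts segmented voxels per annotation label after resampling mask
#' and labels to the same isotropic grid. Labels are mutually exclusive
#' integers (0 = unlabelled); segmented voxels without a label are
#' reported as region \code{"other"}, so region volumes always sum to
#' the whole-mask volume.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param labels integer array of the same shape as the mask.
#' @param regionNames optional named character vector mapping label
#'   integers (as names) to region names.
#' @return data.frame with columns region, label, voxelCount, volumeUm3.
#' @export
measureRegionVolumes <- function(mask, labels, regionNames = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  if (!identical(dim(mask@voxels), dim(labels)))
    stop("mask and labels must share one shape")
  iso <- min(mask@spacing)
  m <- .resampleIso(mask@voxels, mask@spacing, iso)$array
  l <- .resampleIso(labels, mask@spacing, iso)$array
  ids <- sort(unique(as.integer(l[m])))
  counts <- vapply(ids, function(i) sum(m & l == i), numeric(1))
  region <- as.character(ids)
  region[ids == 0] <- "other"
  if (!is.null(regionNames)) {
    hit <- match(as.character(ids), names(regionNames))
    region[!is.na(hit)] <- regionNames[hit[!is.na(hit)]]
  }
  data.frame(region = region, label = ids, voxelCount = counts,
             volumeUm3 = counts * iso^3, row.names = NULL)
}

#' Average the volume series of two viewing angles
#'
#' The two opposite angles give independent measurements of the same
#' fish; their pointwise mean is the per-fish volume curve. Timepoints
#' present in only one series are dropped with a warning.
#'
#' @param a,b \linkS4class{VolumeSeries} of the same fish and region.
#' @param tol time-matching tolerance in hours.
#' @return combined \linkS4class{VolumeSeries}.
#' @export
combineAngles <- function(a, b, tol = 1e-6) {
  stopifnot(is(a, "VolumeSeries"), is(b, "VolumeSeries"))
  if (a@fishId != b@fishId) stop("series belong to different fish")
  if (a@region != b@region) stop("series belong to different regions")
  ia <- integer(0); ib <- integer(0)
  for (i in seq_along(a@times)) {
    j <- which(abs(b@times - a@times[i]) <= tol)[1]
    if (!is.na(j)) { ia <- c(ia, i); ib <- c(ib, j) }
  }
  if (length(ia) == 0) stop("series share no timepoints")
  dropped <- (length(a@times) - length(ia)) + (length(b@times) - length(ib))
  if (dropped > 0)
    warning(dropped, " unmatched timepoint(s) dropped when combining angles")
  VolumeSeries(times = a@times[ia],
               volumes = (a@volumes[ia] + b@volumes[ib]) / 2,
               fishId = a@fishId, region = a@region,
               angleIds = unique(c(a@angleIds, b@angleIds)))
}

#' Shift a volume series along the time axis
#'
#' Applies the per-fish temporal alignment offset determined from an
#' anatomical landmark (the anastomosis of the left and right
#' primordial hindbrain channels) so different fish share one
#' developmental time base. Volumes are untouched.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param shiftHours hours to add to every timepoint.
#' @return the shifted \linkS4class{VolumeSeries}.
#' @export
alignTime <- function(series, shiftHours) {
  stopifnot(is(series, "VolumeSeries"), is.finite(shiftHours))
  VolumeSeries(times = series@times + shiftHours, volumes = series@volumes,
               fishId = series@fishId, region = series@region,
               angleIds = series@angleIds)
}

#' Write a volume series table
#'
#' @param seriesList list of \linkS4class{VolumeSeries}.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
writeVolumeSeries <- function(seriesList, path) {
  if (is(seriesList, "VolumeSeries")) seriesList <- list(seriesList)
  df <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(fish_id = s@fishId, region = s@region, time_hpf = s@times,
               volume_um3 = s@volumes,
               n_angles = max(1L, length(s@angleIds)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a volume series table
#'
#' @param path CSV written by \code{\link{writeVolumeSeries}}.
#' @return list of \linkS4class{VolumeSeries}, one per fish/region.
#' @export
readVolumeSeries <- function(path) {
  df <- utils::read.csv(path)
  keys <- unique(df[, c("fish_id", "region")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$fish_id == keys$fish_id[i] & df$region == keys$region[i], ]
    sub <- sub[order(sub$time_hpf), ]
    VolumeSeries(times = sub$time_hpf, volumes = sub$volume_um3,
                 fishId = as.character(keys$fish_id[i]),
                 region = as.character(keys$region[i]))
  })
}
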