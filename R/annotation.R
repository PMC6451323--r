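# Backward ROI propagation on maximum-intensity-projection time series.
# A region drawn at the last timepoint is tracked back in time: every
# boundary point is matched by zero-normalized cross-correlation of a
# small template (70 px) inside a concentric search window (140 px) of
# the previous frame; per-point shifts are regularized by a median over
# seven neighbouring boundary points, and points falling onto the same
# or neighbouring pixels are merged.

#' Normalized cross-correlation template matching
#'
#' Zero-normalized cross-correlation (ZNCC) of the template over all
#' valid placements in the search image, computed with FFT
#' cross-correlation and integral-image local statistics. Ties are
#' broken by the smallest displacement from the search-image centre,
#' then row-major order. A zero-variance template cannot be matched and
#' is flagged degenerate with zero displacement.
#'
#' @param search 2D numeric matrix.
#' @param template 2D numeric matrix, strictly smaller than search.
#' @return list with \code{position} (y, x of the template centre in
#'   search coordinates), \code{score} and \code{degenerate}.
#' @export
matchTemplate <- function(search, template) {
  H <- nrow(search); W <- ncol(search)
  h <- nrow(template); w <- ncol(template)
  if (h >= H && w >= W) stop("template must be strictly smaller than search")
  if (h > H || w > W) stop("template does not fit in search image")
  n <- h * w
  ctr <- c(floor((h - 1) / 2) + 1, floor((w - 1) / 2) + 1) # centre within template
  mT <- mean(template)
  sT <- sqrt(max(sum((template - mT)^2), 0))
  if (sT == 0) {
    pos <- c(floor((H - 1) / 2) + 1, floor((W - 1) / 2) + 1)
    return(list(position = pos, score = NA_real_, degenerate = TRUE))
  }
  # FFT cross-correlation: sum over the window of search * template
  pad <- matrix(0, H, W)
  pad[1:h, 1:w] <- template
  cc <- Re(stats::fft(stats::fft(search) * Conj(stats::fft(pad)),
                      inverse = TRUE)) / (H * W)
  cc <- cc[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
  s1 <- .localWindowSums(search, h, w)
  s2 <- .localWindowSums(search^2, h, w)
  varS <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(varS) * sT
  znccNum <- cc - s1 * mT
  zncc <- ifelse(denom > 1e-12, znccNum / denom, -Inf)
  best <- max(zncc)
  hits <- which(zncc >= best - 1e-12, arr.ind = TRUE)
  if (nrow(hits) > 1) {
    centres <- cbind(hits[, 1] + ctr[1] - 1, hits[, 2] + ctr[2] - 1)
    mid <- c((H + 1) / 2, (W + 1) / 2)
    disp <- pmax(abs(centres[, 1] - mid[1]), abs(centres[, 2] - mid[2]))
    hits <- hits[order(disp, hits[, 1], hits[, 2]), , drop = FALSE]
  }
  topLeft <- unname(hits[1, ])
  list(position = c(topLeft[1] + ctr[1] - 1, topLeft[2] + ctr[2] - 1),
       score = best, degenerate = FALSE)
}

#' Regularize boundary-point shifts by a running median
#'
#' Componentwise median over a centred circular window of seven
#' boundary points (the point itself and three neighbours each side);
#' boundaries shorter than the window use the global median.
#'
#' @param shifts numeric matrix (m x 2) of raw per-point shift vectors.
#' @param window window length (default 7).
#' @return numeric matrix (m x 2) of effective shifts.
#' @export
regularizeShifts <- function(shifts, window = 7) {
  shifts <- as.matrix(shifts)
  m <- nrow(shifts)
  if (m == 0) stop("need at least one shift")
  if (m < window) {
    med <- apply(shifts, 2, stats::median)
    return(matrix(rep(med, each = m), m, ncol(shifts)))
  }
  half <- (window - 1) %/% 2
  out <- shifts
  for (i in seq_len(m)) {
    idx <- ((i - half - 1):(i + half - 1)) %% m + 1
    out[i, ] <- apply(shifts[idx, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Merge boundary points on identical or neighbouring pixels
#'
#' Scans the boundary in order and drops every point whose pixel equals
#' or is 8-adjacent to the previously kept point. A boundary reduced
#' below three points has collapsed and raises an error.
#'
#' @param points numeric matrix (m x 2) of (y, x) coordinates.
#' @return reduced matrix of points.
#' @export
mergeBoundaryPoints <- function(points) {
  points <- as.matrix(points)
  keep <- 1L
  for (i in seq_len(nrow(points))[-1]) {
    last <- points[keep[length(keep)], ]
    if (max(abs(round(points[i, ]) - round(last))) > 1)
      keep <- c(keep, i)
  }
  if (length(keep) < 3)
    stop("ROI collapsed: fewer than 3 boundary points remain after merging")
  points[keep, , drop = FALSE]
}

# crop a window of target size `size` centred at `centre`, clipped to the
# image; returns the matrix and the (y, x) of its top-left in image coords
.cropWindow <- function(img, centre, size) {
  half <- floor((size - 1) / 2)
  lo <- pmax(1, round(centre) - half)
  hi <- pmin(dim(img), lo + size - 1)
  lo <- pmax(1, hi - size + 1) # re-expand if clipped at the far side
  list(win = img[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE], topLeft = lo)
}

#' Propagate an ROI backward through a projection time series
#'
#' Starting from the region of interest drawn at the last timepoint,
#' sequentially determines the ROI at time t-1 from the ROI at time t:
#' for every boundary point a template (default 70 x 70 px, concentric
#' around the point) is cut from frame t and matched inside a search
#' window (default 140 x 140 px) of frame t-1; the raw shifts are
#' regularized with the median over seven neighbouring points, applied,
#' and coinciding points merged. Windows reaching beyond the image are
#' clipped.
#'
#' @param mipSeries list of 2D matrices ordered by time.
#' @param roiAtLast \linkS4class{BoundaryRoi} at the final timepoint.
#' @param templateSize,searchSize window edge lengths in pixels.
#' @return list of \linkS4class{BoundaryRoi}, one per timepoint.
#' @export
propagateRoi <- function(mipSeries, roiAtLast, templateSize = 70,
                         searchSize = 140) {
  stopifnot(is.list(mipSeries), length(mipSeries) >= 1,
            is(roiAtLast, "BoundaryRoi"))
  T <- length(mipSeries)
  rois <- vector("list", T)
  rois[[T]] <- BoundaryRoi(roiAtLast@points, T)
  if (T == 1) return(rois)
  for (t in T:2) {
    cur <- rois[[t]]@points
    prev <- mipSeries[[t - 1]]
    now <- mipSeries[[t]]
    raw <- matrix(0, nrow(cur), 2)
    for (i in seq_len(nrow(cur))) {
      p <- cur[i, ]
      tw <- .cropWindow(now, p, templateSize)
      sw <- .cropWindow(prev, p, searchSize)
      m <- matchTemplate(sw$win, tw$win)
      if (m$degenerate) next
      # map: the template centre corresponds to point p; its offset
      # inside the (possibly clipped) template window
      tplCentre <- round(p) - tw$topLeft + 1
      tplMid <- c(floor((nrow(tw$win) - 1) / 2) + 1,
                  floor((ncol(tw$win) - 1) / 2) + 1)
      matchGlobal <- sw$topLeft - 1 + m$position + (tplCentre - tplMid)
      raw[i, ] <- matchGlobal - round(p)
    }
    eff <- regularizeShifts(raw)
    moved <- cur + eff
    moved[, 1] <- pmin(pmax(moved[, 1], 1), nrow(prev))
    moved[, 2] <- pmin(pmax(moved[, 2], 1), ncol(prev))
    merged <- tryCatch(mergeBoundaryPoints(moved), error = function(e)
      stop("ROI collapsed while propagating to timepoint ", t - 1, ": ",
           conditionMessage(e), call. = FALSE))
    rois[[t - 1]] <- BoundaryRoi(merged, t - 1)
  }
  rois
}

#' Rasterize a polygonal ROI to a label mask
#'
#' Marks pixels whose centres fall inside the closed boundary polygon.
#'
#' @param roi a \linkS4class{BoundaryRoi}.
#' @param dim image size c(rows, cols).
#' @param label integer written into the mask (default 1).
#' @return integer matrix of 0/label.
#' @export
rasterizeRoi <- function(roi, dim, label = 1L) {
  stopifnot(is(roi, "BoundaryRoi"), length(dim) == 2)
  pts <- roi@points
  bnd <- list(x = c(pts[, 2], pts[1, 2]), y = c(pts[, 1], pts[1, 1]))
  grid <- expand.grid(y = seq_len(dim[1]), x = seq_len(dim[2]))
  inside <- mgcv::in.out(cbind(bnd$x, bnd$y), cbind(grid$x, grid$y))
  matrix(ifelse(inside, as.integer(label), 0L), dim[1], dim[2])
}

#' Write ROIs as a CSV polygon table
#' @param rois list of \linkS4class{BoundaryRoi}.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
writeRoiCsv <- function(rois, path) {
  if (is(rois, "BoundaryRoi")) rois <- list(rois)
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(timepoint = r@timepoint,
               vertex_index = seq_len(nrow(r@points)),
               y = r@points[, 1], x = r@points[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read ROIs from a CSV polygon table
#' @param path CSV written by \code{\link{writeRoiCsv}}.
#' @return list of \linkS4class{BoundaryRoi} ordered by timepoint.
#' @export
readRoiCsv <- function(path) {
  df <- utils::read.csv(path)
  lapply(sort(unique(df$timepoint)), function(tp) {
    sub <- df[df$timepoint == tp, ]
    sub <- sub[order(sub$vertex_index), ]
    BoundaryRoi(cbind(sub$y, sub$x), tp)
  })
}
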