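# Mosaic stitching: pairwise phase-correlation registration initialised
# from stage positions, global least-squares placement, and
# linear-blending fusion. Registration runs on maximum-intensity
# projections and the resulting in-plane offsets are applied to the 3D
# stacks. Offsets are integer voxels throughout: stage repeatability is
# sub-pixel, and segmentation masks must stay binary.

#' Maximum intensity projection
#'
#' @param volume 3D numeric array \code{[z, y, x]}.
#' @param axis axis to project along (default 1 = z).
#' @return 2D matrix of per-pixel maxima.
#' @export
maxProject <- function(volume, axis = 1) {
  .stopIfNot3d(volume)
  stopifnot(axis %in% 1:3)
  apply(volume, setdiff(1:3, axis), max)
}

# real-space normalized cross-correlation of the overlap implied by an
# integer offset d (origin of b minus origin of a); NA when the overlap
# is too small or constant
.overlapNcc <- function(a, b, d, minFrac = 0.1) {
  da <- dim(a); db <- dim(b)
  lo <- pmax(1, 1 + d)            # overlap range in a's frame
  hi <- pmin(da, db + d)
  if (any(hi - lo + 1 <= 0)) return(NA_real_)
  if (prod(hi - lo + 1) < minFrac * min(prod(da), prod(db))) return(NA_real_)
  idxA <- mapply(function(l, h) l:h, lo, hi, SIMPLIFY = FALSE)
  idxB <- mapply(function(l, h, off) (l - off):(h - off), lo, hi, d,
                 SIMPLIFY = FALSE)
  va <- as.numeric(do.call(`[`, c(list(a), idxA)))
  vb <- as.numeric(do.call(`[`, c(list(b), idxB)))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Pairwise offset by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and
#' evaluates its strongest peaks (with wrap-around disambiguation)
#' within \code{searchRadius} of the stage-derived initial offset.
#' Candidates are ranked by real-space normalized cross-correlation of
#' the implied overlap. If no candidate lies within the radius, or the
#' best correlation falls below \code{scoreFloor}, the initial offset is
#' returned flagged unreliable.
#'
#' @param a,b numeric arrays of equal dimensionality (2D or 3D).
#' @param initOffset integer vector, initial guess for origin(b) -
#'   origin(a).
#' @param searchRadius Chebyshev radius around \code{initOffset} (px).
#' @param scoreFloor minimal correlation to accept a peak (default 0.3).
#' @param nPeaks number of spectrum peaks to examine.
#' @return list with \code{offset}, \code{score} and \code{reliable}.
#' @export
phaseCorrelationOffset <- function(a, b, initOffset = NULL, searchRadius = 20,
                                   scoreFloor = 0.3, nPeaks = 8) {
  da <- dim(a)
  stopifnot(!is.null(da), identical(length(da), length(dim(b))))
  nd <- length(da)
  if (is.null(initOffset)) initOffset <- rep(0, nd)
  # phase correlation needs a common grid: pad both to the larger extent
  dmax <- pmax(da, dim(b))
  pad <- function(x) {
    out <- array(0, dmax)
    idx <- lapply(dim(x), seq_len)
    do.call(`[<-`, c(list(out), idx, list(x)))
  }
  fa <- stats::fft(pad(a))
  fb <- stats::fft(pad(b))
  cross <- fa * Conj(fb)
  r <- Re(stats::fft(cross / pmax(Mod(cross), .Machine$double.eps),
                     inverse = TRUE)) / prod(dmax)
  ord <- order(r, decreasing = TRUE)[seq_len(min(nPeaks, length(r)))]
  cands <- list()
  for (p in ord) {
    p0 <- arrayInd(p, dmax) - 1L # 0-based circular shift
    # each dimension is ambiguous modulo the padded extent
    alts <- lapply(seq_len(nd), function(k) unique(c(p0[k], p0[k] - dmax[k])))
    grid <- as.matrix(expand.grid(alts))
    for (i in seq_len(nrow(grid))) {
      d <- as.integer(grid[i, ])
      if (max(abs(d - initOffset)) <= searchRadius)
        cands[[length(cands) + 1]] <- d
    }
  }
  cands <- unique(cands)
  best <- NULL
  for (d in cands) {
    s <- .overlapNcc(a, b, d)
    if (!is.na(s) && (is.null(best) || s > best$score))
      best <- list(offset = d, score = s)
  }
  if (is.null(best) || best$score < scoreFloor) {
    return(list(offset = as.integer(round(initOffset)),
                score = if (is.null(best)) NA_real_ else best$score,
                reliable = FALSE))
  }
  c(best, list(reliable = TRUE))
}

#' Global tile placement from pairwise offsets
#'
#' The first tile is fixed at the origin; the remaining positions
#' minimise the score-weighted squared deviation from the pairwise
#' offsets (independent linear least squares per dimension). Unreliable
#' pairs fall back to their nominal displacement with low weight. A
#' disconnected adjacency graph is an error naming the components.
#'
#' @param pairs data.frame with columns \code{i}, \code{j}, a matrix (or
#'   columns) of per-dimension offsets \code{offset}, \code{score} and
#'   \code{reliable}.
#' @param nominalPositions numeric matrix (n x d) of stage positions in
#'   voxels.
#' @param fallbackWeight weight given to unreliable pairs.
#' @return integer matrix (n x d) of refined positions, tile 1 at 0.
#' @export
globalizeOffsets <- function(pairs, nominalPositions, fallbackWeight = 0.05) {
  n <- nrow(nominalPositions)
  nd <- ncol(nominalPositions)
  stopifnot(nrow(pairs) >= 1)
  g <- igraph::graph_from_edgelist(cbind(pairs$i, pairs$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    grp <- split(seq_len(n), comp$membership)
    stop("tile adjacency graph is disconnected; components: ",
         paste(vapply(grp, function(v) paste(v, collapse = ","),
                      character(1)), collapse = " | "))
  }
  off <- pairs$offset
  if (is.null(dim(off))) off <- matrix(off, ncol = nd)
  w <- ifelse(pairs$reliable, pmax(pairs$score, 1e-3), fallbackWeight)
  for (q in which(!pairs$reliable)) {
    off[q, ] <- nominalPositions[pairs$j[q], ] - nominalPositions[pairs$i[q], ]
  }
  pos <- matrix(0, n, nd)
  if (n > 1) {
    # design over x_2..x_n (x_1 = 0)
    A <- matrix(0, nrow(pairs), n - 1)
    for (q in seq_len(nrow(pairs))) {
      if (pairs$j[q] > 1) A[q, pairs$j[q] - 1] <- 1
      if (pairs$i[q] > 1) A[q, pairs$i[q] - 1] <- -1
    }
    sw <- sqrt(w)
    Aw <- A * sw
    for (k in seq_len(nd)) {
      x <- qr.solve(Aw, off[, k] * sw)
      pos[2:n, k] <- x
    }
  }
  matrix(as.integer(round(pos)), n, nd)
}

#' Fuse tiles by linear blending
#'
#' Each output voxel is the weighted mean of the contributing tiles;
#' the weight of a tile at a voxel is its distance-to-border ramp (the
#' minimal distance to any tile border, plus one), so seams fade
#' linearly and voxels covered by a single tile are copied unchanged.
#'
#' @param tiles list of numeric arrays of equal dimensionality.
#' @param positions integer matrix (n x d) of tile-origin offsets.
#' @return fused array covering the bounding box of all tiles.
#' @export
fuseLinearBlending <- function(tiles, positions) {
  stopifnot(length(tiles) >= 1, nrow(positions) == length(tiles))
  nd <- length(dim(tiles[[1]]))
  positions <- unname(as.matrix(positions))
  positions <- sweep(positions, 2, apply(positions, 2, min)) # shift to 0
  ext <- apply(vapply(seq_along(tiles),
                      function(i) positions[i, ] + dim(tiles[[i]]),
                      numeric(nd)), 1, max)
  num <- array(0, ext)
  den <- array(0, ext)
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    dt <- dim(t)
    ramps <- lapply(dt, function(n) {
      idx <- seq_len(n)
      pmin(idx, n + 1 - idx)
    })
    w <- Reduce(function(acc, k) {
      sweep(acc, k, ramps[[k]], pmin)
    }, seq_len(nd), accumulate = FALSE,
    init = array(Inf, dt))
    idx <- lapply(seq_len(nd), function(k) positions[i, k] + seq_len(dt[k]))
    num <- do.call(`[<-`, c(list(num), idx,
      list(do.call(`[`, c(list(num), idx)) + w * t)))
    den <- do.call(`[<-`, c(list(den), idx,
      list(do.call(`[`, c(list(den), idx)) + w)))
  }
  out <- num / pmax(den, .Machine$double.eps)
  out[den == 0] <- 0
  out
}

#' Stitch a tile set
#'
#' For 3D tiles, registration runs on the z maximum-intensity
#' projections and the refined in-plane (y, x) offsets are applied to
#' the stacks, with z offsets taken from the nominal stage positions;
#' 2D tiles are registered directly. Pairwise offsets come from
#' \code{\link{phaseCorrelationOffset}} initialised at the nominal
#' displacement, global placement from \code{\link{globalizeOffsets}},
#' and fusion from \code{\link{fuseLinearBlending}}.
#'
#' @param tileSet a \linkS4class{TileSet}.
#' @param searchRadius,scoreFloor see \code{\link{phaseCorrelationOffset}}.
#' @return list with \code{fused} (array), \code{positions} (refined,
#'   tile 1 at origin) and the updated \code{tileSet}.
#' @export
stitchDataset <- function(tileSet, searchRadius = 20, scoreFloor = 0.3) {
  stopifnot(is(tileSet, "TileSet"))
  tiles <- tileSet@tiles
  nom <- tileSet@nominalPositions
  nd <- length(dim(tiles[[1]]))
  n <- length(tiles)
  if (n == 1) {
    pos <- matrix(0L, 1, nd)
    tileSet@refinedPositions <- pos
    return(list(fused = tiles[[1]], positions = pos, tileSet = tileSet))
  }
  is3d <- nd == 3
  imgs <- if (is3d) lapply(tiles, maxProject, axis = 1) else tiles
  nomReg <- if (is3d) nom[, 2:3, drop = FALSE] else nom

  adj <- tileSet@adjacency
  if (nrow(adj) == 0) adj <- cbind(seq_len(n - 1), 2:n)
  res <- lapply(seq_len(nrow(adj)), function(q) {
    i <- adj[q, 1]; j <- adj[q, 2]
    init <- nomReg[j, ] - nomReg[i, ]
    phaseCorrelationOffset(imgs[[i]], imgs[[j]], initOffset = init,
                           searchRadius = searchRadius,
                           scoreFloor = scoreFloor)
  })
  pairs <- data.frame(i = adj[, 1], j = adj[, 2])
  pairs$offset <- t(vapply(res, function(r) as.numeric(r$offset),
                           numeric(ncol(nomReg))))
  pairs$score <- vapply(res, function(r)
    ifelse(is.na(r$score), 0, r$score), numeric(1))
  pairs$reliable <- vapply(res, function(r) r$reliable, logical(1))
  reg <- globalizeOffsets(pairs, nomReg)
  pos <- if (is3d) {
    cbind(as.integer(round(nom[, 1] - nom[1, 1])), reg)
  } else reg
  dimnames(pos) <- NULL
  tileSet@refinedPositions <- pos
  list(fused = fuseLinearBlending(tiles, pos), positions = pos,
       tileSet = tileSet)
}
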