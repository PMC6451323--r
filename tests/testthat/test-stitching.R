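test_that("max projection behaves on constant, sparse and shifted volumes", {
  v <- array(3, c(4, 5, 6))
  expect_equal(maxProject(v, 1), matrix(3, 5, 6))
  s <- array(0, c(4, 5, 6))
  s[2, 3, 4] <- 9
  p <- maxProject(s, 1)
  expect_equal(sum(p > 0), 1)
  expect_equal(p[3, 4], 9)
})

test_that("phase correlation recovers constructed shifts and the identity", {
  set.seed(1)
  a <- matrix(runif(64 * 64), 64, 64)
  idn <- phaseCorrelationOffset(a, a, c(0, 0), 10)
  expect_equal(idn$offset, c(0L, 0L))
  expect_equal(idn$score, 1, tolerance = 1e-10)
  b <- a[c(6:64, 1:5), c(62:64, 1:61)] # b[i, j] = a[i + 5, j - 3]
  r <- phaseCorrelationOffset(a, b, c(0, 0), 10)
  expect_equal(r$offset, c(5L, -3L))
  expect_gt(r$score, 0.99)
  expect_true(r$reliable)
})

test_that("pure-noise pairs are flagged unreliable", {
  unreliable <- vapply(1:10, function(s) {
    set.seed(s)
    a <- matrix(rnorm(48 * 48), 48, 48)
    b <- matrix(rnorm(48 * 48), 48, 48)
    !phaseCorrelationOffset(a, b, c(0, 0), 5)$reliable
  }, logical(1))
  expect_gte(mean(unreliable), 0.9)
})

test_that("globalization solves chains exactly and cycles like the oracle", {
  # two tiles, one reliable pair
  pairs <- data.frame(i = 1, j = 2)
  pairs$offset <- matrix(c(0, 70), 1)
  pairs$score <- 0.9
  pairs$reliable <- TRUE
  nom <- matrix(c(0, 0, 0, 68), 2, 2, byrow = TRUE)
  expect_equal(globalizeOffsets(pairs, nom),
               matrix(c(0L, 0L, 0L, 70L), 2, 2, byrow = TRUE))

  # consistent chain of three recovers exactly
  pairs <- data.frame(i = c(1, 2), j = c(2, 3))
  pairs$offset <- rbind(c(0, 70), c(0, 72))
  pairs$score <- c(0.9, 0.8)
  pairs$reliable <- c(TRUE, TRUE)
  nom <- matrix(0, 3, 2)
  expect_equal(globalizeOffsets(pairs, nom)[, 2], c(0L, 70L, 142L))

  # inconsistent 3-cycle matches a dense weighted normal-equations solve
  pairs <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3))
  pairs$offset <- rbind(c(0, 70), c(0, 70), c(0, 141)) # +1 voxel on the long edge
  pairs$score <- c(1, 1, 1)
  pairs$reliable <- rep(TRUE, 3)
  got <- globalizeOffsets(pairs, matrix(0, 3, 2))
  A <- rbind(c(1, 0), c(-1, 1), c(0, 1))
  oracle <- solve(crossprod(A), crossprod(A, c(70, 70, 141)))
  expect_equal(got[2:3, 2], as.integer(round(oracle)))

  # disconnected graphs are reported with their components
  bad <- data.frame(i = 1, j = 2)
  bad$offset <- matrix(c(0, 10), 1)
  bad$score <- 1
  bad$reliable <- TRUE
  expect_error(globalizeOffsets(bad, matrix(0, 4, 2)), "disconnected")
})

test_that("linear blending fuses constants exactly and midpoints symmetrically", {
  one <- matrix(5, 20, 30)
  expect_equal(fuseLinearBlending(list(one), matrix(0, 1, 2)), one)
  # two identical constant tiles: constant result everywhere
  f <- fuseLinearBlending(list(one, one), rbind(c(0, 0), c(0, 15)))
  expect_true(all(abs(f - 5) < 1e-12))
  # tiles of 0 and 100 with an odd symmetric overlap: midpoint is 50
  a <- matrix(0, 21, 41); b <- matrix(100, 21, 41)
  f2 <- fuseLinearBlending(list(a, b), rbind(c(0, 0), c(0, 20)))
  expect_equal(f2[11, 31], 50) # centre of the 21-41 overlap columns
  # intensity range is conserved
  expect_true(all(f2 >= 0 & f2 <= 100))
})

test_that("synthetic tile sets are stitched back exactly (10 seeds)", {
  set.seed(123)
  src <- matrix(runif(120 * 260), 120, 260)
  for (s in 1:10) {
    ts <- generateTileSet(src, 3, 0.3, jitterPx = 5, seed = s)
    st <- stitchDataset(ts, searchRadius = 12)
    expect_equal(st$positions, ts@truePositions,
                 info = paste("seed", s))
  }
})

test_that("3D stitching registers on projections and fuses losslessly", {
  set.seed(77)
  vol <- array(runif(30 * 50 * 180), c(30, 50, 180))
  ts <- generateTileSet(vol, 3, 0.3, jitterPx = 3, seed = 4)
  st <- stitchDataset(ts, searchRadius = 10)
  expect_equal(st$positions, ts@truePositions)
  d <- dim(st$fused)
  expect_equal(st$fused, vol[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])])
  # single tile and zero jitter degenerate cases
  one <- generateTileSet(vol, 1, 0.3)
  expect_identical(stitchDataset(one)$fused, vol)
  nz <- generateTileSet(vol, 3, 0.3, jitterPx = 0, seed = 1)
  expect_equal(stitchDataset(nz, searchRadius = 10)$positions,
               nz@nominalPositions)
})
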