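test_that("luminal proxy handles empty, flat and rescaled inputs", {
  zero <- ChannelVolume(array(0, c(8, 8, 8)), c(1, 1, 1), "rbc")
  expect_warning(m <- luminalProxy(zero), "flat")
  expect_false(any(maskVoxels(m)))

  ph <- smallPhantom()
  m1 <- maskVoxels(luminalProxy(ph@rbc, 2))
  # affine intensity rescaling leaves the Otsu mask unchanged
  rbc2 <- ChannelVolume(intensities(ph@rbc) * 3 + 10, voxelSpacing(ph@rbc),
                        "rbc")
  m2 <- maskVoxels(luminalProxy(rbc2, 2))
  expect_identical(m1, m2)
  expect_error(luminalProxy(ph@endothelial), "rbc")
})

test_that("training sampling is seeded, without replacement, with shortfall", {
  ph <- smallPhantom()
  lum <- luminalProxy(ph@rbc, 2)
  tr <- sampleTrainingPoints(ph@endothelial, lum, N = 500, seed = 3)
  expect_equal(sum(tr@labels == 1), 500)
  expect_equal(sum(tr@labels == 0), 500)
  expect_false(tr@shortfall)
  expect_equal(anyDuplicated(tr@coords), 0)
  tr2 <- sampleTrainingPoints(ph@endothelial, lum, N = 500, seed = 3)
  expect_identical(tr@coords, tr2@coords)
  tr3 <- sampleTrainingPoints(ph@endothelial, lum, N = 500, seed = 4)
  expect_false(identical(tr@coords, tr3@coords))

  # empty lumen mask: zero positives, shortfall flagged
  empty <- BinaryMask(array(FALSE, dim(ph@endothelial)),
                      voxelSpacing(ph@endothelial))
  trE <- sampleTrainingPoints(ph@endothelial, empty, N = 100, seed = 1)
  expect_true(trE@shortfall)
  expect_equal(sum(trE@labels == 1), 0)
})

test_that("SVD weights match the dense pseudo-inverse oracle", {
  ph <- smallPhantom()
  fs <- computeFeatureStack(ph@endothelial)
  lum <- luminalProxy(ph@rbc, 2)
  tr <- sampleTrainingPoints(ph@endothelial, lum, N = 2000, seed = 0)
  mod <- fitFeatureWeights(fs, tr)
  d <- dim(ph@endothelial)
  lin <- tr@coords[, 1] + (tr@coords[, 2] - 1) * d[1] +
    (tr@coords[, 3] - 1) * d[1] * d[2]
  X <- cbind(vapply(fs@features, function(f) f[lin], numeric(length(lin))), 1)
  w <- pinvOracle(X, as.numeric(tr@labels))
  expect_equal(unname(modelWeights(mod)), w, tolerance = 1e-8)

  # rank-deficient system: duplicated feature column still matches oracle
  X2 <- X
  X2[, 5] <- X2[, 1]
  sv <- svd(X2)
  tol <- max(dim(X2)) * .Machine$double.eps * sv$d[1]
  dInv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  wSvd <- as.numeric(sv$v %*% (dInv * crossprod(sv$u, tr@labels)))
  expect_equal(wSvd, pinvOracle(X2, as.numeric(tr@labels)), tolerance = 1e-8)
})

test_that("weight fitting recovers an exact linear target and label symmetry", {
  ph <- smallPhantom()
  fs <- computeFeatureStack(ph@endothelial)
  set.seed(8)
  lin <- sample(length(intensities(ph@endothelial)), 400)
  coords <- arrayInd(lin, dim(ph@endothelial))
  colnames(coords) <- c("z", "y", "x")
  # target equal to the standardized raw feature: weight 1 on raw, 0 rest
  yRaw <- fs@features$raw[lin]
  labs <- as.integer(yRaw > median(yRaw))
  tr <- new("TrainingSet", coords = coords, labels = labs,
            nPerClass = 200L, shortfall = FALSE, seed = 8L)
  mod <- fitFeatureWeights(fs, tr)
  X <- cbind(vapply(fs@features, function(f) f[lin], numeric(400)), 1)
  # swapped labels give complementary predictions (bias column linearity)
  trSwap <- new("TrainingSet", coords = coords, labels = 1L - labs,
                nPerClass = 200L, shortfall = FALSE, seed = 8L)
  modSwap <- fitFeatureWeights(fs, trSwap)
  expect_equal(as.numeric(X %*% modelWeights(modSwap)),
               1 - as.numeric(X %*% modelWeights(mod)), tolerance = 1e-8)
  # single-class training is rejected
  trOne <- new("TrainingSet", coords = coords,
               labels = rep(1L, 400), nPerClass = 400L,
               shortfall = TRUE, seed = 8L)
  expect_error(fitFeatureWeights(fs, trOne), "single class")
})

test_that("scoring is the linear combination it claims to be", {
  ph <- smallPhantom()
  fs <- computeFeatureStack(ph@endothelial)
  mod <- new("SegmentationModel", weights = c(rep(0, 6), 2.5),
             featureMeans = fs@means, featureSds = fs@sds,
             scoreThreshold = NA_real_, trainingSummary = list())
  sc <- scoreVolume(fs, mod)
  expect_true(all(sc == 2.5))
  # doubling weights and bias doubles the score
  w <- c(0.3, -0.1, 0.2, 0.05, -0.4, 0.6, 1)
  m1 <- new("SegmentationModel", weights = w, featureMeans = fs@means,
            featureSds = fs@sds, scoreThreshold = NA_real_,
            trainingSummary = list())
  m2 <- new("SegmentationModel", weights = 2 * w, featureMeans = fs@means,
            featureSds = fs@sds, scoreThreshold = NA_real_,
            trainingSummary = list())
  expect_equal(scoreVolume(fs, m2), 2 * scoreVolume(fs, m1), tolerance = 1e-12)
})

test_that("triangle threshold matches the worked example and the oracle", {
  expect_equal(triangleThreshold(c(100, 0, 0, 0, 10))$bin, 1L)
  # a symmetric histogram gives the same threshold after mirroring
  h <- c(1, 5, 20, 5, 1)
  expect_equal(triangleThreshold(h)$bin, triangleThreshold(rev(h))$bin)
  # single spike is degenerate
  spike <- c(0, 0, 7, 0)
  res <- triangleThreshold(spike)
  expect_true(res$degenerate)
  expect_equal(res$bin, 2L)
  # 50 random histograms against the independent geometric oracle
  set.seed(42)
  for (i in 1:50) {
    n <- sample(8:64, 1)
    counts <- rpois(n, lambda = rexp(n, 1 / 50))
    if (sum(counts > 0) < 2) counts[c(1, n)] <- c(5, 3)
    expect_equal(triangleThreshold(counts)$bin, triangleOracle(counts),
                 info = paste("histogram", i))
  }
})

test_that("morphological opening removes single voxels, keeps solids", {
  m <- array(FALSE, c(16, 16, 16))
  m[3, 3, 3] <- TRUE              # isolated voxel
  m[6:15, 6:15, 6:15] <- TRUE     # solid cube
  cleaned <- maskVoxels(morphologicalCleanup(BinaryMask(m, c(1, 1, 1))))
  expect_false(cleaned[3, 3, 3])
  expect_true(all(cleaned[7:14, 7:14, 7:14])) # interior untouched
  expect_true(all(cleaned[10, 6:15, 10]))     # face centres survive
  expect_true(all(!cleaned | m))              # opening is anti-extensive
  # empty mask stays empty
  e <- BinaryMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_false(any(maskVoxels(morphologicalCleanup(e))))
})

test_that("full segmentation is deterministic and fails cleanly without RBC", {
  ph <- smallPhantom()
  cfg <- segmentationConfig(N = 1500, seed = 2)
  s1 <- segmentVolume(ph@endothelial, ph@rbc, cfg)
  s2 <- segmentVolume(ph@endothelial, ph@rbc, cfg)
  expect_identical(maskVoxels(s1$mask), maskVoxels(s2$mask))
  expect_identical(modelWeights(s1$model), modelWeights(s2$model))

  zeroRbc <- ChannelVolume(array(0, dim(ph@endothelial)),
                           voxelSpacing(ph@endothelial), "rbc")
  expect_error(suppressWarnings(
    segmentVolume(ph@endothelial, zeroRbc, cfg)), "sampling")
})

test_that("segmentation quality degrades monotonically with noise on average", {
  sigmas <- c(0, 8, 25)
  mean_dice <- sapply(sigmas, function(sg) {
    mean(sapply(c(3, 9), function(seed) {
      ph <- smallPhantom(seed = seed, noiseSigma = sg)
      seg <- segmentVolume(ph@endothelial, ph@rbc,
                           segmentationConfig(N = 2000, seed = 0))
      diceCoef(maskVoxels(seg$mask), ph@truthVessel)
    }))
  })
  expect_true(all(diff(mean_dice) <= 0.02))
  expect_gt(mean_dice[1], mean_dice[3])
})
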