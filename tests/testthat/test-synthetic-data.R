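test_that("phantom with no vessels is pure noise with empty truth", {
  ph <- generateVesselPhantom(phantomSpec(shape = c(16, 16, 16),
    nVessels = 0, radiusRange = c(3, 3.5), wallThickness = 1.5,
    noiseSigma = 2, seed = 5))
  expect_false(any(ph@truthVessel))
  expect_false(any(ph@truthLumen))
  expect_gt(sd(intensities(ph@endothelial)), 0)
})

test_that("phantom generation is voxel-identical for a fixed seed", {
  s <- phantomSpec(shape = c(24, 24, 24), nVessels = 1,
                   radiusRange = c(4, 5), wallThickness = 2, seed = 11)
  a <- generateVesselPhantom(s)
  b <- generateVesselPhantom(s)
  expect_identical(intensities(a@endothelial), intensities(b@endothelial))
  expect_identical(intensities(a@rbc), intensities(b@rbc))
  expect_identical(a@truthLumen, b@truthLumen)
})

test_that("truth masks are disjoint and vessel = wall union lumen", {
  ph <- smallPhantom()
  expect_false(any(ph@truthWall & ph@truthLumen))
  expect_identical(ph@truthVessel, ph@truthWall | ph@truthLumen)
})

test_that("noise-free RBC speckles lie inside the true lumen", {
  ph <- generateVesselPhantom(phantomSpec(shape = c(48, 48, 48),
    nVessels = 1, radiusRange = c(7, 8), curvature = 0,
    noiseSigma = 0, seed = 2))
  rbc <- intensities(ph@rbc)
  # the brightest RBC voxels (speckle cores) must be luminal
  if (max(rbc) > 0) {
    core <- rbc > 0.5 * max(rbc)
    expect_gte(sum(core & ph@truthLumen) / sum(core), 0.95)
  }
  # and the luminal proxy derived from them stays in the lumen
  lum <- maskVoxels(luminalProxy(ph@rbc, 2))
  expect_gte(sum(lum & ph@truthLumen) / max(sum(lum), 1), 0.95)
})

test_that("phantom spec validation rejects impossible geometries", {
  expect_error(phantomSpec(shape = c(16, 16, 16), radiusRange = c(5, 10)),
               "cannot fit")
  expect_error(phantomSpec(wallThickness = 10, radiusRange = c(6, 8)),
               "wallThickness")
})

test_that("tile sets have the expected nominal spacing and exact reassembly", {
  img <- matrix(seq_len(170 * 60) %% 97, nrow = 60, ncol = 170)
  ts <- generateTileSet(img, 2, 0.3, jitterPx = 0, seed = 1)
  # width 100 tiles at 30% overlap step to x-offsets 0, 70
  expect_equal(ts@nominalPositions[, 2], c(0, 70))
  expect_equal(ts@truePositions, ts@nominalPositions)

  # single tile: identity
  t1 <- generateTileSet(img, 1, 0.3)
  expect_equal(t1@tiles[[1]], img)
  expect_equal(t1@truePositions[1, ], c(0, 0))

  # with jitter, reassembly at true offsets reproduces the source
  set.seed(99)
  big <- matrix(runif(80 * 300), 80, 300)
  tj <- generateTileSet(big, 3, 0.25, jitterPx = 4, seed = 13)
  for (i in seq_along(tj@tiles)) {
    off <- tj@truePositions[i, 2]
    w <- ncol(tj@tiles[[i]])
    expect_identical(tj@tiles[[i]], big[, (off + 1):(off + w)])
  }
})

test_that("growth series generation follows the model exactly at zero noise", {
  p <- c(A = 2, V_L = 15, alpha = 33, beta = 3)
  s <- generateGrowthSeries(growthSeriesSpec("log_logistic", p,
                                             nPoints = 50, noiseSigma = 0))
  expect_equal(s@volumes, modelValue("log_logistic", p, s@times))
  # at t = alpha the curve passes A + V_L / 2
  expect_equal(modelValue("log_logistic", p, 33), 2 + 15 / 2)
  # determinism under seed
  sp <- growthSeriesSpec("log_normal", c(A = 1, V_L = 5, mu = 3.3, sigma = 0.4),
                         noiseSigma = 0.3, seed = 21)
  expect_identical(generateGrowthSeries(sp)@volumes,
                   generateGrowthSeries(sp)@volumes)
})

test_that("growth series spec validates parameters and sizes", {
  expect_error(growthSeriesSpec("log_normal",
    c(A = 1, V_L = 5, mu = 3, sigma = -1)), "positive")
  expect_error(growthSeriesSpec("log_logistic",
    c(A = 1, V_L = 5, alpha = 30, beta = 2), nPoints = 5), "nPoints")
})
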