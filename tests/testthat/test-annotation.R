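test_that("template matching finds an embedded template exactly", {
  set.seed(2)
  img <- matrix(runif(100 * 100), 100, 100)
  tpl <- img[41:60, 31:50]
  m <- matchTemplate(img, tpl)
  expect_equal(m$position, c(41 + 9, 31 + 9)) # centre of the 20x20 crop
  expect_equal(m$score, 1, tolerance = 1e-8)
  # constant template is degenerate
  flat <- matchTemplate(img, matrix(1, 10, 10))
  expect_true(flat$degenerate)
})

test_that("template embedded in noise is found at the right offset (10 seeds)", {
  for (s in 1:10) {
    set.seed(s)
    tpl <- matrix(runif(15 * 15, 0.5, 1), 15, 15)
    img <- matrix(runif(80 * 80, 0, 0.2), 80, 80)
    oy <- sample(10:55, 1); ox <- sample(10:55, 1)
    img[oy:(oy + 14), ox:(ox + 14)] <- tpl
    m <- matchTemplate(img, tpl)
    expect_equal(m$position, c(oy + 7, ox + 7), info = paste("seed", s))
  }
})

test_that("shift regularization is a circular median with a global fallback", {
  const <- matrix(rep(c(2, -1), each = 9), 9, 2)
  expect_equal(regularizeShifts(const), const)
  # one outlier among equals is replaced by the common value
  sh <- matrix(rep(c(3, 1), each = 9), 9, 2)
  sh[5, ] <- c(40, -12)
  reg <- regularizeShifts(sh)
  expect_equal(reg[5, ], c(3, 1))
  # short lists collapse to the global componentwise median
  s5 <- cbind(c(1, 2, 3, 4, 100), c(0, 0, 1, 1, 1))
  r5 <- regularizeShifts(s5)
  expect_true(all(r5[, 1] == 3))
  expect_true(all(r5[, 2] == 1))
})

test_that("boundary merging drops adjacent points and detects collapse", {
  far <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
  expect_equal(mergeBoundaryPoints(far), far)
  dup <- rbind(far[1, ], far[1, ] + c(0, 1), far[2:4, ])
  expect_equal(nrow(mergeBoundaryPoints(dup)), 4)
  # a tiny ring of mutually 8-adjacent pixels collapses below 3 points
  ring <- cbind(c(5, 5, 6, 6), c(5, 6, 6, 5))
  expect_error(mergeBoundaryPoints(ring), "collapsed")
})

test_that("ROI is static on identical frames and trivial on one frame", {
  set.seed(11)
  frame <- matrix(runif(150 * 150), 150, 150)
  frames <- rep(list(frame), 5)
  roi <- squareRoi(c(60, 90), c(60, 90), timepoint = 5L)
  tr <- propagateRoi(frames, roi)
  for (t in 1:5)
    expect_equal(tr[[t]]@points, roi@points, tolerance = 1e-12)
  single <- propagateRoi(list(frame), roi)
  expect_length(single, 1)
  expect_equal(single[[1]]@points, roi@points)
})

test_that("ROI tracks a rigid 3 px/frame translation within 1 px", {
  frames <- rigidSeries(nFrames = 10, step = 3, size = 200, seed = 7)
  # object bounding box at the last frame
  obj <- which(frames[[10]] > 0.4, arr.ind = TRUE)
  roi <- squareRoi(range(obj[, 1]), range(obj[, 2]), timepoint = 10L)
  tr <- propagateRoi(frames, roi)
  for (t in 9:1) {
    expected <- roi@points - 3 * (10 - t)
    expect_lte(max(abs(apply(tr[[t]]@points, 2, range) -
                       apply(expected, 2, range))), 1)
  }
  # point counts never increase backward in time
  counts <- vapply(tr, function(r) nrow(r@points), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ROI rasterization and CSV round-trip preserve the polygon", {
  roi <- squareRoi(c(5, 14), c(5, 14), margin = 0, spacing = 3,
                   timepoint = 2L)
  lab <- rasterizeRoi(roi, c(20, 20), label = 7L)
  expect_true(lab[10, 10] == 7L)
  expect_true(lab[1, 1] == 0L)
  expect_true(all(lab %in% c(0L, 7L)))
  tmp <- tempfile(fileext = ".csv")
  writeRoiCsv(list(roi), tmp)
  back <- readRoiCsv(tmp)
  expect_equal(back[[1]]@points, unname(roi@points))
  expect_equal(back[[1]]@timepoint, 2L)
})
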