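# Optical flow: the dense Farneback estimator against the circular-shift
# translation oracle, the HSV flow encoding, corner detection and
# Lucas-Kanade trajectory tracking.

test_that("dense flow recovers pure translations within a quarter pixel", {
  tex <- texturedFrame(64, 64)
  for (sh in list(c(0, 3), c(-2, 0), c(0, -4), c(3, 4), c(0, 5))) {
    moved <- circShift(tex, sh[1], sh[2])
    fl <- denseFlow(tex, moved)
    expect_lt(abs(median(fl$dy) - sh[1]), 0.25)
    expect_lt(abs(median(fl$dx) - sh[2]), 0.25)
  }
})

test_that("dense flow on identical frames is essentially zero", {
  tex <- texturedFrame(48, 48, seed = 7)
  fl <- denseFlow(tex, tex)
  expect_lt(max(abs(c(fl$dx, fl$dy))), 0.1)
})

test_that("dense flow rejects mismatched or colour input", {
  expect_error(denseFlow(matrix(0, 8, 8), matrix(0, 8, 9)), "shape")
  expect_error(denseFlow(array(0, c(8, 8, 3)), array(0, c(8, 8, 3))),
               "greyscale")
})

test_that("flow image encoding: zero field black, uniform field one hue, scale invariant", {
  z <- structure(list(dx = matrix(0, 8, 8), dy = matrix(0, 8, 8)),
                 class = "FlowField")
  expect_true(all(flowToImage(z) == 0))
  u <- structure(list(dx = matrix(2, 8, 8), dy = matrix(1, 8, 8)),
                 class = "FlowField")
  img <- flowToImage(u)
  expect_equal(length(unique(as.vector(img[, , 1]))), 1)
  expect_equal(length(unique(as.vector(img[, , 2]))), 1)
  u2 <- structure(list(dx = u$dx * 2, dy = u$dy * 2), class = "FlowField")
  expect_equal(flowToImage(u2), img)
  # normalisation: mixed field keeps relative magnitudes
  mix <- structure(list(dx = rbind(matrix(1, 4, 8), matrix(3, 4, 8)),
                        dy = matrix(0, 8, 8)), class = "FlowField")
  m1 <- flowToImage(mix)
  m2 <- flowToImage(structure(list(dx = mix$dx * 5, dy = mix$dy),
                              class = "FlowField"))
  expect_equal(m1, m2)
})

test_that("corner detection finds separated bright particles", {
  fs <- staticVideo(nParticles = 6, nFrames = 1, size = 64)
  pts <- goodFeaturesToTrack(frames(fs)[[1]], maxCorners = 20,
                             quality = 0.05, minDistance = 4)
  expect_gt(nrow(pts), 0)
  expect_lte(nrow(pts), 20)
  if (nrow(pts) > 1) {
    dmat <- as.matrix(dist(pts))
    expect_gte(min(dmat[upper.tri(dmat)]), 4)
  }
  # a flat image yields no corners
  expect_equal(nrow(goodFeaturesToTrack(matrix(5, 32, 32))), 0)
})

test_that("LK tracks a moving blob with the right arc length", {
  fs <- movingBlobVideo(speed = 2, nFrames = 30)
  tracks <- trackSparse(fs, sparseFlowConfig(maxCorners = 5))
  expect_gt(length(tracks), 0)
  arcs <- vapply(tracks, function(t) sum(sqrt(rowSums(diff(t)^2))),
                 numeric(1))
  # 29 steps x 2 px
  expect_true(all(abs(arcs - 58) < 3))
})

test_that("LK tracks on a static scene are dots", {
  fs <- staticVideo()
  tracks <- trackSparse(fs, sparseFlowConfig(maxCorners = 20))
  expect_gt(length(tracks), 0)
  arcs <- vapply(tracks, function(t) sum(sqrt(rowSums(diff(t)^2))),
                 numeric(1))
  expect_true(all(arcs < 1))
})

test_that("sparse flow image renders at most maxCorners tracks on black", {
  fs <- movingBlobVideo(speed = 2, nFrames = 30)
  img <- sparseFlowImage(fs, sparseFlowConfig(maxCorners = 5))
  expect_equal(dim(img), c(64, 64, 3))
  expect_gt(sum(img > 0), 0)
  # a featureless window warns and returns a blank canvas
  flat <- frameSequence(rep(list(matrix(5, 32, 32)), 5))
  expect_warning(img2 <- sparseFlowImage(flat), "no corners")
  expect_true(all(img2 == 0))
})
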