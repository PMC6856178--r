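# Representation builders: shapes, losslessness and flow-image semantics.

test_that("greyscale stacking gives H x W x T with channel j = frame j", {
  fr <- lapply(1:30, function(j) matrix(j, 224, 224))
  st <- stackGreyscale(fr)
  expect_equal(dim(st), c(224, 224, 30))
  expect_equal(st[1, 1, ], as.numeric(1:30))
  # permuting frames permutes channels identically
  perm <- sample(30)
  expect_equal(stackGreyscale(fr[perm])[5, 5, ], as.numeric(perm))
  # losslessness: pixel multiset per channel preserved
  fr2 <- lapply(1:3, function(j) texturedFrame(16, 16, seed = j))
  st2 <- stackGreyscale(fr2)
  for (j in 1:3) expect_equal(sort(as.vector(st2[, , j])),
                              sort(as.vector(fr2[[j]])))
  expect_error(stackGreyscale(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "mixed")
  expect_error(stackGreyscale(list()), "empty")
})

test_that("vertical frame matrix flattens 64 x 64 frames into 4096 rows", {
  fr <- rep(list(texturedFrame(32, 48, seed = 1)), 30)
  vm <- verticalFrameMatrix(fr)
  expect_equal(dim(vm), c(30, 4096, 1))
  # constant frames give identical rows
  expect_equal(vm[1, , 1], vm[17, , 1])
  # row-major flattening: first 64 entries are the resized frame's first row
  g <- resizeBilinear(fr[[1]], 64, 64)
  expect_equal(vm[1, 1:64, 1], unname(g[1, ]))
  expect_error(verticalFrameMatrix(list()), "empty")
})

test_that("flow pair stacking is sparse-then-dense channel order", {
  s <- array(1, c(16, 16, 3)); d <- array(2, c(16, 16, 3))
  p <- stackFlowPair(s, d)
  expect_equal(dim(p), c(16, 16, 6))
  expect_equal(p[, , 1:3], s)
  expect_equal(p[, , 4:6], d)
  expect_true(all(stackFlowPair(s, d * 0)[, , 4:6] == 0))
  expect_error(stackFlowPair(s, array(0, c(8, 8, 3))), "spatial shape")
})

test_that("sequence flow image: static black, stride accumulates motion", {
  static <- frameSequence(rep(list(texturedFrame(48, 48)), 12))
  expect_true(all(sequenceFlowImage(static,
                                    denseFlowConfig(stride = 1)) == 0))
  # constant per-frame motion (dx = 1): stride 10 sees ~10 px
  tex <- texturedFrame(64, 64, seed = 9)
  fr <- lapply(0:11, function(t) circShift(tex, 0, t))
  mov <- frameSequence(fr)
  flow10 <- denseFlow(frames(mov)[[1]], frames(mov)[[11]])
  expect_lt(abs(median(flow10$dx) - 10), 1)
  m1 <- sequenceFlowImage(mov, denseFlowConfig(stride = 1))
  m10 <- sequenceFlowImage(mov, denseFlowConfig(stride = 10))
  expect_equal(dim(m1), c(64, 64, 3))
  f1 <- denseFlow(frames(mov)[[1]], frames(mov)[[2]])
  expect_gt(mean(sqrt(flow10$dx^2 + flow10$dy^2)),
            mean(sqrt(f1$dx^2 + f1$dy^2)))
  expect_error(sequenceFlowImage(static, denseFlowConfig(stride = 15)),
               "too short")
})

test_that("buildRepresentation covers every kind with consistent shapes", {
  fs <- movingBlobVideo(speed = 2, nFrames = 12, size = 32)
  win <- frameSequence(frames(fs), fps = fps(fs), sourceId = "v1")
  dc <- denseFlowConfig(stride = 1)
  sc <- sparseFlowConfig(maxCorners = 5, seqLen = 12)
  shapes <- list(single_frame = c(32, 32, 1), grey_stack = c(32, 32, 12),
                 frame_matrix = c(12, 4096, 1), sparse_flow = c(32, 32, 3),
                 dense_flow = c(32, 32, 3), flow_pair = c(32, 32, 6))
  for (kind in names(shapes)) {
    s <- buildRepresentation(win, kind, dc, sc)
    expect_equal(dim(s$tensor), shapes[[kind]], info = kind)
    expect_true(all(is.finite(s$tensor)), info = kind)
    expect_equal(s$kind, kind)
    expect_equal(s$sourceId, "v1")
  }
  ts <- buildRepresentation(win, "two_stream_stacked", dc, sc)
  expect_equal(dim(ts$tensor$frame), c(32, 32, 1))
  expect_equal(dim(ts$tensor$flow), c(32, 32, 6))
})

test_that("representation builders are deterministic", {
  fs <- movingBlobVideo(speed = 2, nFrames = 12, size = 32)
  win <- frameSequence(frames(fs), sourceId = "v")
  sc <- sparseFlowConfig(maxCorners = 5, seqLen = 12)
  a <- buildRepresentation(win, "sparse_flow", sparseCfg = sc)
  b <- buildRepresentation(win, "sparse_flow", sparseCfg = sc)
  expect_identical(a$tensor, b$tensor)
  a2 <- buildRepresentation(win, "dense_flow")
  b2 <- buildRepresentation(win, "dense_flow")
  expect_identical(a2$tensor, b2$tensor)
})

test_that("cohort sample building tags every sample with its video", {
  co <- smallCohort()
  ds <- buildCohortSamples(co$videos[1:3], "single_frame",
                           samplingConfig(nSamples = 4, seqLen = 10))
  expect_length(ds$samples, 12)
  expect_equal(unique(table(ds$videoId)), 4L)
})
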