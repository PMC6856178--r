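# The CNN stack: architecture contracts, gradient correctness, the
# training protocol (patience, best checkpoint) and prediction plumbing.

randTensorSamples <- function(n, shape, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(tensor = array(runif(prod(shape), 0, 255), shape),
         kind = "single_frame", sourceId = sprintf("v%02d", i),
         startIndex = 1L))
}

test_that("fusion head geometry follows the backbone and participant dims", {
  bb <- backboneConfig("tiny", c(32, 32, 3), baseWidth = 16)
  m <- buildRegressor(bb, withParticipant = TRUE, participantDim = 3,
                      headWidth = 2048, seed = 1)
  # 4 * baseWidth pooled channels + 3 covariates
  expect_equal(m$featDim, 64)
  expect_equal(m$head[[1]]$nin, 67)
  expect_equal(m$head[[1]]$nout, 2048)
  expect_equal(m$head[[3]]$nin, 2048)
  expect_equal(m$head[[3]]$nout, 2048)
  expect_equal(m$head[[5]]$nout, 3)
  # two-stream: pooled vectors concatenate
  ts <- buildTwoStream(bb, backboneConfig("tiny", c(32, 32, 6),
                                          baseWidth = 16),
                       withParticipant = TRUE, headWidth = 128, seed = 1)
  expect_equal(ts$head[[1]]$nin, 64 + 64 + 3)
})

test_that("models output 3 values per sample and reject bad shapes", {
  bb <- backboneConfig("tiny", c(16, 16, 1), baseWidth = 4)
  m <- buildRegressor(bb, headWidth = 16, seed = 2)
  out <- forwardModel(m, list(array(0.5, c(16, 16, 1, 5))))
  expect_equal(dim(out), c(3L, 5L))
  expect_error(forwardModel(m, list(array(0.5, c(16, 16, 3, 5)))),
               "shape")
})

test_that("backprop gradients match finite differences", {
  set.seed(9)
  bb <- backboneConfig("tiny", c(8, 8, 3), baseWidth = 2)
  m <- buildRegressor(bb, withParticipant = TRUE, participantDim = 3,
                      headWidth = 5, headDropout = 0, seed = 2)
  xs <- list(array(runif(8 * 8 * 3 * 4), c(8, 8, 3, 4)))
  p <- matrix(rnorm(12), 3, 4)
  y <- matrix(runif(12), 3, 4)
  loss <- function() {
    o <- forwardModel(m, xs, p, train = TRUE); mean((o - y)^2)
  }
  o <- forwardModel(m, xs, p, train = TRUE)
  backwardModel(m, 2 * (o - y) / length(y))
  pls <- modelParamLayers(m)
  eps <- 1e-5
  for (li in c(1, 2, length(pls))) {
    l <- pls[[li]]
    for (nm in names(l$par)) {
      grads <- l$grad[[nm]]
      for (j in seq_len(min(3, length(l$par[[nm]])))) {
        orig <- l$par[[nm]][j]
        l$par[[nm]][j] <- orig + eps; lp <- loss()
        l$par[[nm]][j] <- orig - eps; lm <- loss()
        l$par[[nm]][j] <- orig
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - grads[j]) / max(1e-6, abs(num) + abs(grads[j])),
                  1e-4)
      }
    }
  }
})

test_that("residual architectures run forward and backward", {
  for (arch in c("resnet18_like", "resnet50_like")) {
    m <- buildRegressor(backboneConfig(arch, c(16, 16, 3), baseWidth = 4),
                        headWidth = 8, seed = 1)
    x <- list(array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
    out <- forwardModel(m, x, train = TRUE)
    expect_equal(dim(out), c(3L, 2L))
    expect_true(all(is.finite(out)))
    backwardModel(m, out * 0 + 1)
    expect_true(all(vapply(modelParamLayers(m), function(l)
      all(is.finite(unlist(l$grad))), logical(1))))
  }
})

test_that("two-stream models use both branches", {
  set.seed(3)
  bb <- backboneConfig("tiny", c(16, 16, 3), baseWidth = 4)
  m <- buildTwoStream(bb, bb, headWidth = 16, seed = 3)
  xf <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  xl <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  base <- forwardModel(m, list(xf, xl))
  zeroFlow <- forwardModel(m, list(xf, xl * 0))
  zeroFrame <- forwardModel(m, list(xf * 0, xl))
  expect_gt(max(abs(base - zeroFlow)), 1e-8)
  expect_gt(max(abs(base - zeroFrame)), 1e-8)
})

test_that("early stopping follows the patience rule and keeps the best epoch", {
  # improvement at epoch 2, then 20 flat epochs: stop at 22, best = 2
  st <- motiliflow:::earlyStopInit(20)
  mses <- c(5, 4, rep(4, 20))
  for (v in mses) { st <- motiliflow:::earlyStopUpdate(st, v); if (st$stop) break }
  expect_true(st$stop)
  expect_equal(st$epoch, 22L)
  expect_equal(st$bestEpoch, 2L)
  # strictly decreasing sequence never stops
  st2 <- motiliflow:::earlyStopInit(3)
  for (v in seq(10, 1)) st2 <- motiliflow:::earlyStopUpdate(st2, v)
  expect_false(st2$stop)
  expect_equal(st2$bestEpoch, 10L)
})

test_that("training reduces MSE on a learnable toy problem", {
  # brightness-coded labels: mean intensity linearly determines the triple
  set.seed(5)
  n <- 24
  lv <- runif(n)
  samples <- lapply(seq_len(n), function(i)
    list(tensor = array(255 * lv[i], c(8, 8, 1)), kind = "single_frame",
         sourceId = sprintf("v%02d", i), startIndex = 1L))
  labels <- cbind(80 * lv + 10, rep(5, n), 85 - 80 * lv)
  m <- buildRegressor(backboneConfig("tiny", c(8, 8, 1), baseWidth = 2),
                      headWidth = 16, seed = 5)
  trainModel(m, samples, labels, valIdx = 21:24,
             cfg = trainConfig(maxEpochs = 30, patience = 30,
                               batchSize = 8, seed = 5),
             videoId = sprintf("v%02d", seq_len(n)))
  h <- m$history
  expect_lte(nrow(h), 30)
  expect_lt(tail(h$trainMse, 1), h$trainMse[1])
  expect_equal(m$bestEpoch, which.min(h$valMse))
  # prediction plumbing: clipped to [0, 100], 3 columns
  p <- predictModel(m, samples)
  expect_equal(dim(p), c(n, 3L))
  expect_true(all(p >= 0 & p <= 100))
})

test_that("training rejects leaking and degenerate splits", {
  samples <- randTensorSamples(6, c(8, 8, 1))
  labels <- matrix(c(50, 20, 30), 6, 3, byrow = TRUE)
  m <- buildRegressor(backboneConfig("tiny", c(8, 8, 1), baseWidth = 2),
                      headWidth = 8, seed = 1)
  expect_error(trainModel(m, samples, labels, valIdx = integer(0)),
               "empty train or validation")
  expect_error(trainModel(m, samples, labels, valIdx = 5:6,
                          videoId = c("a", "a", "b", "b", "a", "c")),
               "leakage")
})

test_that("video aggregation is the mean over samples and permutation-invariant", {
  pred <- rbind(c(60, 15, 25), c(70, 5, 25), c(50, 25, 25), c(10, 40, 50))
  vid <- c("a", "a", "a", "b")
  agg <- aggregateVideo(pred, vid)
  expect_equal(agg$progressive[agg$id == "a"], 60)
  expect_equal(agg$immotile[agg$id == "a"], 25)
  perm <- c(3, 1, 4, 2)
  agg2 <- aggregateVideo(pred[perm, ], vid[perm])
  expect_equal(agg2[order(agg2$id), -1], agg[order(agg$id), -1],
               ignore_attr = TRUE)
})
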