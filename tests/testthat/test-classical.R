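# ZeroR, early fusion and the classical regressor registry.

mkLabels <- function(df) {
  names(df) <- c("progressive", "non_progressive", "immotile")
  df
}

test_that("ZeroR predicts the training mean for every input", {
  lab <- mkLabels(data.frame(p = c(50, 70), np = c(20, 10),
                             im = c(30, 20)))
  m <- zerorFit(lab)
  p <- zerorPredict(m, 3)
  expect_equal(nrow(p), 3)
  expect_equal(unname(unlist(p[1, ])), c(60, 15, 25))
  expect_equal(p[1, ], p[3, ], ignore_attr = TRUE)
  single <- zerorFit(lab[1, ])
  expect_equal(unname(unlist(zerorPredict(single))), c(50, 20, 30))
  expect_error(zerorFit(lab[0, ]), "empty")
})

test_that("ZeroR training-set MAE equals the mean absolute deviation", {
  set.seed(4)
  co <- generateCohort(30, syntheticVideoSpec(nFrames = 1, nParticles = 20),
                       seed = 4, renderVideos = FALSE)
  lab <- co$labels
  m <- zerorFit(lab)
  pred <- cbind(data.frame(id = lab$id), zerorPredict(m, nrow(lab)))
  rep <- maeReport(pred, lab)
  for (cn in c("progressive", "non_progressive", "immotile"))
    expect_equal(unname(rep[sub("non_", "non", cn)]),
                 mean(abs(lab[[cn]] - mean(lab[[cn]]))))
})

test_that("early fusion concatenates blocks by id", {
  t1 <- data.frame(id = c("a", "b"), f1 = 1:2, f2 = 3:4)
  t2 <- data.frame(id = c("b", "a"), g1 = 5:6)
  fused <- earlyFuse(list(tam = t1, part = t2))
  expect_equal(names(fused), c("id", "tam_f1", "tam_f2", "part_g1"))
  expect_equal(fused$part_g1, c(6L, 5L))  # aligned to t1's id order
  # adding a block widens the table
  t3 <- data.frame(id = c("a", "b"), conc = c(0.1, 0.2))
  expect_equal(ncol(earlyFuse(list(tam = t1, part = t2, conc = t3))), 5)
  # single block is the identity up to renaming
  expect_equal(earlyFuse(list(x = t1))$x_f1, t1$f1)
  expect_error(earlyFuse(list(a = t1, b = t2[1, ])), "disagree")
})

test_that("unknown algorithms are rejected with the registry listed", {
  tbl <- data.frame(id = "a", f = 1)
  lab <- data.frame(id = "a", progressive = 50, non_progressive = 20,
                    immotile = 30)
  expect_error(fitClassical(tbl, lab, "deep_thought"), "linear")
})

test_that("a linear fit interpolates exactly linear targets", {
  set.seed(11)
  n <- 25
  X <- matrix(rnorm(n * 4), n, 4)
  lab <- data.frame(id = sprintf("v%02d", 1:n),
                    progressive = 40 + 10 * X[, 1],
                    non_progressive = 30 - 5 * X[, 2],
                    immotile = 30 + 10 * X[, 1] * 0 + 3 * X[, 3])
  tbl <- data.frame(id = lab$id, X)
  b <- fitClassical(tbl, lab, "linear")
  p <- predictClassical(b, tbl)
  expect_lt(max(abs(p$progressive - lab$progressive)), 1e-6)
  expect_lt(max(abs(p$immotile - lab$immotile)), 1e-6)
})

test_that("every registry algorithm fits constant targets and clips", {
  set.seed(12)
  n <- 20
  tbl <- data.frame(id = sprintf("v%02d", 1:n), matrix(rnorm(n * 3), n, 3))
  lab <- data.frame(id = tbl$id, progressive = rep(60, n),
                    non_progressive = rep(15, n), immotile = rep(25, n))
  for (algo in motiliflow:::classicalRegistry()) {
    b <- fitClassical(tbl, lab, algo, seed = 5)
    p <- predictClassical(b, tbl)
    expect_lt(max(abs(p$progressive - 60)), 2, label = algo)
    expect_true(all(p$progressive >= 0 & p$progressive <= 100),
                info = algo)
  }
})

test_that("seeded fits are deterministic", {
  set.seed(13)
  n <- 30
  tbl <- data.frame(id = sprintf("v%02d", 1:n), matrix(rnorm(n * 5), n, 5))
  lab <- data.frame(id = tbl$id,
                    progressive = runif(n, 20, 80),
                    non_progressive = runif(n, 5, 15))
  lab$immotile <- 100 - lab$progressive - lab$non_progressive
  for (algo in c("random_forest", "random_tree")) {
    p1 <- predictClassical(fitClassical(tbl, lab, algo, seed = 3), tbl)
    p2 <- predictClassical(fitClassical(tbl, lab, algo, seed = 3), tbl)
    expect_identical(p1, p2, info = algo)
  }
})

test_that("label-independent covariates cannot beat ZeroR by much", {
  # participant-only features drawn independently of the labels: grouped-CV
  # average MAE must not undercut ZeroR beyond noise
  co <- generateCohort(45, syntheticVideoSpec(nFrames = 1, nParticles = 20),
                       seed = 21, bmiSlope = 0, renderVideos = FALSE)
  lab <- co$labels
  feat <- co$participants[, c("id", "age", "bmi", "abstinence_days")]
  split <- groupedKFold(lab$id, 3, seed = 21)
  zr <- evaluateMethod(zerorMethodRunner(lab), lab, split, "zeror")
  lin <- evaluateMethod(classicalMethodRunner(feat, lab, "linear"),
                        lab, split, "participant_linear")
  expect_gte(lin$pooled["average"], zr$pooled["average"] - 0.5)
})
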