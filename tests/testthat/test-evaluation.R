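# Grouped folds, MAE accounting and the corrected paired t-test.

test_that("grouped k-fold deals balanced, deterministic, exhaustive folds", {
  ids <- sprintf("v%03d", 1:85)
  sp <- groupedKFold(ids, 3, seed = 9)
  sizes <- sort(tabulate(sp@assignment, 3), decreasing = TRUE)
  expect_equal(sizes, c(29L, 28L, 28L))
  expect_setequal(names(sp@assignment), ids)
  sp2 <- groupedKFold(ids, 3, seed = 9)
  expect_identical(sp@assignment, sp2@assignment)
  expect_false(identical(sp@assignment,
                         groupedKFold(ids, 3, seed = 10)@assignment))
  tiny <- groupedKFold(c("a", "b", "c"), 3, seed = 1)
  expect_equal(sort(unname(tiny@assignment)), 1:3)
  expect_error(groupedKFold(c("a", "b"), 3), "at least")
})

test_that("MAE report is per-variable with a definitional average", {
  lab <- data.frame(id = "v1", progressive = 50, non_progressive = 20,
                    immotile = 30)
  pred <- data.frame(id = "v1", progressive = 60, non_progressive = 15,
                     immotile = 25)
  m <- maeReport(pred, lab)
  expect_equal(unname(m), c(10, 5, 5, 20 / 3))
  expect_equal(unname(maeReport(lab, lab)), c(0, 0, 0, 0))
  set.seed(2)
  labs <- data.frame(id = letters[1:6],
                     progressive = runif(6, 0, 60),
                     non_progressive = runif(6, 0, 30))
  labs$immotile <- 100 - labs$progressive - labs$non_progressive
  preds <- labs
  preds[, 2:4] <- preds[, 2:4] + rnorm(18)
  m2 <- maeReport(preds, labs)
  expect_equal(unname(m2["average"]),
               mean(m2[c("progressive", "nonprogressive", "immotile")]))
  expect_error(maeReport(preds[1:3, ], labs), "id sets differ")
})

test_that("corrected t-test matches the hand-computed value", {
  # diffs (1,2,3), J = 3, ratio n_test/n_train = 0.5:
  # t = 2 / sqrt((1/3 + 1/2) * 1) = 2.1909
  r <- correctedPairedTTest(c(1, 2, 3), tTestConfig(nTrain = 2, nTest = 1))
  expect_equal(r$t, 2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(r$t, 2.1909, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 / sqrt(5 / 6), 2))
  expect_false(r$significant)
})

test_that("corrected t-test degenerate and ordering properties", {
  cfg <- tTestConfig(nTrain = 2, nTest = 1)
  z <- correctedPairedTTest(c(0, 0, 0), cfg)
  expect_equal(z$t, 0); expect_equal(z$p, 1); expect_false(z$significant)
  expect_warning(d <- correctedPairedTTest(c(2, 2, 2), cfg),
                 "zero variance")
  expect_equal(d$p, 0)
  # the correction only shrinks |t| relative to the classical paired test
  set.seed(3)
  for (i in 1:20) {
    diffs <- rnorm(3)
    tc <- correctedPairedTTest(diffs, cfg)$t
    tu <- mean(diffs) / sqrt(var(diffs) / 3)
    expect_lte(abs(tc), abs(tu) + 1e-12)
  }
})

test_that("the corrected test is conservative under the null", {
  # both methods = baseline + iid noise: rejection rate at alpha = 0.05
  # stays below 10% over 500 replicates
  set.seed(77)
  cfg <- tTestConfig(alpha = 0.05, nTrain = 2, nTest = 1)
  rej <- 0
  for (r in 1:500) {
    d <- rnorm(3, 0, 1)
    if (correctedPairedTTest(d, cfg)$significant) rej <- rej + 1
  }
  expect_lte(rej / 500, 0.10)
})

test_that("evaluateMethod guards leakage and pools correctly", {
  set.seed(6)
  co <- generateCohort(12, syntheticVideoSpec(nFrames = 1, nParticles = 10),
                       seed = 6, renderVideos = FALSE)
  lab <- co$labels
  split <- groupedKFold(lab$id, 3, seed = 6)
  ev <- evaluateMethod(zerorMethodRunner(lab), lab, split, "zeror")
  expect_equal(nrow(ev$perFold), 3)
  expect_equal(sum(ev$perFold$n), 12)
  # pooled MAE = sample-count-weighted mean of per-fold MAEs
  expect_equal(unname(ev$pooled["average"]),
               sum(ev$perFold$average * ev$perFold$n) / 12)
  # a runner returning train ids must be rejected
  bad <- function(trainIds, testIds, fold)
    data.frame(id = trainIds[seq_along(testIds)], progressive = 0,
               non_progressive = 0, immotile = 100)
  expect_error(evaluateMethod(bad, lab, split), "wrong id set")
})

test_that("compareMethods reports self-comparison as not significant", {
  set.seed(8)
  co <- generateCohort(12, syntheticVideoSpec(nFrames = 1, nParticles = 10),
                       seed = 8, renderVideos = FALSE)
  lab <- co$labels
  split <- groupedKFold(lab$id, 3, seed = 8)
  zr <- evaluateMethod(zerorMethodRunner(lab), lab, split, "zeror")
  rep <- compareMethods(list(zr), reference = "zeror")
  tb <- reportTable(rep)
  expect_equal(tb$t[tb$method == "zeror"], 0)
  expect_false(tb$significant[tb$method == "zeror"])
  # average column is the mean of the three MAE columns on every row
  expect_equal(tb$average,
               rowMeans(tb[, c("progressive", "nonprogressive",
                               "immotile")]))
  expect_s4_class(rep, "EvalReport")
})
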