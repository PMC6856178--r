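# Synthetic sperm-video simulator: class apportionment, kinematics and
# rendering invariants.

test_that("class counts follow largest-remainder rounding", {
  sp <- syntheticVideoSpec(nParticles = 10,
                           classFractions = c(0.5, 0.3, 0.2), nFrames = 2)
  tr <- simulateTracks(sp, kinematicsParams())
  expect_equal(unname(tr$counts), c(5L, 3L, 2L))
  # remainders decide who gets the spare particle
  expect_equal(motiliflow:::largestRemainderCounts(c(0.5, 0.26, 0.24), 10),
               c(5L, 3L, 2L))
  expect_equal(sum(motiliflow:::largestRemainderCounts(c(1, 1, 1) / 3, 85)),
               85L)
})

test_that("an empty scene is rejected", {
  sp <- syntheticVideoSpec(nParticles = 0, nFrames = 2)
  expect_error(simulateTracks(sp, kinematicsParams()), "empty scene")
})

test_that("immotile-only scenes barely move", {
  sp <- syntheticVideoSpec(nParticles = 8, classFractions = c(0, 0, 1),
                           nFrames = 40, seed = 5)
  kin <- kinematicsParams()
  tr <- simulateTracks(sp, kin)
  for (i in seq_len(8)) {
    p <- tr$positions[i, , ]
    net <- sqrt(colSums((p - p[, 1])^2))
    steps <- sqrt(colSums((p[, -1, drop = FALSE] -
                             p[, -40, drop = FALSE])^2))
    expect_lt(max(net), 1)
    expect_lte(sum(steps), kin@immotileJitter * 40)
  }
})

test_that("a straight progressive particle travels speed x (nFrames - 1)", {
  sp <- syntheticVideoSpec(nParticles = 1, classFractions = c(1, 0, 0),
                           frameSize = c(512, 512), nFrames = 50,
                           noiseSigma = 0, seed = 101)
  kin <- kinematicsParams(progressiveSpeed = 2, progressiveHeadingSigma = 0,
                          nonprogJitter = 0.5)
  tr <- simulateTracks(sp, kin)
  net <- sqrt(sum((tr$positions[1, , 50] - tr$positions[1, , 1])^2))
  # no border reflection for this seed: net equals 49 steps x 2 px
  expect_equal(net, 98, tolerance = 0.01 / 98)
})

test_that("per-frame displacement separates the three classes", {
  sp <- syntheticVideoSpec(nParticles = 30, nFrames = 60, seed = 2)
  kin <- kinematicsParams()
  tr <- simulateTracks(sp, kin)
  stepMean <- vapply(seq_len(30), function(i) {
    p <- tr$positions[i, , ]
    mean(sqrt(colSums((p[, -1] - p[, -ncol(p)])^2)))
  }, numeric(1))
  m <- tapply(stepMean, tr$class, mean)
  expect_gt(m["progressive"], 2 * m["nonprogressive"])
  expect_gt(m["nonprogressive"], 2 * m["immotile"])
})

test_that("non-progressive particles stay inside the confinement radius", {
  sp <- syntheticVideoSpec(nParticles = 12, classFractions = c(0, 1, 0),
                           nFrames = 120, seed = 3)
  kin <- kinematicsParams(nonprogConfineRadius = 5)
  tr <- simulateTracks(sp, kin)
  for (i in seq_len(12)) {
    p <- tr$positions[i, , ]
    expect_lte(max(sqrt(colSums((p - p[, 1])^2))), 5 + 1e-9)
  }
})

test_that("rendering is deterministic and produces bright particles", {
  sp <- syntheticVideoSpec(nParticles = 1, classFractions = c(0, 0, 1),
                           nFrames = 3, noiseSigma = 0, seed = 4)
  tr <- simulateTracks(sp, kinematicsParams(immotileJitter = 0))
  fs <- renderFrames(tr, sp)
  # jitter 0, noise 0: all frames identical
  expect_identical(frames(fs)[[1]], frames(fs)[[2]])
  expect_identical(frames(fs)[[2]], frames(fs)[[3]])
  # brighter than an empty background, bounded to 8-bit range
  expect_gt(mean(frames(fs)[[1]]), 20)
  expect_true(all(frames(fs)[[1]] >= 0 & frames(fs)[[1]] <= 255))
  # exactly one connected bright component (row/col support is one blob)
  f <- frames(fs)[[1]] > 100
  expect_gt(sum(f), 0)
  rr <- range(which(rowSums(f) > 0)); cc <- range(which(colSums(f) > 0))
  expect_true(all(rowSums(f)[rr[1]:rr[2]] > 0))
  expect_true(all(colSums(f)[cc[1]:cc[2]] > 0))
})

test_that("renderFrames rejects frames smaller than the particle head", {
  sp <- syntheticVideoSpec(nParticles = 1, frameSize = c(5, 5),
                           headRadius = 3, nFrames = 2)
  tr <- simulateTracks(sp, kinematicsParams())
  expect_error(renderFrames(tr, sp), "twice the head radius")
})

test_that("cohort labels sum to 100 and match realised particle fractions", {
  co <- smallCohort()
  sums <- rowSums(co$labels[, c("progressive", "non_progressive",
                                "immotile")])
  expect_equal(sums, rep(100, nrow(co$labels)), tolerance = 1e-9)
  for (i in c(1, 5)) {
    counts <- co$tracks[[i]]$counts
    expect_equal(unname(100 * counts / sum(counts)),
                 unname(unlist(co$labels[i, c("progressive",
                                              "non_progressive",
                                              "immotile")])))
  }
})

test_that("cohort generation is deterministic and CSV round-trips", {
  c1 <- generateCohort(4, syntheticVideoSpec(nFrames = 5, nParticles = 8),
                       seed = 31)
  c2 <- generateCohort(4, syntheticVideoSpec(nFrames = 5, nParticles = 8),
                       seed = 31)
  expect_identical(c1$table, c2$table)
  expect_identical(motiliflow:::cohortCsvLines(c1$table),
                   motiliflow:::cohortCsvLines(c2$table))
  d <- withr::local_tempdir()
  writeCohort(c1, d)
  tbl <- read.csv(file.path(d, "cohort.csv"))
  expect_equal(names(tbl), c("id", "progressive", "non_progressive",
                             "immotile", "concentration", "age", "bmi",
                             "abstinence_days"))
  expect_equal(nrow(tbl), 4)
})

test_that("independent covariates are uncorrelated with the labels", {
  co <- generateCohort(200, syntheticVideoSpec(nFrames = 1, nParticles = 30),
                       seed = 17, bmiSlope = 0, renderVideos = FALSE)
  r <- cor(co$table$bmi, co$table$progressive)
  expect_lt(abs(r), 0.2)
  # the association knob induces the requested sign
  co2 <- generateCohort(200, syntheticVideoSpec(nFrames = 1, nParticles = 30),
                        seed = 17, bmiSlope = 0.3, renderVideos = FALSE)
  expect_gt(cor(co2$table$bmi, co2$table$progressive), 0.5)
})

test_that("motility label class enforces its invariants", {
  expect_s4_class(motilityLabel(50, 20, 30), "MotilityLabel")
  expect_error(motilityLabel(50, 20, 31), "sum to 100")
  expect_error(motilityLabel(-1, 71, 30), ">= 0")
  expect_equal(unname(labelVector(motilityLabel(60, 15, 25))),
               c(60, 15, 25))
})
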