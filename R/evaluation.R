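# Grouped three-fold cross-validation, MAE reporting in the standard table
# layout (per motility variable plus their average), and the
# variance-corrected paired t-test used to compare every method against the
# ZeroR baseline.

#' Grouped k-fold assignment of videos
#'
#' Shuffles the video ids with the given seed and deals them round-robin
#' into k folds, so fold sizes differ by at most one (85 videos and k = 3
#' give folds of 29/28/28) and all samples of a video share its fold — no
#' frame of a video can appear on both sides of a split.
#'
#' @param videoIds character vector of unique video ids.
#' @param k number of folds (default 3).
#' @param seed shuffle seed.
#' @return A \code{FoldSplit}.
#' @export
groupedKFold <- function(videoIds, k = 3, seed = 1) {
  videoIds <- as.character(videoIds)
  if (anyDuplicated(videoIds)) stop("video ids must be unique")
  if (length(videoIds) < k)
    stop(sprintf("need at least k = %d videos, got %d", k, length(videoIds)))
  set.seed(as.integer(seed))
  shuffled <- sample(videoIds)
  # i-th shuffled video -> fold ((i-1) mod k) + 1 (round-robin deal)
  assignment <- setNames(as.integer((match(videoIds, shuffled) - 1L) %%
                                      as.integer(k)) + 1L, videoIds)
  new("FoldSplit", k = k, assignment = assignment, seed = seed)
}

#' Mean absolute error per motility variable
#'
#' \code{MAE_v = mean |pred_v - label_v|} over videos, for each motility
#' variable, plus their arithmetic mean as \code{average}.
#'
#' @param predictions,labels data.frames with columns id, progressive,
#'   non_progressive, immotile covering the same id set.
#' @return Named numeric vector (progressive, nonprogressive, immotile,
#'   average).
#' @export
maeReport <- function(predictions, labels) {
  if (!setequal(predictions$id, labels$id))
    stop("prediction and label id sets differ")
  lab <- labels[match(predictions$id, labels$id), ]
  m <- vapply(c("progressive", "non_progressive", "immotile"),
              function(cn) mean(abs(predictions[[cn]] - lab[[cn]])),
              numeric(1))
  c(progressive = unname(m[1]), nonprogressive = unname(m[2]),
    immotile = unname(m[3]), average = mean(m))
}

#' Variance-corrected paired t-test for cross-validated comparisons
#'
#' Paired t-test over per-fold metric differences whose variance term is
#' inflated by the train/test size ratio, compensating for the dependence
#' between cross-validation folds:
#' \deqn{t = \bar d / \sqrt{(1/J + n_{test}/n_{train})\, s_d^2}}
#' with J folds and the sample variance \eqn{s_d^2} of the differences;
#' p from Student's t with J - 1 degrees of freedom, two-sided.
#'
#' @param diffs numeric vector of per-fold differences (method - reference).
#' @param cfg a \code{\link{tTestConfig}}; \code{nTest/nTrain} is the
#'   correction ratio (0.5 for 3-fold CV).
#' @return list(t, p, significant, df).
#' @export
correctedPairedTTest <- function(diffs, cfg = tTestConfig()) {
  stopifnot(is(cfg, "TTestConfig"))
  J <- length(diffs)
  if (J < 2) stop("need at least 2 folds of differences")
  dbar <- mean(diffs)
  s2 <- var(diffs)
  ratio <- cfg@nTest / cfg@nTrain
  if (s2 == 0) {
    if (dbar == 0) return(list(t = 0, p = 1, significant = FALSE, df = J - 1))
    warning("zero variance with non-zero mean difference; p set to 0")
    return(list(t = sign(dbar) * Inf, p = 0, significant = TRUE, df = J - 1))
  }
  tstat <- dbar / sqrt((1 / J + ratio) * s2)
  p <- 2 * pt(-abs(tstat), df = J - 1)
  list(t = tstat, p = p, significant = p <= cfg@alpha, df = J - 1)
}

#' Evaluate a method with grouped cross-validation
#'
#' Runs \code{methodRunner} once per fold (training side = all other
#' folds), collects per-video predictions on the held-out fold, and reports
#' per-fold and pooled MAE. The runner signature is
#' \code{function(trainIds, testIds, fold)} returning a data.frame of
#' predictions (id + three percentages) for \code{testIds}.
#'
#' @param methodRunner the fold runner.
#' @param labels per-video label data.frame (id, progressive,
#'   non_progressive, immotile).
#' @param split a \code{FoldSplit} over the label ids.
#' @param methodName row label for reports.
#' @return list with \code{perFold} (data.frame), \code{pooled} (named MAE
#'   vector), \code{predictions} (pooled per-video data.frame) and
#'   \code{foldAvg} (per-fold average-MAE vector used for testing).
#' @export
evaluateMethod <- function(methodRunner, labels, split,
                           methodName = "method") {
  stopifnot(is(split, "FoldSplit"))
  ids <- names(split@assignment)
  if (!setequal(ids, labels$id)) stop("split and labels disagree on ids")
  perFold <- NULL; preds <- NULL
  for (fold in seq_len(split@k)) {
    testIds <- ids[split@assignment == fold]
    trainIds <- ids[split@assignment != fold]
    p <- methodRunner(trainIds, testIds, fold)
    if (!setequal(p$id, testIds))
      stop("method runner returned predictions for the wrong id set")
    stopifnot(length(intersect(trainIds, p$id)) == 0)  # leakage guard
    m <- maeReport(p, labels[labels$id %in% testIds, ])
    perFold <- rbind(perFold,
                     data.frame(method = methodName, fold = fold,
                                n = length(testIds), t(m)))
    preds <- rbind(preds, p)
  }
  pooled <- maeReport(preds, labels)
  list(perFold = perFold, pooled = pooled, predictions = preds,
       foldAvg = perFold$average, methodName = methodName)
}

#' Compare evaluated methods against a reference
#'
#' Builds the summary table (per-variable and average MAE pooled over
#' folds) and tests each method's per-fold average MAE against the
#' reference method with the corrected paired t-test on identical folds.
#'
#' @param evals list of results from \code{\link{evaluateMethod}} (same
#'   split for all).
#' @param reference name of the reference method (default "zeror").
#' @param alpha significance level.
#' @return An \code{\link{EvalReport-class}} object.
#' @export
compareMethods <- function(evals, reference = "zeror", alpha = 0.05) {
  names(evals) <- vapply(evals, `[[`, character(1), "methodName")
  if (!reference %in% names(evals))
    stop(sprintf("reference method '%s' not among evaluated methods",
                 reference))
  folds <- lapply(evals, function(e) e$perFold$n)
  if (length(unique(folds)) != 1)
    stop("methods were evaluated on different folds")
  ref <- evals[[reference]]
  J <- length(ref$foldAvg)
  nTest <- ref$perFold$n
  nTrain <- sum(nTest) - nTest
  cfg <- tTestConfig(alpha = alpha, nTrain = mean(nTrain),
                     nTest = mean(nTest))
  rows <- NULL; perFold <- NULL
  for (e in evals) {
    tt <- correctedPairedTTest(e$foldAvg - ref$foldAvg, cfg)
    rows <- rbind(rows, data.frame(
      method = e$methodName, progressive = e$pooled["progressive"],
      nonprogressive = e$pooled["nonprogressive"],
      immotile = e$pooled["immotile"], average = e$pooled["average"],
      t = tt$t, p = tt$p, significant = tt$significant))
    perFold <- rbind(perFold, e$perFold)
  }
  rownames(rows) <- NULL
  new("EvalReport", table = rows, perFold = perFold, k = J)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report an \code{EvalReport}.
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  js <- file.path(dir, "report.json")
  write.csv(report@table, csv, row.names = FALSE)
  jsonlite::write_json(list(table = report@table, perFold = report@perFold),
                       js, dataframe = "rows", digits = NA)
  invisible(c(csv = csv, json = js))
}
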