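# End-to-end pipeline: simulate a cohort, build representations, train the
# requested methods, and evaluate them with grouped cross-validation
# against the ZeroR baseline. A RunConfig gathers every tunable with the
# reference defaults; runs echo their exact configuration next to their
# outputs and identical re-runs reuse the cached report.

#' Pipeline run configuration
#'
#' Gathers every tunable of the pipeline stages. Defaults follow the
#' reference protocol where one exists (50 fps, 30-frame windows, Nadam at
#' 0.002/0.9/0.999 with patience 20, 3-fold grouped CV, alpha 0.05);
#' desk-scale defaults (64 x 64 frames, tiny backbone, small sample counts)
#' keep a full run tractable on one CPU.
#'
#' @param nVideos cohort size.
#' @param spec per-video \code{\link{syntheticVideoSpec}} template.
#' @param kin \code{\link{kinematicsParams}}.
#' @param sampling \code{\link{samplingConfig}} (samples per video, window).
#' @param denseCfg,sparseCfg flow configurations.
#' @param backbone \code{\link{backboneConfig}} for deep methods; its input
#'   channel count is adapted per representation kind.
#' @param train \code{\link{trainConfig}}.
#' @param kinds representation kinds to evaluate (see
#'   \code{representationKinds()}).
#' @param withParticipant also train participant-fusion variants?
#' @param k folds.
#' @param alpha significance level.
#' @param headWidth fusion-head hidden width.
#' @param seed master seed.
#' @param outDir output directory ("" = no files written).
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(nVideos = 12,
                      spec = syntheticVideoSpec(),
                      kin = kinematicsParams(),
                      sampling = samplingConfig(nSamples = 4, seqLen = 30),
                      denseCfg = denseFlowConfig(),
                      sparseCfg = sparseFlowConfig(),
                      backbone = backboneConfig(baseWidth = 8),
                      train = trainConfig(maxEpochs = 8, patience = 20),
                      kinds = "dense_flow",
                      withParticipant = FALSE,
                      k = 3, alpha = 0.05, headWidth = 128, seed = 1,
                      outDir = "") {
  cfg <- list(nVideos = nVideos, spec = spec, kin = kin, sampling = sampling,
              denseCfg = denseCfg, sparseCfg = sparseCfg,
              backbone = backbone, train = train, kinds = kinds,
              withParticipant = withParticipant, k = k, alpha = alpha,
              headWidth = headWidth, seed = seed, outDir = outDir)
  bad <- setdiff(cfg$kinds, representationKinds())
  if (length(bad)) stop("unknown representation kind(s): ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "RunConfig"
  cfg
}

s4ToList <- function(x)
  setNames(lapply(slotNames(x), function(s) slot(x, s)), slotNames(x))

#' Serialise a RunConfig to a JSON string
#'
#' The echo written beside every run's outputs; reloading it reproduces the
#' run. Unknown keys are rejected on reload.
#'
#' @param cfg a \code{"RunConfig"}.
#' @return JSON string.
#' @export
runConfigJson <- function(cfg) {
  x <- unclass(cfg)
  for (nm in names(x)) if (isVirtualClass(class(x[[nm]])) || isS4(x[[nm]]))
    x[[nm]] <- s4ToList(x[[nm]])
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname runConfigJson
#' @param json JSON string or file path produced by \code{runConfigJson}.
#' @export
runConfigFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  ref <- runConfig()
  unknown <- setdiff(names(x), names(unclass(ref)))
  if (length(unknown))
    stop("unknown RunConfig keys: ", paste(unknown, collapse = ", "))
  build <- function(ctor, lst) do.call(ctor, lst)
  runConfig(nVideos = x$nVideos,
            spec = build(syntheticVideoSpec, x$spec),
            kin = build(kinematicsParams, x$kin),
            sampling = build(samplingConfig, x$sampling),
            denseCfg = build(denseFlowConfig, x$denseCfg),
            sparseCfg = build(sparseFlowConfig, x$sparseCfg),
            backbone = build(backboneConfig, x$backbone),
            train = build(trainConfig, x$train),
            kinds = x$kinds, withParticipant = x$withParticipant,
            k = x$k, alpha = x$alpha, headWidth = x$headWidth,
            seed = x$seed, outDir = x$outDir)
}

# Hold out a grouped validation subset of the training videos for early
# stopping (the held-out CV test fold is never touched during training).
splitTrainVal <- function(trainVideoIds, valFraction = 0.25, seed = 1) {
  set.seed(as.integer(seed))
  ids <- unique(trainVideoIds)
  nVal <- max(1, round(valFraction * length(ids)))
  valIds <- sample(ids, nVal)
  list(trainIds = setdiff(ids, valIds), valIds = valIds)
}

#' Fold runner for a deep representation method
#'
#' Returns a \code{function(trainIds, testIds, fold)} closure for
#' \code{\link{evaluateMethod}}: it splits the fold's training videos into
#' an inner train/validation pair (grouped by video), trains a fresh model,
#' predicts every test sample and aggregates per video.
#'
#' @param kind representation kind.
#' @param dataset result of \code{\link{buildCohortSamples}} for that kind.
#' @param labelsBySample N x 3 matrix of per-sample labels.
#' @param backbone \code{\link{backboneConfig}} template (channels adapted).
#' @param trainCfg \code{\link{trainConfig}}.
#' @param participants optional per-sample covariate matrix.
#' @param headWidth fusion-head width.
#' @param valFraction fraction of training videos held out for early
#'   stopping.
#' @return runner closure.
#' @export
deepMethodRunner <- function(kind, dataset, labelsBySample, backbone,
                             trainCfg, participants = NULL,
                             headWidth = 2048, valFraction = 0.25) {
  force(kind); force(dataset); force(labelsBySample)
  function(trainIds, testIds, fold) {
    vid <- dataset$videoId
    sv <- splitTrainVal(trainIds, valFraction,
                        seed = trainCfg@seed + 101 * fold)
    idxTrain <- which(vid %in% sv$trainIds)
    idxVal <- which(vid %in% sv$valIds)
    idxTest <- which(vid %in% testIds)
    sub <- c(idxTrain, idxVal)
    first <- dataset$samples[[sub[1]]]$tensor
    shape <- if (is.list(first)) dim(first$frame) else dim(first)
    bb <- backbone
    bb@inputShape <- shape
    withP <- !is.null(participants)
    model <- if (is.list(first)) {
      flowShape <- dim(first$flow)
      fb <- backbone; fb@inputShape <- shape
      lb <- backbone; lb@inputShape <- flowShape
      buildTwoStream(fb, lb, withParticipant = withP,
                     participantDim = if (withP) ncol(participants) else 3,
                     headWidth = headWidth, seed = trainCfg@seed + fold)
    } else
      buildRegressor(bb, withParticipant = withP,
                     participantDim = if (withP) ncol(participants) else 3,
                     headWidth = headWidth, seed = trainCfg@seed + fold)
    trainModel(model, dataset$samples[sub], labelsBySample[sub, , drop = FALSE],
               valIdx = seq_along(idxVal) + length(idxTrain),
               cfg = trainCfg,
               participants = if (withP) participants[sub, , drop = FALSE],
               videoId = vid[sub])
    pred <- predictModel(model, dataset$samples[idxTest],
                         participants = if (withP)
                           participants[idxTest, , drop = FALSE],
                         tta = trainCfg@augment)
    aggregateVideo(pred, vid[idxTest])
  }
}

#' ZeroR fold runner
#'
#' @param labels per-video label data.frame.
#' @return runner closure for \code{\link{evaluateMethod}}.
#' @export
zerorMethodRunner <- function(labels) {
  function(trainIds, testIds, fold) {
    m <- zerorFit(labels[labels$id %in% trainIds, ])
    cbind(data.frame(id = testIds, stringsAsFactors = FALSE),
          zerorPredict(m, length(testIds)))
  }
}

#' Fold runner for a classical feature-table method
#'
#' @param featureTable data.frame with id + features (see
#'   \code{\link{earlyFuse}}).
#' @param labels per-video label data.frame.
#' @param algorithmId registry id for \code{\link{fitClassical}}.
#' @param seed fit seed.
#' @return runner closure.
#' @export
classicalMethodRunner <- function(featureTable, labels, algorithmId,
                                  seed = 1) {
  function(trainIds, testIds, fold) {
    tr <- featureTable[featureTable$id %in% trainIds, , drop = FALSE]
    te <- featureTable[featureTable$id %in% testIds, , drop = FALSE]
    bundle <- fitClassical(tr, labels[labels$id %in% trainIds, ],
                           algorithmId, seed = seed + fold)
    predictClassical(bundle, te)
  }
}

#' Run the full pipeline
#'
#' simulate -> represent -> train -> evaluate. Stages run in order; when
#' \code{outDir} is set, the exact configuration is echoed as
#' \code{config.json} beside the outputs and an identical re-run reuses the
#' cached \code{report.json} instead of recomputing.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose print per-stage progress and timings.
#' @return An \code{\link{EvalReport-class}}.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  cfgJson <- runConfigJson(config)
  if (nzchar(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    echoPath <- file.path(config$outDir, "config.json")
    reportPath <- file.path(config$outDir, "report.json")
    if (file.exists(echoPath) && file.exists(reportPath) &&
        identical(paste(readLines(echoPath), collapse = "\n"),
                  as.character(cfgJson))) {
      say("[cache] config unchanged; reusing %s", reportPath)
      js <- jsonlite::fromJSON(reportPath)
      return(new("EvalReport", table = js$table, perFold = js$perFold,
                 k = config$k))
    }
    writeLines(cfgJson, echoPath)
  }
  t0 <- Sys.time()
  cohort <- generateCohort(config$nVideos, config$spec, config$kin,
                           seed = config$seed)
  say("[simulate] %d videos in %.1fs", config$nVideos,
      as.numeric(Sys.time() - t0, units = "secs"))
  split <- groupedKFold(cohort$labels$id, k = config$k, seed = config$seed)
  evals <- list(evaluateMethod(zerorMethodRunner(cohort$labels),
                               cohort$labels, split, methodName = "zeror"))
  for (kind in config$kinds) {
    t1 <- Sys.time()
    ds <- buildCohortSamples(cohort$videos, kind, config$sampling,
                             config$denseCfg, config$sparseCfg)
    labM <- as.matrix(cohort$labels[match(ds$videoId, cohort$labels$id),
                                    c("progressive", "non_progressive",
                                      "immotile")])
    say("[featurize] %s: %d samples in %.1fs", kind, length(ds$samples),
        as.numeric(Sys.time() - t1, units = "secs"))
    variants <- list(list(name = kind, part = NULL))
    if (config$withParticipant) {
      pm <- as.matrix(cohort$participants[match(ds$videoId,
                                                cohort$participants$id),
                                          c("age", "bmi",
                                            "abstinence_days")])
      variants <- c(variants, list(list(name = paste0(kind, "+pd"),
                                        part = pm)))
    }
    for (vt in variants) {
      t2 <- Sys.time()
      runner <- deepMethodRunner(kind, ds, labM, config$backbone,
                                 config$train, participants = vt$part,
                                 headWidth = config$headWidth)
      evals <- c(evals, list(evaluateMethod(runner, cohort$labels, split,
                                            methodName = vt$name)))
      say("[train+eval] %s in %.1fs", vt$name,
          as.numeric(Sys.time() - t2, units = "secs"))
    }
  }
  report <- compareMethods(evals, reference = "zeror", alpha = config$alpha)
  if (nzchar(config$outDir)) writeReport(report, config$outDir)
  report
}
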