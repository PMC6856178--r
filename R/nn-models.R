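# Deep regressors: convolutional backbones (a CPU-scale "tiny" net and
# scaled-down ResNet-18/50-style residual nets), the participant-data
# fusion head (global average pooling -> concatenation -> two 2048-unit
# dense layers -> 3 outputs), two-stream variants, and the training
# protocol (joint MSE over the three motility outputs, Nadam, early
# stopping with best-checkpoint selection).

convBnRelu <- function(cin, cout, k = 3, stride = 1)
  list(newConv(cin, cout, k, stride), newBatchNorm(cout), newReLU())

basicBlock <- function(cin, cout, stride) {
  main <- c(convBnRelu(cin, cout, 3, stride),
            list(newConv(cout, cout, 3, 1), newBatchNorm(cout)))
  proj <- if (stride != 1 || cin != cout)
    list(newConv(cin, cout, 1, stride, pad = 0), newBatchNorm(cout))
  list(newResidual(main, proj), newReLU())
}

bottleneckBlock <- function(cin, mid, stride) {
  cout <- 4 * mid
  main <- c(convBnRelu(cin, mid, 1, 1),
            convBnRelu(mid, mid, 3, stride),
            list(newConv(mid, cout, 1, 1, pad = 0), newBatchNorm(cout)))
  proj <- if (stride != 1 || cin != cout)
    list(newConv(cin, cout, 1, stride, pad = 0), newBatchNorm(cout))
  list(newResidual(main, proj), newReLU())
}

# Returns list(layers, outChannels). The final GAP layer is appended so a
# branch maps (H, W, C, N) -> (outChannels x N).
buildBackbone <- function(cfg) {
  stopifnot(is(cfg, "BackboneConfig"))
  cin <- cfg@inputShape[3]
  w <- cfg@baseWidth
  if (cfg@architectureId == "tiny") {
    layers <- c(convBnRelu(cin, w, 3, 2), convBnRelu(w, 2 * w, 3, 2),
                convBnRelu(2 * w, 4 * w, 3, 2), convBnRelu(4 * w, 4 * w, 3, 2))
    outC <- 4 * w
  } else if (cfg@architectureId == "resnet18_like") {
    layers <- convBnRelu(cin, w, 3, 1)
    plan <- list(c(w, 1), c(2 * w, 2), c(4 * w, 2), c(8 * w, 2))
    cur <- w
    for (st in plan) {
      layers <- c(layers, basicBlock(cur, st[1], st[2]),
                  basicBlock(st[1], st[1], 1))
      cur <- st[1]
    }
    outC <- cur
  } else {  # resnet50_like
    layers <- convBnRelu(cin, w, 3, 1)
    plan <- list(c(w, 1, 3), c(2 * w, 2, 4), c(4 * w, 2, 6), c(8 * w, 2, 3))
    cur <- w
    for (st in plan) {
      layers <- c(layers, bottleneckBlock(cur, st[1], st[2]))
      cur <- 4 * st[1]
      for (r in seq_len(st[3] - 1))
        layers <- c(layers, bottleneckBlock(cur, st[1], 1))
    }
    outC <- cur
  }
  list(layers = c(layers, list(newGAP())), outChannels = outC)
}

buildHead <- function(nin, headWidth, nout = 3, dropout = 0) {
  reg <- function() if (dropout > 0) list(newDropout(dropout)) else list()
  c(list(newDense(nin, headWidth), newReLU()), reg(),
    list(newDense(headWidth, headWidth), newReLU()), reg(),
    list(newDense(headWidth, nout)))
}

#' Build a convolutional motility regressor
#'
#' One backbone branch, global average pooling, optional concatenation of
#' the participant covariate vector, then two dense hidden layers of
#' \code{headWidth} units (2048 in the reference configuration) and a
#' 3-unit linear output — one value per motility variable.
#'
#' @param backbone a \code{\link{backboneConfig}}.
#' @param withParticipant fuse participant data into the head?
#' @param participantDim covariate count (3, or 4 with concentration).
#' @param headWidth hidden width of the fusion head (default 2048).
#' @param headDropout dropout rate after each hidden head layer during
#'   training (0 disables).
#' @param modalityDropout probability of blanking the whole covariate
#'   vector of a training sample (multimodal regularisation: with few
#'   training videos the covariate triple uniquely identifies a video, so
#'   an unregularised fusion head memorises labels through it).
#' @param seed seed for weight initialisation.
#' @return A model handle (environment) for \code{\link{trainModel}} /
#'   \code{\link{predictModel}}.
#' @export
buildRegressor <- function(backbone, withParticipant = FALSE,
                           participantDim = 3, headWidth = 2048,
                           headDropout = 0, modalityDropout = 0.5,
                           seed = 1) {
  set.seed(seed)
  bb <- buildBackbone(backbone)
  nin <- bb$outChannels + if (withParticipant) participantDim else 0
  model <- new.env(parent = emptyenv())
  model$branches <- list(bb$layers)
  model$inputShapes <- list(backbone@inputShape)
  model$head <- buildHead(nin, headWidth, dropout = headDropout)
  # the covariate path starts inert: a fusion model is initialised to
  # compute exactly what the image-only model computes, and only moves
  # weight onto the covariates if their gradient supports it
  if (withParticipant)
    model$head[[1]]$par$W[bb$outChannels + seq_len(participantDim), ] <- 0
  model$withParticipant <- withParticipant
  model$modalityDropout <- if (withParticipant) modalityDropout else 0
  model$participantDim <- if (withParticipant) participantDim else 0
  model$featDim <- bb$outChannels
  model$headWidth <- headWidth
  model$t <- 0L
  model
}

#' Build a two-stream motility regressor
#'
#' Parallel appearance and motion branches: the raw anchor frame passes
#' through one backbone, the optical-flow representation (sparse RGB, dense
#' RGB, or the 6-channel sparse+dense stack) through another. Both pooled
#' vectors are concatenated (plus participant data when enabled) and fed to
#' the shared fusion head.
#'
#' @param frameBranch,flowBranch \code{\link{backboneConfig}}s for the two
#'   streams; the flow branch's channel count selects the variant (3 or 6).
#' @inheritParams buildRegressor
#' @return A model handle.
#' @export
buildTwoStream <- function(frameBranch, flowBranch, withParticipant = FALSE,
                           participantDim = 3, headWidth = 2048,
                           headDropout = 0, modalityDropout = 0.5,
                           seed = 1) {
  set.seed(seed)
  b1 <- buildBackbone(frameBranch)
  b2 <- buildBackbone(flowBranch)
  nin <- b1$outChannels + b2$outChannels +
    if (withParticipant) participantDim else 0
  model <- new.env(parent = emptyenv())
  model$branches <- list(b1$layers, b2$layers)
  model$inputShapes <- list(frameBranch@inputShape, flowBranch@inputShape)
  model$head <- buildHead(nin, headWidth, dropout = headDropout)
  if (withParticipant)
    model$head[[1]]$par$W[b1$outChannels + b2$outChannels +
                            seq_len(participantDim), ] <- 0
  model$withParticipant <- withParticipant
  model$modalityDropout <- if (withParticipant) modalityDropout else 0
  model$participantDim <- if (withParticipant) participantDim else 0
  model$featDim <- b1$outChannels + b2$outChannels
  model$headWidth <- headWidth
  model$t <- 0L
  model
}

modelParamLayers <- function(model) {
  out <- list()
  for (br in model$branches) out <- c(out, collectLayers(br))
  c(out, collectLayers(model$head))
}

forwardModel <- function(model, xs, pmat = NULL, train = FALSE) {
  pooled <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    d <- dim(xs[[i]])
    exp <- model$inputShapes[[i]]
    if (!all(d[1:3] == exp))
      stop(sprintf("branch %d input shape (%s) does not match config (%s)",
                   i, paste(d[1:3], collapse = "x"),
                   paste(exp, collapse = "x")))
    pooled[[i]] <- forwardSeq(model$branches[[i]], xs[[i]], train)
  }
  feat <- do.call(rbind, pooled)
  if (model$withParticipant) {
    if (is.null(pmat)) stop("model expects participant data")
    feat <- rbind(feat, pmat)
  }
  if (train) model$branchRows <- vapply(pooled, nrow, integer(1))
  forwardSeq(model$head, feat, train)
}

backwardModel <- function(model, dout) {
  dfeat <- backwardSeq(model$head, dout)
  rows <- model$branchRows
  at <- 0
  for (i in seq_along(model$branches)) {
    dbr <- dfeat[(at + 1):(at + rows[i]), , drop = FALSE]
    backwardSeq(model$branches[[i]], dbr)
    at <- at + rows[i]
  }
  invisible(NULL)
}

# assemble a batch 4D array from a list of 3D sample tensors
bindBatch <- function(tensors, idx) {
  d <- dim(tensors[[idx[1]]])
  array(unlist(tensors[idx], use.names = FALSE), c(d, length(idx)))
}

# Split sample tensors into per-branch lists; single-stream models get a
# one-element list.
sampleBranches <- function(samples) {
  first <- samples[[1]]$tensor
  if (is.list(first))
    list(lapply(samples, function(s) s$tensor$frame),
         lapply(samples, function(s) s$tensor$flow))
  else list(lapply(samples, function(s) s$tensor))
}

#' Train a deep motility regressor
#'
#' Minimises the mean squared error over the three outputs jointly with the
#' Nadam optimiser, evaluating the validation MSE each epoch. Training
#' stops when the validation MSE has not improved for \code{patience}
#' epochs, and the returned model carries the weights of the epoch with the
#' minimum validation MSE, not the last epoch. Image inputs are scaled to
#' \[0, 1\] and targets to \[0, 1\] internally; participant covariates are
#' z-scored with training-set statistics stored on the model.
#'
#' @param model handle from \code{\link{buildRegressor}} /
#'   \code{\link{buildTwoStream}}.
#' @param samples list of representation samples
#'   (\code{\link{buildRepresentation}}).
#' @param labels N x 3 matrix of motility percentages (one row per sample).
#' @param valIdx indices of validation samples; the rest train. Train and
#'   validation must come from disjoint video sets.
#' @param cfg a \code{\link{trainConfig}}.
#' @param participants optional N x p matrix of covariates.
#' @param videoId optional character vector used to assert the train/val
#'   video-level split.
#' @param verbose print per-epoch losses.
#' @return The model handle, with \code{model$history} (per-epoch train/val
#'   MSE, percent^2 scale) and \code{model$bestEpoch} set.
#' @export
trainModel <- function(model, samples, labels, valIdx, cfg = trainConfig(),
                       participants = NULL, videoId = NULL,
                       verbose = FALSE) {
  stopifnot(is(cfg, "TrainConfig"))
  n <- length(samples)
  labels <- as.matrix(labels)
  if (nrow(labels) != n) stop("labels must have one row per sample")
  trainIdx <- setdiff(seq_len(n), valIdx)
  if (length(trainIdx) == 0 || length(valIdx) == 0)
    stop("empty train or validation split")
  if (!is.null(videoId) &&
      length(intersect(videoId[trainIdx], videoId[valIdx])) > 0)
    stop("train and validation sets share video ids (leakage)")
  set.seed(as.integer(cfg@seed))
  branches <- sampleBranches(samples)
  y <- t(labels) / 100                      # 3 x N, unit scale
  pmat <- NULL
  if (model$withParticipant) {
    if (is.null(participants)) stop("model expects participant data")
    participants <- as.matrix(participants)
    mu <- colMeans(participants[trainIdx, , drop = FALSE])
    sdv <- apply(participants[trainIdx, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    model$pScale <- list(mu = mu, sd = sdv)
    pmat <- t(sweep(sweep(participants, 2, mu), 2, sdv, "/"))
  }
  # start the output layer at the training-mean label
  outLayer <- model$head[[length(model$head)]]
  outLayer$par$b <- rowMeans(y[, trainIdx, drop = FALSE])
  paramLayers <- modelParamLayers(model)
  evalMse <- function(idx) {
    tot <- 0
    for (ch in split(idx, ceiling(seq_along(idx) / cfg@batchSize))) {
      xs <- lapply(branches, function(br) bindBatch(br, ch) / 255)
      out <- forwardModel(model, xs,
                          if (!is.null(pmat)) pmat[, ch, drop = FALSE],
                          train = FALSE)
      tot <- tot + sum((out - y[, ch, drop = FALSE])^2)
    }
    tot / (3 * length(idx))
  }
  state <- earlyStopInit(cfg@patience)
  best <- snapshotParams(paramLayers)
  history <- data.frame(epoch = integer(0), trainMse = numeric(0),
                        valMse = numeric(0))
  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- sample(trainIdx)
    chunks <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
    trainLoss <- 0
    for (ch in chunks) {
      xs <- lapply(branches, function(br) bindBatch(br, ch) / 255)
      if (cfg@augment) {
        # spatial symmetries leave motility fractions unchanged
        flipH <- runif(1) < 0.5; flipW <- runif(1) < 0.5
        transpose <- runif(1) < 0.5
        if (flipH) xs <- lapply(xs, function(x)
          x[dim(x)[1]:1, , , , drop = FALSE])
        if (flipW) xs <- lapply(xs, function(x)
          x[, dim(x)[2]:1, , , drop = FALSE])
        if (transpose) xs <- lapply(xs, function(x)
          if (dim(x)[1] == dim(x)[2]) aperm(x, c(2, 1, 3, 4)) else x)
      }
      pch <- if (!is.null(pmat)) pmat[, ch, drop = FALSE]
      if (!is.null(pch) && model$modalityDropout > 0) {
        blank <- runif(ncol(pch)) < model$modalityDropout
        pch[, blank] <- 0
      }
      out <- forwardModel(model, xs, pch, train = TRUE)
      err <- out - y[, ch, drop = FALSE]
      trainLoss <- trainLoss + sum(err^2)
      backwardModel(model, 2 * err / length(err))
      model$t <- model$t + 1L
      nadamStep(paramLayers, cfg@learningRate, cfg@beta1, cfg@beta2, model$t)
    }
    valMse <- evalMse(valIdx)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                trainMse = 1e4 * trainLoss /
                                  (3 * length(trainIdx)),
                                valMse = 1e4 * valMse))
    if (verbose)
      message(sprintf("epoch %3d  train %8.3f  val %8.3f", epoch,
                      history$trainMse[epoch], history$valMse[epoch]))
    state <- earlyStopUpdate(state, valMse)
    if (state$bestEpoch == epoch) best <- snapshotParams(paramLayers)
    if (state$stop) break
  }
  restoreParams(paramLayers, best)
  model$history <- history
  model$bestEpoch <- state$bestEpoch
  model
}

#' Predict motility labels for representation samples
#'
#' @param model trained model handle.
#' @param samples list of representation samples.
#' @param participants optional covariate matrix (raw scale; the model's
#'   stored training z-scoring is applied).
#' @param batchSize forward-pass batch size.
#' @param tta average predictions over the four spatial flip variants
#'   (test-time augmentation); motility fractions are flip-invariant.
#' @return N x 3 matrix of percentages clipped to \[0, 100\], columns
#'   progressive / non_progressive / immotile.
#' @export
predictModel <- function(model, samples, participants = NULL,
                         batchSize = 32, tta = FALSE) {
  branches <- sampleBranches(samples)
  n <- length(samples)
  pmat <- NULL
  if (model$withParticipant) {
    if (is.null(participants)) stop("model expects participant data")
    participants <- as.matrix(participants)
    pmat <- t(sweep(sweep(participants, 2, model$pScale$mu), 2,
                    model$pScale$sd, "/"))
  }
  variants <- if (tta) list(c(FALSE, FALSE), c(TRUE, FALSE),
                            c(FALSE, TRUE), c(TRUE, TRUE))
              else list(c(FALSE, FALSE))
  out <- matrix(0, n, 3)
  for (ch in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    xs0 <- lapply(branches, function(br) bindBatch(br, ch) / 255)
    acc <- 0
    for (v in variants) {
      xs <- xs0
      if (v[1]) xs <- lapply(xs, function(x) x[dim(x)[1]:1, , , ,
                                               drop = FALSE])
      if (v[2]) xs <- lapply(xs, function(x) x[, dim(x)[2]:1, , ,
                                               drop = FALSE])
      acc <- acc + forwardModel(model, xs,
                                if (!is.null(pmat))
                                  pmat[, ch, drop = FALSE],
                                train = FALSE)
    }
    out[ch, ] <- t(acc / length(variants)) * 100
  }
  out <- clipRange(out, 0, 100)
  colnames(out) <- c("progressive", "non_progressive", "immotile")
  out
}

#' Aggregate per-sample predictions to per-video labels
#'
#' The models predict per sample; the per-video prediction compared against
#' the single manual label is the unweighted mean over that video's
#' samples (permutation-invariant).
#'
#' @param predictions N x 3 matrix from \code{\link{predictModel}}.
#' @param videoId character vector of length N.
#' @return data.frame with id and the three mean predicted percentages.
#' @export
aggregateVideo <- function(predictions, videoId) {
  stopifnot(nrow(predictions) == length(videoId))
  ids <- unique(videoId)
  agg <- t(vapply(ids, function(v)
    colMeans(predictions[videoId == v, , drop = FALSE]), numeric(3)))
  data.frame(id = ids, progressive = agg[, 1], non_progressive = agg[, 2],
             immotile = agg[, 3], stringsAsFactors = FALSE)
}
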