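#' @import methods
#' @importFrom stats rnorm runif sd var quantile predict coef pt setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib motiliflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# MotilityLabel
# ---------------------------------------------------------------------------

#' MotilityLabel: the three WHO motility percentages
#'
#' A triple of percentages (progressive, non-progressive, immotile) that sums
#' to 100. This is the regression target of every model in the package.
#'
#' @slot progressive percentage of progressively motile spermatozoa.
#' @slot nonprogressive percentage of non-progressively motile spermatozoa.
#' @slot immotile percentage of immotile spermatozoa.
#' @export
setClass("MotilityLabel",
  representation(progressive = "numeric", nonprogressive = "numeric",
                 immotile = "numeric"),
  validity = function(object) {
    v <- c(object@progressive, object@nonprogressive, object@immotile)
    if (length(v) != 3 || any(!is.finite(v)))
      return("all three percentages must be finite scalars")
    if (any(v < 0)) return("percentages must be >= 0")
    if (abs(sum(v) - 100) > 1e-6)
      return(sprintf("percentages must sum to 100 (got %.8f)", sum(v)))
    TRUE
  })

#' Construct a MotilityLabel
#'
#' @param progressive,nonprogressive,immotile percentages in \[0, 100\],
#'   summing to 100.
#' @return A \code{MotilityLabel}.
#' @examples
#' motilityLabel(50, 20, 30)
#' @export
motilityLabel <- function(progressive, nonprogressive, immotile) {
  new("MotilityLabel", progressive = as.numeric(progressive),
      nonprogressive = as.numeric(nonprogressive),
      immotile = as.numeric(immotile))
}

#' @describeIn motilityLabel coerce to a named numeric triple.
#' @param x a \code{MotilityLabel}.
#' @export
labelVector <- function(x) {
  stopifnot(is(x, "MotilityLabel"))
  c(progressive = x@progressive, nonprogressive = x@nonprogressive,
    immotile = x@immotile)
}

setMethod("show", "MotilityLabel", function(object) {
  cat(sprintf("MotilityLabel: progressive %.2f%% | non-progressive %.2f%% | immotile %.2f%%\n",
              object@progressive, object@nonprogressive, object@immotile))
})

# ---------------------------------------------------------------------------
# Synthetic-cohort parameter classes
# ---------------------------------------------------------------------------

#' Kinematic parameters of the synthetic sperm classes
#'
#' Per-frame motion parameters for the three particle classes that define
#' ground-truth motility in simulated videos: directed movers (progressive),
#' confined in-place jitterers (non-progressive) and static particles
#' (immotile). Class separability requires the progressive per-frame speed to
#' exceed twice the non-progressive jitter step.
#'
#' @slot progressiveSpeed mean per-frame displacement of progressive
#'   particles (px/frame, > 0).
#' @slot progressiveHeadingSigma per-frame heading noise (radians).
#' @slot nonprogJitter per-frame random-walk step (px) of non-progressive
#'   particles.
#' @slot nonprogConfineRadius maximum displacement (px) of a non-progressive
#'   particle from its anchor point.
#' @slot immotileJitter sub-pixel tremor amplitude (px), in \[0, 0.5).
#' @export
setClass("KinematicsParams",
  representation(progressiveSpeed = "numeric",
                 progressiveHeadingSigma = "numeric",
                 nonprogJitter = "numeric",
                 nonprogConfineRadius = "numeric",
                 immotileJitter = "numeric"),
  prototype(progressiveSpeed = 3, progressiveHeadingSigma = 0.2,
            nonprogJitter = 1, nonprogConfineRadius = 6,
            immotileJitter = 0.3),
  validity = function(object) {
    if (object@progressiveSpeed <= 0) return("progressiveSpeed must be > 0")
    if (object@progressiveSpeed <= 2 * object@nonprogJitter)
      return("progressiveSpeed must exceed 2 * nonprogJitter (class separability)")
    if (object@nonprogJitter < 0 || object@nonprogConfineRadius <= 0)
      return("non-progressive jitter/confinement must be non-negative/positive")
    if (object@immotileJitter < 0 || object@immotileJitter >= 0.5)
      return("immotileJitter must be in [0, 0.5)")
    TRUE
  })

#' @rdname KinematicsParams-class
#' @param progressiveSpeed,progressiveHeadingSigma,nonprogJitter,nonprogConfineRadius,immotileJitter
#'   see the class slots.
#' @return A \code{KinematicsParams} object.
#' @examples
#' kinematicsParams(progressiveSpeed = 2.5)
#' @export
kinematicsParams <- function(progressiveSpeed = 3,
                             progressiveHeadingSigma = 0.2,
                             nonprogJitter = 1,
                             nonprogConfineRadius = 6,
                             immotileJitter = 0.3) {
  new("KinematicsParams", progressiveSpeed = progressiveSpeed,
      progressiveHeadingSigma = progressiveHeadingSigma,
      nonprogJitter = nonprogJitter,
      nonprogConfineRadius = nonprogConfineRadius,
      immotileJitter = immotileJitter)
}

#' Specification of one synthetic semen-sample video
#'
#' @slot nParticles number of sperm-like particles in the scene.
#' @slot classFractions proportions (progressive, non-progressive, immotile),
#'   summing to 1; the video's motility label is this triple times 100.
#' @slot frameSize (height, width) in px.
#' @slot nFrames number of frames.
#' @slot fps frame rate (frames/second); microscopy recordings emulated here
#'   use 50 fps.
#' @slot noiseSigma std. dev. of additive Gaussian background noise (8-bit
#'   intensity scale).
#' @slot headRadius radius (px) of the rendered sperm head disc.
#' @slot seed integer seed driving tracks, rendering noise and covariates.
#' @export
setClass("SyntheticVideoSpec",
  representation(nParticles = "numeric", classFractions = "numeric",
                 frameSize = "numeric", nFrames = "numeric", fps = "numeric",
                 noiseSigma = "numeric", headRadius = "numeric",
                 seed = "numeric"),
  prototype(nParticles = 40, classFractions = c(1, 1, 1) / 3,
            frameSize = c(64, 64), nFrames = 75, fps = 50, noiseSigma = 8,
            headRadius = 3, seed = 1),
  validity = function(object) {
    f <- object@classFractions
    if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      return("classFractions must be 3 non-negative proportions summing to 1")
    if (object@nFrames < 1) return("nFrames must be >= 1")
    if (object@fps <= 0) return("fps must be > 0")
    if (length(object@frameSize) != 2 || any(object@frameSize < 1))
      return("frameSize must be (height, width), both >= 1")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@headRadius <= 0) return("headRadius must be > 0")
    TRUE
  })

#' @rdname SyntheticVideoSpec-class
#' @param nParticles,classFractions,frameSize,nFrames,fps,noiseSigma,headRadius,seed
#'   see the class slots.
#' @return A \code{SyntheticVideoSpec}.
#' @examples
#' syntheticVideoSpec(nParticles = 10, classFractions = c(0.5, 0.3, 0.2))
#' @export
syntheticVideoSpec <- function(nParticles = 40,
                               classFractions = c(1, 1, 1) / 3,
                               frameSize = c(64, 64), nFrames = 75, fps = 50,
                               noiseSigma = 8, headRadius = 3, seed = 1) {
  new("SyntheticVideoSpec", nParticles = nParticles,
      classFractions = classFractions, frameSize = frameSize,
      nFrames = nFrames, fps = fps, noiseSigma = noiseSigma,
      headRadius = headRadius, seed = seed)
}

# ---------------------------------------------------------------------------
# FrameSequence
# ---------------------------------------------------------------------------

#' FrameSequence: ordered video frames with frame-rate metadata
#'
#' The unit every representation builder consumes. Frames are numeric
#' matrices (greyscale, H x W) or H x W x 3 arrays (colour) holding 8-bit
#' intensities in \[0, 255\]; all frames of a sequence share one shape.
#'
#' @slot frames list of frames.
#' @slot fps frames per second.
#' @slot sourceId identifier of the originating video.
#' @export
setClass("FrameSequence",
  representation(frames = "list", fps = "numeric", sourceId = "character"),
  validity = function(object) {
    if (length(object@frames) < 1) return("a FrameSequence needs >= 1 frame")
    if (object@fps <= 0) return("fps must be > 0")
    d1 <- dim(object@frames[[1]])
    if (is.null(d1)) return("frames must be matrices or H x W x 3 arrays")
    ok <- vapply(object@frames, function(f) identical(dim(f), d1), logical(1))
    if (!all(ok)) return("all frames must share one shape")
    TRUE
  })

#' @rdname FrameSequence-class
#' @param frames list of H x W matrices or H x W x 3 arrays in \[0, 255\].
#' @param fps frames per second (default 50).
#' @param sourceId video identifier.
#' @return A \code{FrameSequence}.
#' @export
frameSequence <- function(frames, fps = 50, sourceId = "video") {
  new("FrameSequence", frames = frames, fps = fps, sourceId = sourceId)
}

#' @rdname FrameSequence-class
#' @param x a \code{FrameSequence}.
#' @export
frames <- function(x) x@frames

#' @rdname FrameSequence-class
#' @export
fps <- function(x) x@fps

#' @rdname FrameSequence-class
#' @export
sourceId <- function(x) x@sourceId

#' @rdname FrameSequence-class
#' @export
numFrames <- function(x) length(x@frames)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]])
  kind <- if (length(d) == 2) "greyscale" else "colour"
  cat(sprintf("FrameSequence '%s': %d %s frame(s) of %d x %d at %g fps (%.1f s)\n",
              object@sourceId, length(object@frames), kind, d[1], d[2],
              object@fps, length(object@frames) / object@fps))
})

setMethod("length", "FrameSequence", function(x) length(x@frames))

# ---------------------------------------------------------------------------
# Sampling / representation configuration
# ---------------------------------------------------------------------------

#' Frame-sampling configuration
#'
#' Controls how many model-input samples are drawn per video and how many
#' consecutive frames each sample spans (30 for sequence representations,
#' 1 for single-frame prediction). The reference protocol draws 250 samples
#' per video, evenly distributed across the whole recording.
#'
#' @slot nSamples samples per video.
#' @slot seqLen frames per sample.
#' @export
setClass("SamplingConfig",
  representation(nSamples = "numeric", seqLen = "numeric"),
  prototype(nSamples = 250, seqLen = 30),
  validity = function(object) {
    if (object@nSamples < 1) return("nSamples must be >= 1")
    if (object@seqLen < 1) return("seqLen must be >= 1")
    TRUE
  })

#' @rdname SamplingConfig-class
#' @param nSamples samples per video (default 250).
#' @param seqLen frames per sample (default 30).
#' @return A \code{SamplingConfig}.
#' @export
samplingConfig <- function(nSamples = 250, seqLen = 30)
  new("SamplingConfig", nSamples = nSamples, seqLen = seqLen)

#' Dense optical-flow configuration
#'
#' Parameters of the Farneback polynomial-expansion flow estimator. The
#' stride is the frame gap between the two compared frames: 1 compares
#' consecutive frames, 10 accumulates motion over a ten-frame gap.
#'
#' @slot stride frame gap between compared frames.
#' @slot levels number of pyramid levels.
#' @slot winSize side of the Gaussian aggregation window (px).
#' @slot iterations displacement-refinement iterations per level.
#' @slot polyN neighbourhood half-width of the polynomial expansion.
#' @slot polySigma Gaussian applicability std. dev. of the expansion.
#' @export
setClass("DenseFlowConfig",
  representation(stride = "numeric", levels = "numeric", winSize = "numeric",
                 iterations = "numeric", polyN = "numeric",
                 polySigma = "numeric"),
  prototype(stride = 1, levels = 3, winSize = 15, iterations = 3, polyN = 5,
            polySigma = 1.2),
  validity = function(object) {
    if (object@stride < 1) return("stride must be >= 1")
    if (object@levels < 1 || object@iterations < 1)
      return("levels and iterations must be >= 1")
    if (object@polyN < 2 || object@winSize < 3)
      return("polyN must be >= 2 and winSize >= 3")
    TRUE
  })

#' @rdname DenseFlowConfig-class
#' @param stride,levels,winSize,iterations,polyN,polySigma see class slots.
#' @return A \code{DenseFlowConfig}.
#' @export
denseFlowConfig <- function(stride = 1, levels = 3, winSize = 15,
                            iterations = 3, polyN = 5, polySigma = 1.2)
  new("DenseFlowConfig", stride = stride, levels = levels, winSize = winSize,
      iterations = iterations, polyN = polyN, polySigma = polySigma)

#' Sparse optical-flow (trajectory image) configuration
#'
#' Corner detection on the first frame of a window followed by pyramidal
#' Lucas-Kanade tracking across the window; surviving tracks are rendered as
#' coloured polylines.
#'
#' @slot maxCorners maximum number of tracked corners.
#' @slot cornerQuality minimum corner quality relative to the strongest.
#' @slot minCornerDistance minimum pairwise distance between corners (px).
#' @slot lkWindow Lucas-Kanade integration window side (px).
#' @slot seqLen frames tracked per trajectory image.
#' @export
setClass("SparseFlowConfig",
  representation(maxCorners = "numeric", cornerQuality = "numeric",
                 minCornerDistance = "numeric", lkWindow = "numeric",
                 seqLen = "numeric"),
  prototype(maxCorners = 60, cornerQuality = 0.05, minCornerDistance = 4,
            lkWindow = 15, seqLen = 30),
  validity = function(object) {
    v <- c(object@maxCorners, object@cornerQuality, object@minCornerDistance,
           object@lkWindow, object@seqLen)
    if (any(v <= 0)) return("all sparse-flow parameters must be positive")
    TRUE
  })

#' @rdname SparseFlowConfig-class
#' @param maxCorners,cornerQuality,minCornerDistance,lkWindow,seqLen see
#'   class slots.
#' @return A \code{SparseFlowConfig}.
#' @export
sparseFlowConfig <- function(maxCorners = 60, cornerQuality = 0.05,
                             minCornerDistance = 4, lkWindow = 15,
                             seqLen = 30)
  new("SparseFlowConfig", maxCorners = maxCorners,
      cornerQuality = cornerQuality, minCornerDistance = minCornerDistance,
      lkWindow = lkWindow, seqLen = seqLen)

# ---------------------------------------------------------------------------
# Model / training / evaluation configuration
# ---------------------------------------------------------------------------

#' Convolutional backbone configuration
#'
#' @slot architectureId one of \code{"tiny"} (four strided conv blocks, for
#'   CPU-scale experiments), \code{"resnet18_like"} (basic residual blocks,
#'   stage plan 2-2-2-2) or \code{"resnet50_like"} (bottleneck residual
#'   blocks, stage plan 3-4-6-3).
#' @slot inputShape (H, W, C); C must match the representation kind
#'   (1, 3, 6 or 30 channels).
#' @slot baseWidth channel count of the first stage; deeper stages double it.
#' @slot pretrained reserved flag for externally initialised weights;
#'   only meaningful for 3-channel single-frame inputs and off by default.
#' @export
setClass("BackboneConfig",
  representation(architectureId = "character", inputShape = "numeric",
                 baseWidth = "numeric", pretrained = "logical"),
  prototype(architectureId = "tiny", inputShape = c(64, 64, 1),
            baseWidth = 16, pretrained = FALSE),
  validity = function(object) {
    if (!object@architectureId %in%
        c("tiny", "resnet18_like", "resnet50_like"))
      return("architectureId must be tiny, resnet18_like or resnet50_like")
    if (length(object@inputShape) != 3 || any(object@inputShape < 1))
      return("inputShape must be (H, W, C)")
    if (!object@inputShape[3] %in% c(1, 3, 6, 30))
      return("input channel count must be one of 1, 3, 6, 30")
    if (object@pretrained && object@inputShape[3] != 3)
      return("pretrained weights are only defined for 3-channel inputs")
    TRUE
  })

#' @rdname BackboneConfig-class
#' @param architectureId,inputShape,baseWidth,pretrained see class slots.
#' @return A \code{BackboneConfig}.
#' @export
backboneConfig <- function(architectureId = "tiny", inputShape = c(64, 64, 1),
                           baseWidth = 16, pretrained = FALSE)
  new("BackboneConfig", architectureId = architectureId,
      inputShape = inputShape, baseWidth = baseWidth, pretrained = pretrained)

#' Training protocol configuration
#'
#' Mean-squared-error loss over the three motility outputs jointly, a
#' Nadam optimiser (learning rate 0.002, beta1 0.900, beta2 0.999), early
#' stopping once the validation MSE has not improved for \code{patience}
#' epochs, and selection of the checkpoint with minimum validation MSE.
#'
#' @slot learningRate Nadam step size.
#' @slot beta1,beta2 Nadam moment decay rates.
#' @slot patience epochs without validation improvement before stopping.
#' @slot maxEpochs hard epoch cap.
#' @slot batchSize minibatch size.
#' @slot augment random horizontal/vertical flips of training batches
#'   (label-preserving for motility fractions; default off).
#' @slot seed integer seed for weight init and batch shuffling.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", patience = "numeric",
                 maxEpochs = "numeric", batchSize = "numeric",
                 augment = "logical", seed = "numeric"),
  prototype(learningRate = 0.002, beta1 = 0.900, beta2 = 0.999,
            patience = 20, maxEpochs = 200, batchSize = 16,
            augment = FALSE, seed = 1),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@patience < 1) return("patience must be >= 1")
    if (object@beta1 < 0 || object@beta1 >= 1 ||
        object@beta2 < 0 || object@beta2 >= 1)
      return("beta1 and beta2 must lie in [0, 1)")
    if (object@maxEpochs < 1 || object@batchSize < 1)
      return("maxEpochs and batchSize must be >= 1")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param learningRate,beta1,beta2,patience,maxEpochs,batchSize,augment,seed
#'   see class slots.
#' @return A \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.002, beta1 = 0.900, beta2 = 0.999,
                        patience = 20, maxEpochs = 200, batchSize = 16,
                        augment = FALSE, seed = 1)
  new("TrainConfig", learningRate = learningRate, beta1 = beta1,
      beta2 = beta2, patience = patience, maxEpochs = maxEpochs,
      batchSize = batchSize, augment = augment, seed = seed)

#' Corrected paired t-test configuration
#'
#' @slot alpha significance level (default 0.05).
#' @slot nTrain,nTest per-fold training and test sample counts; their ratio
#'   \code{nTest/nTrain} inflates the variance of the paired test to account
#'   for the dependence between cross-validation folds (0.5 for 3-fold CV).
#' @export
setClass("TTestConfig",
  representation(alpha = "numeric", nTrain = "numeric", nTest = "numeric"),
  prototype(alpha = 0.05, nTrain = 2, nTest = 1),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must be in (0, 1)")
    if (object@nTrain <= 0 || object@nTest <= 0)
      return("nTrain and nTest must be > 0")
    TRUE
  })

#' @rdname TTestConfig-class
#' @param alpha,nTrain,nTest see class slots.
#' @return A \code{TTestConfig}.
#' @export
tTestConfig <- function(alpha = 0.05, nTrain = 2, nTest = 1)
  new("TTestConfig", alpha = alpha, nTrain = nTrain, nTest = nTest)

#' Grouped cross-validation fold assignment
#'
#' @slot k number of folds.
#' @slot assignment named integer vector: video id -> fold index in 1..k.
#' @slot seed seed used for the shuffle.
#' @export
setClass("FoldSplit",
  representation(k = "numeric", assignment = "integer", seed = "numeric"),
  validity = function(object) {
    if (object@k < 2) return("k must be >= 2")
    if (is.null(names(object@assignment)))
      return("assignment must be named by video id")
    if (any(object@assignment < 1 | object@assignment > object@k))
      return("fold indices must lie in 1..k")
    sizes <- tabulate(object@assignment, nbins = object@k)
    if (max(sizes) - min(sizes) > 1)
      return("fold sizes must differ by at most 1")
    TRUE
  })

#' Cross-validated evaluation report
#'
#' One row per method with MAE for each motility variable, their average, and
#' the corrected paired t-test against a reference method.
#'
#' @slot table pooled per-method summary (data.frame).
#' @slot perFold per-method, per-fold MAE breakdown (data.frame).
#' @slot k number of CV folds.
#' @export
setClass("EvalReport",
  representation(table = "data.frame", perFold = "data.frame", k = "numeric"),
  validity = function(object) {
    need <- c("method", "progressive", "nonprogressive", "immotile", "average")
    if (!all(need %in% names(object@table)))
      return(paste("table must have columns:", paste(need, collapse = ", ")))
    TRUE
  })

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d method(s), %d-fold grouped cross-validation\n",
              nrow(object@table), object@k))
  tb <- object@table
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], round, 3)
  print(tb, row.names = FALSE)
})

#' @rdname EvalReport-class
#' @param x an \code{EvalReport}.
#' @export
reportTable <- function(x) x@table

#' @rdname EvalReport-class
#' @export
reportPerFold <- function(x) x@perFold
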