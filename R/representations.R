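# The four model-input representations built from frame windows:
# channel-wise greyscale stacks, vertical frame matrices, sparse-flow
# trajectory images and dense-flow images (plus the 6-channel pairing used
# by the two-stream stacked variant). All builders are deterministic given
# their inputs and configuration.

#' Stack greyscale frames channel-wise
#'
#' Converts a window of frames to greyscale and stacks them along the
#' channel axis, so a 30-frame window of 224 x 224 frames becomes a
#' 224 x 224 x 30 tensor whose channel j is frame j.
#'
#' @param frameList list of same-shape frames (grey or colour).
#' @return H x W x T numeric array.
#' @export
stackGreyscale <- function(frameList) {
  if (length(frameList) == 0) stop("empty frame window")
  grey <- lapply(frameList, toGreyscale)
  d <- dim(grey[[1]])
  same <- vapply(grey, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("mixed frame shapes in window")
  out <- array(0, c(d[1], d[2], length(grey)))
  for (j in seq_along(grey)) out[, , j] <- grey[[j]]
  out
}

#' Vertical frame matrix representation
#'
#' Each frame of the window is greyscaled, resized to 64 x 64 and flattened
#' row-major into a 4096-vector; the vectors are stacked as rows, giving a
#' T x 4096 x 1 tensor (30 x 4096 x 1 for the standard 30-frame window).
#'
#' @param frameList list of frames.
#' @param side resize target (default 64, giving 4096-long rows).
#' @return T x side^2 x 1 numeric array.
#' @export
verticalFrameMatrix <- function(frameList, side = 64) {
  if (length(frameList) == 0) stop("empty frame window")
  n <- length(frameList)
  out <- array(0, c(n, side * side, 1))
  for (j in seq_len(n)) {
    g <- resizeBilinear(toGreyscale(frameList[[j]]), side, side)
    out[j, , 1] <- as.vector(t(g))  # row-major flatten
  }
  out
}

#' Stack sparse and dense flow images channel-wise
#'
#' The two-stream "stacked" variant's flow input: the sparse trajectory
#' image occupies channels 1-3 and the dense flow image channels 4-6.
#'
#' @param sparseImg,denseImg H x W x 3 arrays of equal spatial shape.
#' @return H x W x 6 array.
#' @export
stackFlowPair <- function(sparseImg, denseImg) {
  if (!identical(dim(sparseImg)[1:2], dim(denseImg)[1:2]))
    stop("sparse and dense flow images must share spatial shape")
  out <- array(0, c(dim(sparseImg)[1], dim(sparseImg)[2], 6))
  out[, , 1:3] <- sparseImg
  out[, , 4:6] <- denseImg
  out
}

#' Dense-flow image for a frame window
#'
#' Computes dense flow between the window's anchor (first) frame and the
#' frame \code{stride} positions later, then encodes it with
#' \code{\link{flowToImage}}. Stride 1 compares consecutive frames; stride
#' 10 accumulates motion over a ten-frame gap, which enlarges the measured
#' displacement.
#'
#' @param seq a \code{\link{frameSequence}} window with at least
#'   \code{stride + 1} frames.
#' @param cfg a \code{\link{denseFlowConfig}}.
#' @return H x W x 3 RGB array.
#' @export
sequenceFlowImage <- function(seq, cfg = denseFlowConfig()) {
  stopifnot(is(seq, "FrameSequence"))
  if (length(seq@frames) < cfg@stride + 1)
    stop(sprintf("window too short: need >= %d frames for stride %d",
                 cfg@stride + 1, cfg@stride))
  a <- toGreyscale(seq@frames[[1]])
  b <- toGreyscale(seq@frames[[1 + cfg@stride]])
  flowToImage(denseFlow(a, b, cfg))
}

representationKinds <- function()
  c("single_frame", "grey_stack", "frame_matrix", "sparse_flow",
    "dense_flow", "flow_pair", "two_stream_sparse", "two_stream_dense",
    "two_stream_stacked")

#' Build one representation sample from a frame window
#'
#' Dispatcher over the representation kinds. For single-stream kinds the
#' result's \code{tensor} is one array; the two-stream kinds return a list
#' of two arrays (raw anchor frame and flow image).
#'
#' @param window a \code{\link{frameSequence}} of \code{seqLen} frames
#'   starting at the sample's anchor.
#' @param kind one of \code{representationKinds()}.
#' @param denseCfg,sparseCfg flow configurations.
#' @param resizeTo optional (H, W) to resize frames before stacking.
#' @return list with \code{tensor}, \code{kind}, \code{sourceId},
#'   \code{startIndex}.
#' @export
buildRepresentation <- function(window, kind, denseCfg = denseFlowConfig(),
                                sparseCfg = sparseFlowConfig(),
                                resizeTo = NULL, startIndex = 1L) {
  kind <- match.arg(kind, representationKinds())
  rs <- function(f) if (is.null(resizeTo)) f else
    resizeBilinear(f, resizeTo[1], resizeTo[2])
  fr <- frames(window)
  anchorGrey <- function() {
    g <- rs(toGreyscale(fr[[1]]))
    array(g, c(dim(g), 1))
  }
  tensor <- switch(kind,
    single_frame = anchorGrey(),
    grey_stack = stackGreyscale(lapply(fr, function(f) rs(toGreyscale(f)))),
    frame_matrix = verticalFrameMatrix(fr),
    sparse_flow = sparseFlowImage(window, sparseCfg),
    dense_flow = sequenceFlowImage(window, denseCfg),
    flow_pair = stackFlowPair(sparseFlowImage(window, sparseCfg),
                              sequenceFlowImage(window, denseCfg)),
    two_stream_sparse = list(frame = anchorGrey(),
                             flow = sparseFlowImage(window, sparseCfg)),
    two_stream_dense = list(frame = anchorGrey(),
                            flow = sequenceFlowImage(window, denseCfg)),
    two_stream_stacked = list(frame = anchorGrey(),
                              flow = stackFlowPair(
                                sparseFlowImage(window, sparseCfg),
                                sequenceFlowImage(window, denseCfg))))
  list(tensor = tensor, kind = kind, sourceId = sourceId(window),
       startIndex = startIndex)
}

#' Build a representation dataset for a cohort of videos
#'
#' For every video, draws \code{nSamples} evenly distributed windows of
#' \code{seqLen} frames (\code{\link{sampleEvenly}}) and builds the chosen
#' representation for each. Sample i of video v inherits v's motility label.
#'
#' @param videos list of \code{\link{frameSequence}} objects.
#' @param kind representation kind.
#' @param sampling a \code{\link{samplingConfig}}.
#' @param denseCfg,sparseCfg flow configurations.
#' @param resizeTo optional (H, W) frame resize.
#' @return list with \code{samples} (list of representation samples) and
#'   \code{videoId} (character vector, one per sample).
#' @export
buildCohortSamples <- function(videos, kind, sampling = samplingConfig(),
                               denseCfg = denseFlowConfig(),
                               sparseCfg = sparseFlowConfig(),
                               resizeTo = NULL) {
  samples <- list(); videoId <- character(0)
  # single-frame prediction samples single frames; all sequence
  # representations use the configured window
  seqLen <- if (kind == "single_frame") 1 else sampling@seqLen
  for (v in videos) {
    starts <- sampleEvenly(length(v@frames),
                           samplingConfig(sampling@nSamples, seqLen))
    for (s in starts) {
      win <- frameSequence(v@frames[s:(s + seqLen - 1)], fps = v@fps,
                           sourceId = v@sourceId)
      samples[[length(samples) + 1]] <-
        buildRepresentation(win, kind, denseCfg, sparseCfg, resizeTo,
                            startIndex = s)
      videoId <- c(videoId, v@sourceId)
    }
  }
  list(samples = samples, videoId = videoId)
}
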