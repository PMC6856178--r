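# Frame I/O and the two frame-sampling strategies.
#
# Videos are read from directories of numbered PNG frames (the package's
# on-disk video format; microscopy recordings are exported to frame
# directories before analysis). Frame-rate metadata travels in an optional
# meta.json ({"fps": 50}) next to the frames; without it the nominal 50 fps
# of the emulated recordings is assumed.

#' Read a video from a directory of numbered PNG frames
#'
#' Frames are read in lexicographic filename order. Colour PNGs are kept as
#' H x W x 3 arrays, greyscale as matrices; intensities are rescaled to the
#' 8-bit \[0, 255\] range. An optional \code{meta.json} file in the directory
#' supplies the frame rate.
#'
#' @param path directory containing \code{*.png} frames.
#' @param defaultFps frame rate used when no metadata is present.
#' @return A \code{\link{frameSequence}}.
#' @export
readVideo <- function(path, defaultFps = 50) {
  if (!file.exists(path))
    stop(sprintf("video source does not exist: %s", path))
  if (!dir.exists(path))
    stop(sprintf(paste("'%s' is not a frame directory; decode container",
                       "files to numbered PNG frames first"), path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no PNG frames found in %s", path))
  fpsVal <- defaultFps
  meta <- file.path(path, "meta.json")
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta)
    if (!is.null(m$fps)) fpsVal <- as.numeric(m$fps)
  }
  fr <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) {
      if (dim(a)[3] >= 3) a <- a[, , 1:3] else a <- a[, , 1]
    }
    a * 255
  })
  frameSequence(fr, fps = fpsVal, sourceId = basename(path))
}

#' Write a FrameSequence as a directory of numbered PNG frames
#'
#' The inverse of \code{\link{readVideo}}: frames become
#' \code{frame_000000.png, ...} plus a \code{meta.json} holding the frame
#' rate.
#'
#' @param seq a \code{\link{frameSequence}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFrameDir <- function(seq, dir) {
  stopifnot(is(seq, "FrameSequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq@frames)) {
    f <- clipRange(seq@frames[[i]] / 255, 0, 1)
    png::writePNG(f, file.path(dir, sprintf("frame_%06d.png", i - 1)))
  }
  jsonlite::write_json(list(fps = seq@fps),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Convert a frame to greyscale
#'
#' BT.601 luma conversion (weights 0.299 / 0.587 / 0.114), rounded back to
#' the 8-bit integer scale. Greyscale input is returned unchanged, making
#' the conversion idempotent.
#'
#' @param frame H x W matrix or H x W x 3 array in \[0, 255\].
#' @return H x W greyscale matrix.
#' @examples
#' toGreyscale(array(c(255, 0, 0), c(1, 1, 3)))  # pure red -> 76
#' @export
toGreyscale <- function(frame) {
  d <- dim(frame)
  if (length(d) == 2) return(frame)
  if (length(d) == 3 && d[3] == 3)
    return(round(0.299 * frame[, , 1] + 0.587 * frame[, , 2] +
                 0.114 * frame[, , 3]))
  if (length(d) == 3 && d[3] == 1) return(frame[, , 1])
  stop("frame must be H x W or H x W x 3")
}

#' First-and-middle-frame sampling
#'
#' The classical-baseline sampling scheme: for each of the first
#' \code{seconds} seconds of video, take the first and the middle frame of
#' that second — two frames per second, 120 frames for a 60 s window.
#'
#' @param seq a \code{\link{frameSequence}} spanning at least
#'   \code{seconds} seconds.
#' @param seconds length of the sampled window (default 60).
#' @return Sorted integer vector of 1-based frame indices, of length
#'   \code{2 * seconds}.
#' @export
sampleFirstMiddle <- function(seq, seconds = 60) {
  stopifnot(is(seq, "FrameSequence"))
  f <- seq@fps
  if (length(seq@frames) < seconds * f)
    stop(sprintf("video too short: %d frames < %g s at %g fps",
                 length(seq@frames), seconds, f))
  k <- 0:(seconds - 1)
  idx <- sort(c(k * f, k * f + floor(f / 2))) + 1L
  as.integer(idx)
}

#' Evenly distributed sample start indices
#'
#' Start indices of \code{nSamples} windows of \code{seqLen} frames spread
#' evenly across the whole video: the first window starts at the first
#' frame, the last ends at the last frame, intermediate starts are linearly
#' interpolated and rounded. Overlap between consecutive windows is allowed
#' when the video is short.
#'
#' @param totalFrames number of frames in the video.
#' @param cfg a \code{\link{samplingConfig}}.
#' @return Integer vector of 1-based start indices (monotone non-decreasing).
#' @examples
#' sampleEvenly(7500, samplingConfig(nSamples = 250, seqLen = 30))
#' @export
sampleEvenly <- function(totalFrames, cfg = samplingConfig()) {
  stopifnot(is(cfg, "SamplingConfig"))
  n <- cfg@nSamples; L <- cfg@seqLen
  if (totalFrames < L)
    stop(sprintf("insufficient frames: %d < seqLen %d", totalFrames, L))
  if (n == 1) return(1L)
  i <- 0:(n - 1)
  starts <- floor(i * (totalFrames - L) / (n - 1) + 0.5)  # round half up
  as.integer(starts) + 1L
}
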