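# Tamura texture descriptors: coarseness, contrast and a 16-bin
# directionality histogram. Flattened, one frame yields 18 values, so the
# classical baseline's 120 sampled frames give a 2160-dimensional
# per-video feature vector (2160 / 120 = 18 fixes this composition).

# Integral-image window means over (2s+1)-free square windows of side 2^k,
# evaluated at every pixel with replicate borders.
windowMeans <- function(img, size) {
  if (size == 1) return(img)
  half <- size / 2
  # pad so every pixel has a full window
  p <- padReplicate(img, ceiling(half) + 1)
  ii <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  h <- nrow(img); w <- ncol(img)
  offTop <- ceiling(half) + 1
  r0 <- (1:h) + offTop - half; r1 <- r0 + size - 1
  c0 <- (1:w) + offTop - half; c1 <- c0 + size - 1
  # sum over [r0..r1] x [c0..c1] via the integral image (prepend zero row/col)
  z <- matrix(0, nrow(ii) + 1, ncol(ii) + 1)
  z[-1, -1] <- ii
  s <- z[cbind(rep(r1 + 1, w), rep(c1 + 1, each = h))] -
       z[cbind(rep(r0, w), rep(c1 + 1, each = h))] -
       z[cbind(rep(r1 + 1, w), rep(c0, each = h))] +
       z[cbind(rep(r0, w), rep(c0, each = h))]
  matrix(s, h, w) / (size * size)
}

#' Tamura coarseness
#'
#' For every pixel, means over square windows of side 2^k (k = 0..kMax) are
#' compared through horizontal and vertical differences of windows shifted
#' by half the window size; the k maximising the difference is selected
#' (ties broken toward the smallest k, so a constant image has coarseness
#' 2^0 = 1) and the coarseness is the mean of 2^k over pixels. Invariant to
#' constant intensity offsets.
#'
#' @param img greyscale matrix, at least 32 x 32 for the full k range.
#' @param kMax largest window exponent (default 5); reduced with a warning
#'   when the image is too small.
#' @return scalar coarseness in \[1, 2^kMax\].
#' @export
tamuraCoarseness <- function(img, kMax = 5) {
  h <- nrow(img); w <- ncol(img)
  while (2^kMax > min(h, w) && kMax > 0) {
    kMax <- kMax - 1
    warning(sprintf("image too small for full window range; kMax reduced to %d",
                    kMax))
  }
  bestE <- matrix(-Inf, h, w)
  bestK <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in 0:kMax) {
    size <- 2^k
    m <- windowMeans(img, size)
    shift <- max(1, size / 2)
    mp <- padReplicate(m, shift)
    ctr <- function(dr, dc)
      mp[cbind(as.vector(rows + shift + dr), as.vector(cols + shift + dc))]
    eh <- abs(ctr(0, shift) - ctr(0, -shift))
    ev <- abs(ctr(shift, 0) - ctr(-shift, 0))
    e <- matrix(pmax(eh, ev), h, w)
    better <- e > bestE + 1e-12   # strict: ties keep the smaller k
    bestK[better] <- k
    bestE[better] <- e[better]
  }
  mean(2^bestK)
}

#' Tamura contrast
#'
#' \eqn{\sigma / \alpha_4^{1/4}} with \eqn{\alpha_4 = \mu_4 / \sigma^4}
#' (kurtosis); defined as 0 for a constant image. Scales linearly with
#' intensity: multiplying the image by c multiplies the contrast by c.
#'
#' @param img greyscale matrix.
#' @return scalar contrast.
#' @export
tamuraContrast <- function(img) {
  mu <- mean(img)
  s2 <- mean((img - mu)^2)
  if (s2 == 0) return(0)
  mu4 <- mean((img - mu)^4)
  alpha4 <- mu4 / s2^2
  sqrt(s2) / alpha4^0.25
}

#' Tamura directionality histogram
#'
#' Prewitt gradients; pixels whose gradient magnitude reaches
#' \code{threshold} contribute their edge direction
#' \eqn{\theta = \arctan(\Delta V / \Delta H) + \pi/2 \in [0, \pi)} to a
#' histogram of \code{bins} equal bins, normalised to sum 1. If no pixel
#' passes the threshold the histogram is uniform.
#'
#' @param img greyscale matrix.
#' @param bins number of orientation bins (default 16).
#' @param threshold gradient-magnitude threshold on the 8-bit scale
#'   (default 12).
#' @return numeric vector of length \code{bins} summing to 1.
#' @export
tamuraDirectionality <- function(img, bins = 16, threshold = 12) {
  prewittH <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # d/dx
  dH <- correlate3x3(img, prewittH) / 3
  dV <- correlate3x3(img, t(prewittH)) / 3
  mag <- (abs(dH) + abs(dV)) / 2
  sel <- mag >= threshold
  if (!any(sel)) return(rep(1 / bins, bins))
  h <- dH[sel]; v <- dV[sel]
  t0 <- ifelse(abs(h) > 1e-12, atan(v / h), pi / 2)
  theta <- t0 + pi / 2
  theta[theta >= pi] <- theta[theta >= pi] - pi   # wrap into [0, pi)
  idx <- floor(theta / (pi / bins)) + 1
  idx[idx > bins] <- bins
  hist <- tabulate(idx, nbins = bins)
  hist / sum(hist)
}

#' Full Tamura descriptor of one frame
#'
#' @param img greyscale matrix.
#' @return numeric vector of length 18: coarseness, contrast, then the
#'   16-bin directionality histogram.
#' @export
tamuraDescriptor <- function(img) {
  c(coarseness = tamuraCoarseness(img),
    contrast = tamuraContrast(img),
    setNames(tamuraDirectionality(img), paste0("dir", 1:16)))
}

#' Per-video Tamura feature vector
#'
#' The classical baseline's feature extraction: sample the first and middle
#' frame of each of the first 60 seconds (\code{\link{sampleFirstMiddle}};
#' 120 frames at any fps), compute the 18-value Tamura descriptor of each,
#' and concatenate in frame order into a 2160-dimensional vector.
#'
#' @param seq a \code{\link{frameSequence}} spanning at least
#'   \code{seconds} seconds.
#' @param seconds sampled window length (default 60).
#' @return numeric vector of length \code{2 * seconds * 18} (2160 for the
#'   default window) with the video id as attribute \code{"sourceId"}.
#' @export
videoFeatureVector <- function(seq, seconds = 60) {
  idx <- sampleFirstMiddle(seq, seconds)
  desc <- lapply(idx, function(i) tamuraDescriptor(toGreyscale(seq@frames[[i]])))
  out <- unlist(desc, use.names = FALSE)
  attr(out, "sourceId") <- seq@sourceId
  out
}
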