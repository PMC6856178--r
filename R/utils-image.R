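# Low-level image primitives shared by the flow estimators, texture
# descriptors and representation builders. Frames are numeric matrices
# indexed [row (y), column (x)], intensities on the 8-bit scale.

clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Replicate-pad a matrix by (py, px) on each side.
padReplicate <- function(img, py, px = py) {
  h <- nrow(img); w <- ncol(img)
  ri <- clipRange(seq_len(h + 2 * py) - py, 1, h)
  ci <- clipRange(seq_len(w + 2 * px) - px, 1, w)
  img[ri, ci, drop = FALSE]
}

# 1D correlation along matrix rows (i.e. across columns, the x axis) with
# replicate borders. kernel has odd length.
correlateRows <- function(img, kernel) {
  n <- length(kernel); r <- (n - 1) / 2
  p <- padReplicate(img, 0, r)
  out <- matrix(0, nrow(img), ncol(img))
  for (t in seq_len(n))
    out <- out + kernel[t] * p[, t:(t + ncol(img) - 1), drop = FALSE]
  out
}

# 1D correlation along matrix columns (the y axis) with replicate borders.
correlateCols <- function(img, kernel) {
  n <- length(kernel); r <- (n - 1) / 2
  p <- padReplicate(img, r, 0)
  out <- matrix(0, nrow(img), ncol(img))
  for (t in seq_len(n))
    out <- out + kernel[t] * p[t:(t + nrow(img) - 1), , drop = FALSE]
  out
}

# Separable 2D correlation: columns then rows.
correlateSep <- function(img, kCol, kRow = kCol)
  correlateRows(correlateCols(img, kCol), kRow)

# Full (non-separable) 3x3 correlation, used for the Prewitt operators.
correlate3x3 <- function(img, kernel) {
  stopifnot(identical(dim(kernel), c(3L, 3L)))
  p <- padReplicate(img, 1, 1)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3)
    if (kernel[i, j] != 0)
      out <- out + kernel[i, j] * p[i:(i + h - 1), j:(j + w - 1), drop = FALSE]
  out
}

gaussianKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Bilinearly sample img at fractional (row, col) coordinate matrices.
# Coordinates are clamped to the image domain (replicate behaviour).
bilinearSample <- function(img, rowCoord, colCoord) {
  h <- nrow(img); w <- ncol(img)
  r <- clipRange(rowCoord, 1, h)
  c <- clipRange(colCoord, 1, w)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- clipRange(r0, 1, h - 1); c0 <- clipRange(c0, 1, w - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i10 <- cbind(as.vector(r0 + 1), as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c0 + 1))
  i11 <- cbind(as.vector(r0 + 1), as.vector(c0 + 1))
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
       (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  matrix(v, nrow(rowCoord), ncol(rowCoord))
}

#' Bilinear image resize
#'
#' Resizes a greyscale matrix or H x W x 3 array to a new (height, width)
#' using bilinear interpolation with the pixel-centre coordinate convention.
#'
#' @param img numeric matrix or H x W x 3 array.
#' @param height,width output size in px.
#' @return resized matrix or array of the same channel count.
#' @export
resizeBilinear <- function(img, height, width) {
  if (length(dim(img)) == 3) {
    out <- array(0, c(height, width, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- resizeBilinear(img[, , ch], height, width)
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  if (h == height && w == width) return(img)
  # map output pixel centres onto input pixel centres
  rowSrc <- (seq_len(height) - 0.5) * h / height + 0.5
  colSrc <- (seq_len(width) - 0.5) * w / width + 0.5
  rc <- matrix(rowSrc, height, width)
  cc <- matrix(colSrc, height, width, byrow = TRUE)
  bilinearSample(img, rc, cc)
}
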