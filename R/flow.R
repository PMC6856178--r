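# Optical flow: dense two-frame estimation by Farneback polynomial
# expansion (multi-scale, iterative), sparse corner tracking by pyramidal
# Lucas-Kanade, and the encodings that turn either into model-input images.
#
# Flow convention: dx = displacement along columns (x), dy = along rows (y),
# both in px, describing motion from the first to the second frame.

# --- polynomial expansion -------------------------------------------------

# Quadratic polynomial expansion of an image under a Gaussian applicability:
# f(p + (x, y)) ~ c + bx x + by y + axx x^2 + ayy y^2 + axy x y.
# Returns per-pixel coefficient planes via separable correlations.
polyExpansion <- function(img, polyN = 5, polySigma = 1.2) {
  xk <- (-polyN):polyN
  g <- exp(-xk^2 / (2 * polySigma^2)); g <- g / sum(g)
  g0 <- g; g1 <- xk * g; g2 <- xk^2 * g
  s2 <- sum(g2)          # second moment of normalised g
  s4 <- sum(xk^4 * g)
  # normal-equation matrix for basis (1, x, y, x^2, y^2, xy)
  G <- matrix(0, 6, 6)
  G[1, 1] <- 1
  G[2, 2] <- G[3, 3] <- s2
  G[1, 4] <- G[4, 1] <- G[1, 5] <- G[5, 1] <- s2
  G[4, 4] <- G[5, 5] <- s4
  G[4, 5] <- G[5, 4] <- s2^2
  G[6, 6] <- s2^2
  Ginv <- solve(G)
  # moments m_{x^i y^j}: correlate rows (x) with gi, columns (y) with gj
  cc <- function(ki, kj) correlateCols(correlateRows(img, ki), kj)
  m <- list(cc(g0, g0),   # 1
            cc(g1, g0),   # x
            cc(g0, g1),   # y
            cc(g2, g0),   # x^2
            cc(g0, g2),   # y^2
            cc(g1, g1))   # xy
  coefName <- c("c", "bx", "by", "axx", "ayy", "axy")
  out <- setNames(vector("list", 6), coefName)
  for (i in 1:6) {
    acc <- 0
    for (j in 1:6) if (Ginv[i, j] != 0) acc <- acc + Ginv[i, j] * m[[j]]
    out[[i]] <- acc
  }
  out
}

# One flow-refinement pass at a single scale given expansions of both frames
# and the current flow estimate (dx0, dy0).
flowUpdate <- function(e1, e2, dx0, dy0, winSize) {
  h <- nrow(dx0); w <- ncol(dx0)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rT <- rows + dy0; cT <- cols + dx0
  samp <- function(p) bilinearSample(p, rT, cT)
  a11 <- (e1$axx + samp(e2$axx)) / 2
  a22 <- (e1$ayy + samp(e2$ayy)) / 2
  a12 <- (e1$axy + samp(e2$axy)) / 4   # off-diagonal of the averaged A
  db1 <- -0.5 * (samp(e2$bx) - e1$bx) + a11 * dx0 + a12 * dy0
  db2 <- -0.5 * (samp(e2$by) - e1$by) + a12 * dx0 + a22 * dy0
  # aggregate A^T A d = A^T db over a Gaussian window
  gw <- gaussianKernel1d(winSize / 4, radius = floor(winSize / 2))
  sm <- function(p) correlateSep(p, gw)
  G11 <- sm(a11^2 + a12^2)
  G12 <- sm(a12 * (a11 + a22))
  G22 <- sm(a22^2 + a12^2)
  h1 <- sm(a11 * db1 + a12 * db2)
  h2 <- sm(a12 * db1 + a22 * db2)
  det <- G11 * G22 - G12^2
  bad <- abs(det) < 1e-9
  det[bad] <- 1
  dx <- (G22 * h1 - G12 * h2) / det
  dy <- (G11 * h2 - G12 * h1) / det
  dx[bad] <- 0; dy[bad] <- 0
  list(dx = dx, dy = dy)
}

downsampleHalf <- function(img) {
  g <- gaussianKernel1d(1)
  s <- correlateSep(img, g)
  resizeBilinear(s, max(1, floor(nrow(img) / 2)), max(1, floor(ncol(img) / 2)))
}

#' Dense optical flow between two frames
#'
#' Estimates per-pixel displacement from \code{frameA} to \code{frameB} with
#' the Farneback polynomial-expansion method: each frame is locally
#' approximated by a quadratic polynomial under a Gaussian applicability,
#' and the displacement field that maps one expansion onto the other is
#' solved over a Gaussian aggregation window, iteratively and over an image
#' pyramid so that displacements of several pixels are recovered.
#'
#' @param frameA,frameB same-shape greyscale matrices.
#' @param cfg a \code{\link{denseFlowConfig}}.
#' @return A list of class \code{"FlowField"} with matrices \code{dx} and
#'   \code{dy} (px) of the frame shape.
#' @export
denseFlow <- function(frameA, frameB, cfg = denseFlowConfig()) {
  stopifnot(is(cfg, "DenseFlowConfig"))
  if (!identical(dim(frameA), dim(frameB)))
    stop("frames must share one shape")
  if (length(dim(frameA)) != 2)
    stop("dense flow expects greyscale frames")
  # pyramid (finest first)
  pyrA <- list(frameA); pyrB <- list(frameB)
  lv <- 1
  while (lv < cfg@levels && min(dim(pyrA[[lv]])) >= 16) {
    pyrA[[lv + 1]] <- downsampleHalf(pyrA[[lv]])
    pyrB[[lv + 1]] <- downsampleHalf(pyrB[[lv]])
    lv <- lv + 1
  }
  dx <- matrix(0, nrow(pyrA[[lv]]), ncol(pyrA[[lv]]))
  dy <- dx
  for (level in rev(seq_len(lv))) {
    a <- pyrA[[level]]; b <- pyrB[[level]]
    if (!identical(dim(dx), dim(a))) {
      dx <- 2 * resizeBilinear(dx, nrow(a), ncol(a))
      dy <- 2 * resizeBilinear(dy, nrow(a), ncol(a))
    }
    e1 <- polyExpansion(a, cfg@polyN, cfg@polySigma)
    e2 <- polyExpansion(b, cfg@polyN, cfg@polySigma)
    for (it in seq_len(cfg@iterations)) {
      upd <- flowUpdate(e1, e2, dx, dy, cfg@winSize)
      dx <- upd$dx; dy <- upd$dy
    }
  }
  structure(list(dx = dx, dy = dy), class = "FlowField")
}

#' Encode a dense flow field as an RGB image
#'
#' Standard HSV flow visualisation: hue encodes the flow angle, saturation
#' is maximal, and value is the flow magnitude normalised by the field's own
#' maximum (an all-zero field maps to a black image; scaling every vector by
#' a constant leaves the image unchanged).
#'
#' @param flow a \code{FlowField} from \code{\link{denseFlow}}.
#' @return H x W x 3 RGB array in \[0, 255\].
#' @export
flowToImage <- function(flow) {
  mag <- sqrt(flow$dx^2 + flow$dy^2)
  mx <- max(mag)
  v <- if (mx > 0) mag / mx else mag * 0
  ang <- atan2(flow$dy, flow$dx)          # [-pi, pi]
  hue <- (ang + pi) / (2 * pi)
  hue <- clipRange(hue, 0, 1)
  cols <- grDevices::hsv(h = as.vector(hue), s = 1, v = as.vector(v))
  rgb <- grDevices::col2rgb(cols)
  h <- nrow(mag); w <- ncol(mag)
  out <- array(0, c(h, w, 3))
  out[, , 1] <- matrix(rgb[1, ], h, w)
  out[, , 2] <- matrix(rgb[2, ], h, w)
  out[, , 3] <- matrix(rgb[3, ], h, w)
  out
}

# --- corner detection -----------------------------------------------------

#' Detect trackable corners (sperm heads) in a frame
#'
#' Shi-Tomasi variant of the Harris-Stephens corner measure: the minimum
#' eigenvalue of the locally averaged gradient structure tensor. Corners
#' below \code{quality} times the strongest response are rejected, and a
#' greedy minimum-distance pass enforces spatial separation.
#'
#' @param img greyscale matrix.
#' @param maxCorners maximum number of corners returned.
#' @param quality minimum accepted quality relative to the best corner.
#' @param minDistance minimum pairwise distance in px.
#' @return n x 2 matrix of (row, col) corner positions, strongest first;
#'   zero rows when the frame has no corner response.
#' @export
goodFeaturesToTrack <- function(img, maxCorners = 60, quality = 0.05,
                                minDistance = 4) {
  sobelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)      # d/dx (cols)
  ix <- correlate3x3(img, sobelX) / 8
  iy <- correlate3x3(img, t(sobelX)) / 8
  box <- rep(1 / 3, 3)
  sxx <- correlateSep(ix * ix, box)
  syy <- correlateSep(iy * iy, box)
  sxy <- correlateSep(ix * iy, box)
  tr <- sxx + syy
  dd <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  lmin <- (tr - dd) / 2
  mx <- max(lmin)
  if (mx <= 0) return(matrix(0, 0, 2))
  # 3x3 non-maximum suppression
  p <- padReplicate(lmin, 1, 1)
  h <- nrow(lmin); w <- ncol(lmin)
  isMax <- lmin >= mx * quality
  for (i in 1:3) for (j in 1:3)
    if (!(i == 2 && j == 2))
      isMax <- isMax & (lmin >= p[i:(i + h - 1), j:(j + w - 1)])
  cand <- which(isMax, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(0, 0, 2))
  ord <- order(lmin[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(0, 0, 2)
  for (i in seq_len(nrow(cand))) {
    pnt <- cand[i, ]
    if (nrow(keep) == 0 ||
        min((keep[, 1] - pnt[1])^2 + (keep[, 2] - pnt[2])^2) >=
          minDistance^2)
      keep <- rbind(keep, pnt)
    if (nrow(keep) >= maxCorners) break
  }
  dimnames(keep) <- NULL
  keep
}

# --- pyramidal Lucas-Kanade tracking --------------------------------------

# Refine the displacement of a set of points between two frames with
# iterative Lucas-Kanade on an image pyramid. points: n x 2 (row, col).
# Returns list(points = n x 2 updated, status = logical n).
lkStep <- function(frameA, frameB, points, winRadius = 7, levels = 2,
                   maxIter = 10, eps = 0.01) {
  n <- nrow(points)
  if (n == 0) return(list(points = points, status = logical(0)))
  pyrA <- list(frameA); pyrB <- list(frameB)
  lv <- 1
  while (lv < levels && min(dim(pyrA[[lv]])) >= 4 * winRadius) {
    pyrA[[lv + 1]] <- downsampleHalf(pyrA[[lv]])
    pyrB[[lv + 1]] <- downsampleHalf(pyrB[[lv]])
    lv <- lv + 1
  }
  off <- as.matrix(expand.grid(dr = -winRadius:winRadius,
                               dc = -winRadius:winRadius))
  v <- matrix(0, n, 2)   # (dy, dx) accumulated at finest scale
  status <- rep(TRUE, n)
  for (level in rev(seq_len(lv))) {
    sc <- 2^(level - 1)
    A <- pyrA[[level]]; B <- pyrB[[level]]
    gxK <- c(-0.5, 0, 0.5)
    Ax <- correlateRows(A, gxK); Ay <- correlateCols(A, gxK)
    for (i in seq_len(n)) {
      if (!status[i]) next
      p <- points[i, ] / sc
      pv <- v[i, ] / sc
      # windows are sampled with replicate borders, so near-border points
      # keep tracking; the track only fails on a degenerate gradient matrix
      # or when the tracked point itself leaves the frame.
      rw <- p[1] + off[, 1]; cw <- p[2] + off[, 2]
      rwM <- matrix(rw, ncol = 1); cwM <- matrix(cw, ncol = 1)
      tI <- bilinearSample(A, rwM, cwM)
      gx <- bilinearSample(Ax, rwM, cwM)
      gy <- bilinearSample(Ay, rwM, cwM)
      g11 <- sum(gx * gx); g12 <- sum(gx * gy); g22 <- sum(gy * gy)
      det <- g11 * g22 - g12^2
      if (det < 1e-6) { status[i] <- FALSE; next }
      for (it in seq_len(maxIter)) {
        tJ <- bilinearSample(B, matrix(rw + pv[1], ncol = 1),
                             matrix(cw + pv[2], ncol = 1))
        e <- tI - tJ
        b1 <- sum(gx * e); b2 <- sum(gy * e)
        ddx <- (g22 * b1 - g12 * b2) / det
        ddy <- (g11 * b2 - g12 * b1) / det
        pv <- pv + c(ddy, ddx)
        if (sqrt(ddx^2 + ddy^2) < eps) break
      }
      v[i, ] <- pv * sc
    }
    # v carries down to the next (finer) level already at finest-scale units
  }
  newPts <- points + v
  inb <- newPts[, 1] >= 1 & newPts[, 1] <= nrow(frameA) &
         newPts[, 2] >= 1 & newPts[, 2] <= ncol(frameA)
  status <- status & inb
  list(points = newPts, status = status)
}

#' Track corner points across a frame sequence
#'
#' Detects corners on the first frame and follows each with pyramidal
#' Lucas-Kanade through every subsequent frame. Tracks whose solve fails or
#' that leave the frame are dropped (no mid-sequence re-seeding).
#'
#' @param seq a \code{\link{frameSequence}} of greyscale frames.
#' @param cfg a \code{\link{sparseFlowConfig}}.
#' @return List of tracks; each track is an m x 2 matrix of (row, col)
#'   positions, one row per frame survived (m <= length(seq)).
#' @export
trackSparse <- function(seq, cfg = sparseFlowConfig()) {
  stopifnot(is(seq, "FrameSequence"), is(cfg, "SparseFlowConfig"))
  fr <- lapply(seq@frames, toGreyscale)
  pts <- goodFeaturesToTrack(fr[[1]], cfg@maxCorners, cfg@cornerQuality,
                             cfg@minCornerDistance)
  if (nrow(pts) == 0) {
    warning("no corners found on the first frame; returning no tracks")
    return(list())
  }
  winRadius <- max(2, floor(cfg@lkWindow / 2))
  nT <- min(length(fr), cfg@seqLen)
  tracks <- lapply(seq_len(nrow(pts)), function(i) pts[i, , drop = FALSE])
  alive <- rep(TRUE, nrow(pts))
  cur <- pts
  for (t in seq_len(nT - 1)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    st <- lkStep(fr[[t]], fr[[t + 1]], cur[idx, , drop = FALSE],
                 winRadius = winRadius)
    cur[idx, ] <- st$points
    alive[idx[!st$status]] <- FALSE
    for (j in idx[st$status])
      tracks[[j]] <- rbind(tracks[[j]], cur[j, ])
  }
  tracks[vapply(tracks, nrow, integer(1)) == nT]
}

# Fixed palette for rendered trajectories: distinct, bright, deterministic.
trackPalette <- function() {
  rbind(c(255, 64, 64), c(64, 255, 64), c(64, 128, 255), c(255, 255, 64),
        c(255, 64, 255), c(64, 255, 255), c(255, 160, 32), c(160, 64, 255),
        c(128, 255, 128), c(255, 128, 160), c(96, 192, 255), c(200, 200, 200))
}

# Draw a 1-px-wide segment into an RGB canvas by dense sampling.
drawSegment <- function(canvas, p0, p1, colour) {
  len <- sqrt(sum((p1 - p0)^2))
  nStep <- max(2, ceiling(len * 2) + 1)
  ts <- seq(0, 1, length.out = nStep)
  rr <- round(p0[1] + ts * (p1[1] - p0[1]))
  cc <- round(p0[2] + ts * (p1[2] - p0[2]))
  ok <- rr >= 1 & rr <= dim(canvas)[1] & cc >= 1 & cc <= dim(canvas)[2]
  for (ch in 1:3)
    canvas[cbind(rr[ok], cc[ok], ch)] <- colour[ch]
  canvas
}

#' Sparse optical-flow trajectory image
#'
#' The sparse-flow representation: corners detected on the first frame of a
#' window are tracked across it, and each surviving trajectory is rendered
#' as a 1-px polyline in its own palette colour on a black canvas of the
#' frame size.
#'
#' @param seq a \code{\link{frameSequence}} window (typically 30 frames).
#' @param cfg a \code{\link{sparseFlowConfig}}.
#' @return H x W x 3 RGB array in \[0, 255\].
#' @export
sparseFlowImage <- function(seq, cfg = sparseFlowConfig()) {
  d <- dim(seq@frames[[1]])[1:2]
  canvas <- array(0, c(d[1], d[2], 3))
  tracks <- trackSparse(seq, cfg)
  pal <- trackPalette()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    colour <- pal[(k - 1) %% nrow(pal) + 1, ]
    if (nrow(tr) == 1) {
      p <- round(tr[1, ])
      if (all(p >= 1) && p[1] <= d[1] && p[2] <= d[2])
        for (ch in 1:3) canvas[p[1], p[2], ch] <- colour[ch]
    } else {
      for (s in seq_len(nrow(tr) - 1))
        canvas <- drawSegment(canvas, tr[s, ], tr[s + 1, ], colour)
    }
  }
  canvas
}
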