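# Minimal CNN training stack used by the deep regressors: conv2d (im2col +
# BLAS gemm, C++ gather/scatter), batch normalisation, ReLU, global average
# pooling and dense layers, with reverse-mode gradients and a Nadam
# optimiser. Activation tensors are (H, W, C, N) arrays; pooled features
# and dense activations are (features x batch) matrices.

newLayer <- function(type, par = list(), extra = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$par <- par
  l$grad <- lapply(par, function(p) p * 0)
  l$m <- lapply(par, function(p) p * 0)
  l$v <- lapply(par, function(p) p * 0)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  l
}

heInit <- function(nrow, ncol, fanIn) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fanIn)), nrow, ncol)
}

newConv <- function(cin, cout, k = 3, stride = 1, pad = (k - 1) %/% 2) {
  fanIn <- cin * k * k
  newLayer("conv",
           par = list(W = heInit(fanIn, cout, fanIn), b = rep(0, cout)),
           extra = list(cin = cin, cout = cout, k = k, stride = stride,
                        pad = pad))
}

newBatchNorm <- function(c, momentum = 0.9, eps = 1e-5) {
  newLayer("bn",
           par = list(gamma = rep(1, c), beta = rep(0, c)),
           extra = list(c = c, momentum = momentum, eps = eps,
                        runMean = rep(0, c), runVar = rep(1, c)))
}

newReLU <- function() newLayer("relu")
newGAP <- function() newLayer("gap")
newDropout <- function(p = 0.2) newLayer("dropout", extra = list(p = p))

newDense <- function(nin, nout) {
  newLayer("dense",
           par = list(W = heInit(nin, nout, nin), b = rep(0, nout)),
           extra = list(nin = nin, nout = nout))
}

# residual wrapper: y = main(x) + (proj(x) or x)
newResidual <- function(main, proj = NULL)
  newLayer("res", extra = list(main = main, proj = proj))

# --- forward --------------------------------------------------------------

forwardLayer <- function(l, x, train) {
  switch(l$type,
    conv = {
      d <- dim(x)
      cols <- nn_im2col(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
      ho <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1
      wo <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1
      out <- crossprod(l$par$W, cols) + l$par$b
      if (train) { l$cols <- cols; l$inDim <- d; l$outHW <- c(ho, wo) }
      aperm(array(out, c(l$cout, ho, wo, d[4])), c(2, 3, 1, 4))
    },
    bn = {
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
      if (train) {
        mu <- colMeans(xm)
        xc <- sweep(xm, 2, mu)
        va <- colMeans(xc^2)
        l$runMean <- l$momentum * l$runMean + (1 - l$momentum) * mu
        l$runVar <- l$momentum * l$runVar + (1 - l$momentum) * va
      } else {
        mu <- l$runMean; va <- l$runVar
        xc <- sweep(xm, 2, mu)
      }
      istd <- 1 / sqrt(va + l$eps)
      xhat <- sweep(xc, 2, istd, "*")
      ym <- sweep(sweep(xhat, 2, l$par$gamma, "*"), 2, l$par$beta, "+")
      if (train) { l$xhat <- xhat; l$istd <- istd; l$inDim <- d }
      aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    relu = {
      if (train) l$mask <- x > 0
      x * (x > 0)
    },
    dropout = {
      if (!train) return(x)
      l$mask <- (matrix(runif(length(x)), nrow(x)) >= l$p) / (1 - l$p)
      x * l$mask
    },
    gap = {
      d <- dim(x)
      if (train) l$inDim <- d
      matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    },
    dense = {
      if (train) l$x <- x
      crossprod(l$par$W, x) + l$par$b
    },
    res = {
      main <- forwardSeq(l$main, x, train)
      skip <- if (is.null(l$proj)) x else forwardSeq(l$proj, x, train)
      main + skip
    },
    stop("unknown layer type ", l$type))
}

forwardSeq <- function(layers, x, train) {
  for (l in layers) x <- forwardLayer(l, x, train)
  x
}

# --- backward -------------------------------------------------------------

backwardLayer <- function(l, dout) {
  switch(l$type,
    conv = {
      d <- l$inDim; hw <- l$outHW
      dm <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = l$cout)
      l$grad$W <- l$cols %*% t(dm)
      l$grad$b <- rowSums(dm)
      dcols <- l$par$W %*% dm
      l$cols <- NULL
      nn_col2im(dcols, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    },
    bn = {
      d <- l$inDim
      dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
      m <- nrow(dm)
      l$grad$gamma <- colSums(dm * l$xhat)
      l$grad$beta <- colSums(dm)
      dxhat <- sweep(dm, 2, l$par$gamma, "*")
      # dx = istd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
      t1 <- m * dxhat
      t2 <- matrix(colSums(dxhat), m, d[3], byrow = TRUE)
      t3 <- l$xhat * matrix(colSums(dxhat * l$xhat), m, d[3], byrow = TRUE)
      dxm <- sweep(t1 - t2 - t3, 2, l$istd / m, "*")
      l$xhat <- NULL
      aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    relu = dout * l$mask,
    dropout = dout * l$mask,
    gap = {
      d <- l$inDim
      scale <- 1 / (d[1] * d[2])
      array(rep(as.vector(dout) * scale, each = d[1] * d[2]), d)
    },
    dense = {
      l$grad$W <- l$x %*% t(dout)
      l$grad$b <- rowSums(dout)
      dx <- l$par$W %*% dout
      l$x <- NULL
      dx
    },
    res = {
      dmain <- backwardSeq(l$main, dout)
      dskip <- if (is.null(l$proj)) dout else backwardSeq(l$proj, dout)
      dmain + dskip
    },
    stop("unknown layer type ", l$type))
}

backwardSeq <- function(layers, dout) {
  for (l in rev(layers)) dout <- backwardLayer(l, dout)
  dout
}

# --- parameter handling ---------------------------------------------------

collectLayers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "res") {
      out <- c(out, collectLayers(l$main))
      if (!is.null(l$proj)) out <- c(out, collectLayers(l$proj))
    } else if (length(l$par)) out <- c(out, list(l))
  }
  out
}

# Nadam update (Adam with Nesterov momentum). Parameters and moments are
# mutated in place in C++; they are privately owned by the layer
# environments (snapshot/restore always deep-copy).
nadamStep <- function(paramLayers, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in paramLayers) {
    for (nm in names(l$par))
      nn_nadam_update(l$par[[nm]], l$m[[nm]], l$v[[nm]], l$grad[[nm]],
                      lr, beta1, beta2, bc1, bc2, eps)
  }
}

deepCopy <- function(x) lapply(x, function(a) a + 0)

snapshotParams <- function(paramLayers)
  lapply(paramLayers, function(l) list(
    par = deepCopy(l$par),
    runMean = if (l$type == "bn") l$runMean + 0,
    runVar = if (l$type == "bn") l$runVar + 0))

restoreParams <- function(paramLayers, snap) {
  for (i in seq_along(paramLayers)) {
    paramLayers[[i]]$par <- deepCopy(snap[[i]]$par)
    if (!is.null(snap[[i]]$runMean)) {
      paramLayers[[i]]$runMean <- snap[[i]]$runMean + 0
      paramLayers[[i]]$runVar <- snap[[i]]$runVar + 0
    }
  }
}

# --- early stopping -------------------------------------------------------

# Early-stopping bookkeeping: strict improvement resets the counter; once
# `patience` epochs pass without improvement training stops and the best
# epoch's weights are kept.
earlyStopInit <- function(patience)
  list(patience = patience, best = Inf, bestEpoch = 0L, since = 0L,
       epoch = 0L, stop = FALSE)

earlyStopUpdate <- function(state, valMse) {
  state$epoch <- state$epoch + 1L
  if (valMse < state$best) {
    state$best <- valMse
    state$bestEpoch <- state$epoch
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
    if (state$since >= state$patience) state$stop <- TRUE
  }
  state
}
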