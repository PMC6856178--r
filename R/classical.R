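# Classical baseline: the ZeroR null model, early fusion of feature blocks,
# and per-variable scalar regressors from standard libraries behind one
# registry. Each motility variable gets its own independently fitted
# regressor (the toolkit algorithms predict one value at a time);
# predictions are clipped to [0, 100] and not renormalised.

labelColumns <- c("progressive", "non_progressive", "immotile")

#' ZeroR null model
#'
#' Predicts the arithmetic mean of the training labels for every input,
#' per motility variable. This is the significance baseline: its
#' cross-validation coefficient Q^2 is 0 by definition.
#'
#' @param trainLabels data.frame with columns progressive, non_progressive,
#'   immotile (one row per training video).
#' @return An object of class \code{"ZeroRModel"}.
#' @export
zerorFit <- function(trainLabels) {
  if (nrow(trainLabels) == 0) stop("empty training set")
  m <- vapply(labelColumns, function(cn) mean(trainLabels[[cn]]), numeric(1))
  structure(list(meanLabel = m), class = "ZeroRModel")
}

#' @rdname zerorFit
#' @param model a fitted ZeroR model.
#' @param n number of rows to predict (the prediction is constant).
#' @return data.frame of n identical predicted label rows.
#' @export
zerorPredict <- function(model, n = 1) {
  stopifnot(inherits(model, "ZeroRModel"))
  out <- as.data.frame(matrix(rep(model$meanLabel, each = n), nrow = n))
  names(out) <- labelColumns
  out
}

#' Early fusion of per-video feature blocks
#'
#' Concatenates feature blocks (e.g. the 2160-dim Tamura block and the
#' 3-dim participant block) row-wise by video id, in the given block order.
#'
#' @param blocks named list of data.frames, each with an \code{id} column
#'   and numeric feature columns; all blocks must cover the same id set.
#' @return data.frame with \code{id} plus the concatenated features, rows
#'   ordered as the first block.
#' @export
earlyFuse <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  ids <- blocks[[1]]$id
  for (b in blocks[-1]) {
    missing <- setdiff(ids, b$id)
    extra <- setdiff(b$id, ids)
    if (length(missing) || length(extra))
      stop("feature blocks disagree on video ids; missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    b <- b[match(ids, b$id), setdiff(names(b), "id"), drop = FALSE]
    names(b) <- paste0(nm, "_", names(b))
    out <- cbind(out, b)
  }
  rownames(out) <- NULL
  out
}

classicalRegistry <- function()
  c("linear", "random_forest", "gaussian_process", "svr_smo_like",
    "elastic_net", "random_tree")

# Minimum-norm least squares via SVD; works for p > n.
svdLinearFit <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  coefs <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
  coefs
}

fitOne <- function(algorithmId, X, y, seed) {
  set.seed(seed)
  switch(algorithmId,
    linear = {
      Xi <- cbind(1, X)
      list(coef = svdLinearFit(Xi, y),
           predict = function(m, Xn) as.vector(cbind(1, Xn) %*% m$coef))
    },
    random_forest = {
      fit <- randomForest::randomForest(x = X, y = y, ntree = 100)
      list(fit = fit, predict = function(m, Xn) as.vector(predict(m$fit, Xn)))
    },
    gaussian_process = {
      fit <- kernlab::gausspr(x = X, y = y, variance.model = FALSE)
      list(fit = fit,
           predict = function(m, Xn) as.vector(kernlab::predict(m$fit, Xn)))
    },
    svr_smo_like = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "radial")
      list(fit = fit, predict = function(m, Xn) as.vector(predict(m$fit, Xn)))
    },
    elastic_net = {
      fit <- glmnet::glmnet(X, y, alpha = 0.5)
      lam <- min(fit$lambda)
      list(fit = fit, lambda = lam,
           predict = function(m, Xn)
             as.vector(predict(m$fit, Xn, s = m$lambda)))
    },
    random_tree = {
      df <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = df,
                          control = rpart::rpart.control(cp = 0.001))
      list(fit = fit,
           predict = function(m, Xn)
             as.vector(predict(m$fit, data.frame(Xn))))
    },
    stop(sprintf("unknown algorithm '%s'; registry: %s", algorithmId,
                 paste(classicalRegistry(), collapse = ", "))))
}

# algorithms whose inputs are standardised on the training fold
needsScaling <- c("linear", "gaussian_process", "svr_smo_like", "elastic_net")

#' Fit a classical per-variable regressor bundle
#'
#' Fits one scalar regressor per motility variable over a feature table.
#' For scale-sensitive algorithms the features are standardised with
#' training-fold mean and standard deviation; the same transform is applied
#' at prediction time. The random seed is fixed and recorded on the bundle.
#'
#' @param table feature data.frame with an \code{id} column (see
#'   \code{\link{earlyFuse}}).
#' @param labels data.frame with id, progressive, non_progressive, immotile.
#' @param algorithmId one of \code{classicalRegistry()}.
#' @param seed integer seed.
#' @return An object of class \code{"ClassicalBundle"}.
#' @export
fitClassical <- function(table, labels, algorithmId, seed = 1) {
  if (!algorithmId %in% classicalRegistry())
    stop(sprintf("unknown algorithm '%s'; registry: %s", algorithmId,
                 paste(classicalRegistry(), collapse = ", ")))
  stopifnot(all(table$id %in% labels$id))
  lab <- labels[match(table$id, labels$id), ]
  X <- as.matrix(table[, setdiff(names(table), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("feature table contains non-finite values")
  scal <- NULL
  if (algorithmId %in% needsScaling) {
    mu <- colMeans(X); sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1
    scal <- list(mu = mu, sd = sdv)
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }
  models <- lapply(seq_along(labelColumns), function(j) {
    y <- lab[[labelColumns[j]]]
    # constant targets break library fits that standardise y internally
    if (var(y) == 0)
      list(mu = y[1], predict = function(m, Xn) rep(m$mu, nrow(Xn)))
    else fitOne(algorithmId, X, y, seed + j)
  })
  structure(list(models = models, algorithmId = algorithmId,
                 scaling = scal, seed = seed,
                 featureNames = colnames(X)),
            class = "ClassicalBundle")
}

#' @rdname fitClassical
#' @param bundle a fitted \code{"ClassicalBundle"}.
#' @return \code{predictClassical}: data.frame with id and the three
#'   predicted motility percentages, clipped to \[0, 100\].
#' @export
predictClassical <- function(bundle, table) {
  stopifnot(inherits(bundle, "ClassicalBundle"))
  X <- as.matrix(table[, setdiff(names(table), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  if (!is.null(bundle$scaling))
    X <- sweep(sweep(X, 2, bundle$scaling$mu), 2, bundle$scaling$sd, "/")
  pred <- vapply(seq_along(labelColumns), function(j) {
    m <- bundle$models[[j]]
    clipRange(m$predict(m, X), 0, 100)
  }, numeric(nrow(X)))
  pred <- matrix(pred, nrow = nrow(X))
  out <- data.frame(id = table$id, pred, stringsAsFactors = FALSE)
  names(out) <- c("id", labelColumns)
  out
}
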