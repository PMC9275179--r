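## Supervised stage: dense multilayer perceptrons with ReLU hidden layers
## and softmax outputs, trained with mini-batch Adam on cross-entropy.
## Unselected CpG features are zeroed at the input, so model outputs are a
## function of the selected features only.

#' Adam optimiser state
#'
#' First/second moment moving averages
#' `m_t = beta1 * m_{t-1} + (1 - beta1) * g_t` and
#' `v_t = beta2 * v_{t-1} + (1 - beta2) * g_t^2`, with the defaults of the
#' method's original authors (0.9, 0.999, 1e-08).
#'
#' @param shapes List of parameter arrays (or their dims) to track.
#' @param learningRate Step size.
#' @param beta1,beta2 Exponential decay of the first/second moments.
#' @param epsilon Small constant preventing division by zero.
#' @return An `AdamState` list.
#' @export
adamInit <- function(shapes, learningRate = 0.001, beta1 = 0.9,
                     beta2 = 0.999, epsilon = 1e-08) {
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)")
  if (epsilon <= 0) stop("epsilon must be positive")
  zero <- lapply(shapes, function(p) array(0, dim = dim(as.array(p))))
  structure(list(m = zero, v = zero, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, stepCount = 0L,
                 learningRate = learningRate),
            class = "AdamState")
}

#' One Adam update
#'
#' Updates the moment estimates per their exponential-decay recursions and
#' applies the bias-corrected step
#' `param - lr * mhat / (sqrt(vhat) + epsilon)` with
#' `mhat = m / (1 - beta1^t)`, `vhat = v / (1 - beta2^t)`.
#'
#' @param state An [adamInit()] state.
#' @param params List of parameter arrays.
#' @param grads List of gradient arrays of matching shapes.
#' @return List with updated `state` and `params`.
#' @export
adamStep <- function(state, params, grads) {
  if (length(params) != length(grads))
    stop("params and grads must have the same length")
  t <- state$stepCount + 1L
  lr <- state$learningRate
  for (i in seq_along(params)) {
    if (!identical(dim(as.array(params[[i]])), dim(as.array(grads[[i]]))))
      stop("shape mismatch between parameter and gradient ", i)
    g <- grads[[i]]
    state$m[[i]] <- state$beta1 * state$m[[i]] + (1 - state$beta1) * g
    state$v[[i]] <- state$beta2 * state$v[[i]] + (1 - state$beta2) * g * g
    mhat <- state$m[[i]] / (1 - state$beta1^t)
    vhat <- state$v[[i]] / (1 - state$beta2^t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + state$epsilon)
  }
  state$stepCount <- t
  list(state = state, params = params)
}

#' Zero the unselected features of an input
#'
#' Implements "unselected features get zero weight" as input masking:
#' positions outside the mask are set to 0, selected positions pass
#' through, so the network output depends on selected features only.
#'
#' @param x Numeric vector or samples-by-features matrix.
#' @param mask A [FeatureMask-class] (or logical vector) of matching width.
#' @return The masked input of the same shape.
#' @export
maskInput <- function(x, mask) {
  bits <- if (is(mask, "FeatureMask")) mask@bits else as.logical(mask)
  if (is.matrix(x)) {
    if (ncol(x) != length(bits)) stop("input width does not match the mask")
    x[, !bits] <- 0
  } else {
    if (length(x) != length(bits)) stop("input width does not match the mask")
    x[!bits] <- 0
  }
  x
}

#' MLP architecture specification
#'
#' @param inputWidth Number of input features (the platform locus count).
#' @param hiddenLayers Integer widths of the dense ReLU hidden layers.
#' @param classes Character output class labels (binary malignancy:
#'   malignant/benign; pan-classification: cancer types plus normal).
#' @param learningRate Adam step size.
#' @param featureMask Optional [FeatureMask-class] applied to every input.
#' @return An `MlpSpec` list.
#' @export
mlpSpec <- function(inputWidth, hiddenLayers = 64L, classes,
                    learningRate = 0.001, featureMask = NULL) {
  if (any(hiddenLayers < 1L)) stop("hidden widths must be positive")
  structure(list(inputWidth = as.integer(inputWidth),
                 hiddenLayers = as.integer(hiddenLayers),
                 classes = as.character(classes),
                 learningRate = learningRate, featureMask = featureMask),
            class = "MlpSpec")
}

relu <- function(z) pmax(z, 0)

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlpForward <- function(W, b, X) {
  A <- list(X)
  L <- length(W)
  for (l in seq_len(L - 1L)) {
    A[[l + 1L]] <- relu(A[[l]] %*% W[[l]] +
                        matrix(b[[l]], nrow(X), length(b[[l]]), byrow = TRUE))
  }
  Z <- A[[L]] %*% W[[L]] + matrix(b[[L]], nrow(X), length(b[[L]]), byrow = TRUE)
  list(A = A, P = softmaxRows(Z))
}

crossEntropy <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

#' Train a multilayer perceptron
#'
#' Dense ReLU layers, softmax output, cross-entropy loss, mini-batch Adam
#' with bias correction. When an evaluation split is supplied, training
#' stops early once the evaluation loss has not improved for `patience`
#' epochs and the best-so-far parameters are kept. Deterministic per seed.
#'
#' @param x Samples-by-features numeric matrix (no missing values).
#' @param y Factor or character vector of per-sample class labels; every
#'   class in `spec$classes` must have at least 2 training samples.
#' @param spec An [mlpSpec()].
#' @param epochs Maximum training epochs (default 100).
#' @param batch Mini-batch size (default 32).
#' @param seed Integer seed for weight initialisation and shuffling.
#' @param evalX,evalY Optional evaluation split for early stopping.
#' @param patience Early-stopping patience in epochs.
#' @return An `MlpModel` (weights, spec, classes, per-epoch history).
#' @export
trainMlp <- function(x, y, spec, epochs = 100L, batch = 32L, seed = 1L,
                     evalX = NULL, evalY = NULL, patience = 10L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("training data must be fully observed")
  if (ncol(x) != spec$inputWidth)
    stop("input width (", ncol(x), ") does not match the spec (",
         spec$inputWidth, ")")
  y <- factor(as.character(y), levels = spec$classes)
  if (anyNA(y)) stop("labels outside the spec's classes")
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("stratification error: class(es) with fewer than 2 training samples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  if (!is.null(spec$featureMask)) {
    x <- maskInput(x, spec$featureMask)
    if (!is.null(evalX)) evalX <- maskInput(as.matrix(evalX), spec$featureMask)
  }
  K <- length(spec$classes)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  if (!is.null(evalX)) {
    evalY <- factor(as.character(evalY), levels = spec$classes)
    YE <- diag(K)[as.integer(evalY), , drop = FALSE]
  }

  widths <- c(spec$inputWidth, spec$hiddenLayers, K)
  withSeed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1L],
                                    sd = sqrt(2 / widths[l])),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    params <- c(W, b)
    state <- adamInit(params, learningRate = spec$learningRate)
    nW <- length(W)
    n <- nrow(x)
    hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                       eval_loss = NA_real_)
    bestLoss <- Inf; bestParams <- params; bad <- 0L
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq.int(1L, n, by = batch)
      for (s in starts) {
        rows <- idx[s:min(s + batch - 1L, n)]
        Xb <- x[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        W <- params[seq_len(nW)]; bb <- params[nW + seq_len(nW)]
        fw <- mlpForward(W, bb, Xb)
        m <- nrow(Xb)
        dZ <- (fw$P - Yb) / m
        gW <- vector("list", nW); gB <- vector("list", nW)
        for (l in rev(seq_len(nW))) {
          gW[[l]] <- crossprod(fw$A[[l]], dZ)
          gB[[l]] <- colSums(dZ)
          if (l > 1L) {
            dA <- dZ %*% t(W[[l]])
            dZ <- dA * (fw$A[[l]] > 0)
          }
        }
        upd <- adamStep(state, params, c(gW, gB))
        state <- upd$state; params <- upd$params
      }
      W <- params[seq_len(nW)]; bb <- params[nW + seq_len(nW)]
      hist$train_loss[ep] <- crossEntropy(mlpForward(W, bb, x)$P, Y)
      if (!is.null(evalX)) {
        el <- crossEntropy(mlpForward(W, bb, evalX)$P, YE)
        hist$eval_loss[ep] <- el
        if (el < bestLoss - 1e-9) {
          bestLoss <- el; bestParams <- params; bad <- 0L
        } else bad <- bad + 1L
        if (bad >= patience) { hist <- hist[seq_len(ep), ]; break }
      }
    }
    if (!is.null(evalX)) params <- bestParams
    structure(list(spec = spec, classes = spec$classes,
                   W = params[seq_len(nW)], b = params[nW + seq_len(nW)],
                   history = hist),
              class = "MlpModel")
  })
}

#' Predict class scores and labels
#'
#' Per-sample softmax scores (summing to 1 across classes) and arg-max
#' labels; score ties resolve to the lexicographically first class.
#'
#' @param object A fitted `MlpModel`.
#' @param x Samples-by-features matrix of the model's input width.
#' @param ... Unused.
#' @return List with `scores` (matrix, one column per class) and `labels`
#'   (character vector).
#' @export
predict.MlpModel <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$spec$inputWidth)
    stop("input width does not match the model")
  if (!is.null(object$spec$featureMask))
    x <- maskInput(x, object$spec$featureMask)
  P <- mlpForward(object$W, object$b, x)$P
  colnames(P) <- object$classes
  labels <- vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    top <- object$classes[p >= max(p) - 1e-12]
    sort(top)[1L]
  }, character(1))
  list(scores = P, labels = labels)
}

#' @export
print.MlpModel <- function(x, ...) {
  cat("MlpModel:", x$spec$inputWidth, "->",
      paste(x$spec$hiddenLayers, collapse = " -> "), "->",
      length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), ")\n")
  invisible(x)
}

nParamsMlp <- function(spec, nClasses) {
  widths <- c(spec$inputWidth, spec$hiddenLayers, nClasses)
  sum(widths[-length(widths)] * widths[-1L] + widths[-1L])
}

#' Hyperparameter grid search
#'
#' Exhaustively evaluates the Cartesian grid of learning rates, base
#' hidden-layer sizes and hidden-layer counts (the published grid is
#' 3 rates x 4 sizes x 3 counts = 36 candidates). For layer count `L` and
#' base size `s` the widths halve: `s, s/2, ..., matching the reported
#' two-layer optimum (256, 128). Each candidate is trained on the training
#' split and scored by accuracy on the evaluation split; ties break toward
#' fewer parameters, then lower learning rate.
#'
#' @param x,y Training split.
#' @param evalX,evalY Evaluation split.
#' @param classes Output class labels.
#' @param learningRates,hiddenSizes,layerCounts Grid axes.
#' @param featureMask Optional input [FeatureMask-class].
#' @param epochs,batch,patience Passed to [trainMlp()].
#' @param seed Integer seed (shared by every candidate).
#' @return List with `spec` (the winning [mlpSpec()]) and `results`
#'   (data.frame of every candidate with its evaluation accuracy).
#' @export
gridSearch <- function(x, y, evalX, evalY, classes,
                       learningRates = c(0.1, 0.01, 0.001),
                       hiddenSizes = c(512L, 256L, 128L, 64L),
                       layerCounts = c(1L, 2L, 4L),
                       featureMask = NULL, epochs = 50L, batch = 32L,
                       patience = 10L, seed = 1L) {
  if (!length(learningRates) || !length(hiddenSizes) || !length(layerCounts))
    stop("empty hyperparameter grid")
  grid <- expand.grid(lr = learningRates, size = hiddenSizes,
                      layers = layerCounts, KEEP.OUT.ATTRS = FALSE)
  res <- grid
  res$accuracy <- NA_real_
  res$n_params <- NA_integer_
  specs <- vector("list", nrow(grid))
  evalYc <- as.character(evalY)
  for (i in seq_len(nrow(grid))) {
    widths <- pmax(1L, as.integer(grid$size[i] / 2^(seq_len(grid$layers[i]) - 1L)))
    sp <- mlpSpec(ncol(x), widths, classes, grid$lr[i], featureMask)
    fit <- trainMlp(x, y, sp, epochs = epochs, batch = batch, seed = seed,
                    evalX = evalX, evalY = evalY, patience = patience)
    pred <- predict(fit, evalX)
    res$accuracy[i] <- mean(pred$labels == evalYc)
    res$n_params[i] <- nParamsMlp(sp, length(classes))
    specs[[i]] <- sp
  }
  ord <- order(-res$accuracy, res$n_params, res$lr)
  list(spec = specs[[ord[1L]]], results = res)
}

#' Stratified train/test split
#'
#' Splits sample indices class-by-class so the train and test sets are
#' disjoint and exhaustive, with the configured train fraction (default
#' 70/30) applied within every class.
#'
#' @param y Per-sample class labels.
#' @param fraction Train fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List of integer index vectors `train` and `test`.
#' @export
trainTestSplit <- function(y, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  y <- as.character(y)
  withSeed(seed, {
    train <- integer()
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nTrain <- max(1L, round(length(idx) * fraction))
      train <- c(train, sample(idx, min(nTrain, length(idx))))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}
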