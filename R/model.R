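## Fully connected classifier: [dense -> batch norm -> ELU -> dropout] per
## hidden layer, then dense(1) -> sigmoid, trained with Adam on binary
## cross-entropy over class-balanced minibatches. Implemented directly with
## vectorised matrix algebra; batch normalization uses epsilon 1e-3 and
## moving-average momentum 0.99, weights are Glorot-uniform initialized,
## and Adam uses beta1 0.9, beta2 0.999, epsilon 1e-7.

BCE_CLIP <- 1e-7
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-7

#' Classifier configuration constructor
#'
#' Defaults follow the repertoire-scale setup: 882 input features, hidden
#' layers of 6, 3 and 2 units, dropout 0.5, ELU alpha 1, Adam learning rate
#' 6e-7, batch size 128 (64 clones per class), 10 epochs. The default
#' learning rate was tuned for training sets of millions of observations;
#' desk-scale experiments raise it through this constructor.
#'
#' @param inputDim,hiddenUnits,dropoutRate,eluAlpha,learningRate,batchSize,epochs,seed,bnEps,bnMomentum
#'   see [ModelConfig-class]
#' @return a [ModelConfig-class]
#' @export
modelConfig <- function(inputDim = 882L, hiddenUnits = c(6L, 3L, 2L),
                        dropoutRate = 0.5, eluAlpha = 1,
                        learningRate = 6e-7, batchSize = 128L,
                        epochs = 10L, seed = 1L,
                        bnEps = 1e-3, bnMomentum = 0.99) {
  new("ModelConfig", inputDim = as.integer(inputDim),
      hiddenUnits = as.integer(hiddenUnits),
      dropoutRate = as.numeric(dropoutRate), eluAlpha = as.numeric(eluAlpha),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), bnEps = as.numeric(bnEps),
      bnMomentum = as.numeric(bnMomentum))
}

.glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

#' Build an untrained classifier
#'
#' Initializes all layer parameters (Glorot-uniform weights, zero biases,
#' unit batch-norm scale, zero running means, unit running variances) under
#' the config seed.
#'
#' @param config a [ModelConfig-class]
#' @return an untrained [PolyspecModel-class]
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  dims <- c(config@inputDim, config@hiddenUnits)
  params <- withSeed(config@seed, {
    layers <- lapply(seq_along(config@hiddenUnits), function(h) {
      u <- dims[h + 1L]
      list(W = .glorot(dims[h], u), b = numeric(u),
           gamma = rep(1, u), beta = numeric(u),
           rmean = numeric(u), rvar = rep(1, u))
    })
    list(layers = layers,
         Wout = .glorot(dims[length(dims)], 1L), bout = 0)
  })
  new("PolyspecModel", params = params, config = config,
      trainingLog = numeric(0L))
}

## labels -> 0/1 integer with polyspecific as the positive class
.binLabels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), LABEL_LEVELS)
    if (length(bad)) stop(sprintf("unknown label '%s'", bad[1L]))
    as.integer(labels == "polyspecific")
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' Class-balanced minibatch index stream
#'
#' Each batch holds exactly batchSize/2 indices of either class, drawn
#' uniformly with replacement within class (so a minority class smaller
#' than batchSize/2 still fills its half with repeats). Deterministic under
#' the seed.
#'
#' @param labels class labels (character/factor with polyspecific positive,
#'   or 0/1)
#' @param batchSize even batch size
#' @param steps number of batches to draw
#' @param seed integer RNG seed
#' @return list of integer index vectors of length batchSize
#' @export
balancedMinibatches <- function(labels, batchSize, steps, seed = 1L) {
  y <- .binLabels(labels)
  if (batchSize %% 2L != 0L) stop("batchSize must be even")
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (!length(pos) || !length(neg))
    stop("both classes must be present for balanced minibatch sampling")
  half <- batchSize %/% 2L
  withSeed(seed, lapply(seq_len(steps), function(s)
    c(sample(pos, half, replace = TRUE), sample(neg, half, replace = TRUE))))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce <- function(p, y) {
  p <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Forward pass in training mode; returns caches for backprop and the
## updated running statistics.
.forwardTrain <- function(params, cfg, X) {
  caches <- vector("list", length(params$layers))
  A <- X
  for (h in seq_along(params$layers)) {
    ly <- params$layers[[h]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2L, ly$b, `+`)
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2             # biased batch variance
    inv <- 1 / sqrt(va + cfg@bnEps)
    xhat <- sweep(sweep(Z, 2L, mu, `-`), 2L, inv, `*`)
    Y <- sweep(sweep(xhat, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
    E <- ifelse(Y > 0, Y, cfg@eluAlpha * (exp(Y) - 1))
    keep <- 1 - cfg@dropoutRate
    mask <- if (cfg@dropoutRate > 0)
      matrix(stats::rbinom(length(E), 1L, keep), nrow(E)) / keep
    else matrix(1, nrow(E), ncol(E))
    D <- E * mask
    ## moving averages
    params$layers[[h]]$rmean <- cfg@bnMomentum * ly$rmean + (1 - cfg@bnMomentum) * mu
    params$layers[[h]]$rvar <- cfg@bnMomentum * ly$rvar + (1 - cfg@bnMomentum) * va
    caches[[h]] <- list(A = A, Z = Z, mu = mu, inv = inv, xhat = xhat,
                        Y = Y, E = E, mask = mask)
    A <- D
  }
  z <- drop(A %*% params$Wout) + params$bout
  list(params = params, caches = caches, lastA = A, p = .sigmoid(z))
}

## Gradients of all parameters for one batch (training-mode forward state).
.backward <- function(params, cfg, fw, y) {
  B <- length(y)
  grads <- list(layers = vector("list", length(params$layers)))
  dz <- (fw$p - y) / B                      # d(loss)/d(z_out)
  grads$Wout <- crossprod(fw$lastA, dz)
  grads$bout <- sum(dz)
  dA <- matrix(dz, ncol = 1L) %*% t(params$Wout) # B x units_H
  for (h in rev(seq_along(params$layers))) {
    ly <- params$layers[[h]]
    ca <- fw$caches[[h]]
    dE <- dA * ca$mask                      # through dropout
    dY <- dE * ifelse(ca$Y > 0, 1, ca$E + cfg@eluAlpha) # through ELU
    dgamma <- colSums(dY * ca$xhat)
    dbeta <- colSums(dY)
    dxhat <- sweep(dY, 2L, ly$gamma, `*`)
    ## batch-norm backward (biased variance)
    Zc <- sweep(ca$Z, 2L, ca$mu, `-`)
    dvar <- colSums(dxhat * Zc) * (-0.5) * ca$inv^3
    dmu <- colSums(dxhat) * (-ca$inv) + dvar * colMeans(-2 * Zc)
    dZ <- sweep(dxhat, 2L, ca$inv, `*`) +
      sweep(Zc, 2L, 2 * dvar / B, `*`) +
      matrix(dmu / B, nrow(dY), ncol(dY), byrow = TRUE)
    grads$layers[[h]] <- list(W = crossprod(ca$A, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

## One Adam update over the parameter/gradient trees.
.adamStep <- function(params, grads, state, lr, t) {
  upd <- function(p, g, m, v) {
    m <- ADAM_BETA1 * m + (1 - ADAM_BETA1) * g
    v <- ADAM_BETA2 * v + (1 - ADAM_BETA2) * g^2
    mhat <- m / (1 - ADAM_BETA1^t)
    vhat <- v / (1 - ADAM_BETA2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + ADAM_EPS), m = m, v = v)
  }
  for (h in seq_along(params$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      r <- upd(params$layers[[h]][[nm]], grads$layers[[h]][[nm]],
               state$layers[[h]][[nm]]$m, state$layers[[h]][[nm]]$v)
      params$layers[[h]][[nm]] <- r$p
      state$layers[[h]][[nm]] <- r[c("m", "v")]
    }
  }
  r <- upd(params$Wout, grads$Wout, state$Wout$m, state$Wout$v)
  params$Wout <- r$p; state$Wout <- r[c("m", "v")]
  r <- upd(params$bout, grads$bout, state$bout$m, state$bout$v)
  params$bout <- r$p; state$bout <- r[c("m", "v")]
  list(params = params, state = state)
}

.adamInit <- function(params) {
  zero <- function(p) list(m = p * 0, v = p * 0)
  list(layers = lapply(params$layers, function(ly)
         lapply(ly[c("W", "b", "gamma", "beta")], zero)),
       Wout = zero(params$Wout), bout = zero(params$bout))
}

#' Train the classifier with balanced minibatches
#'
#' Runs \code{epochs x ceil(N / batchSize)} Adam updates on binary
#' cross-entropy, each minibatch drawn class-balanced with replacement.
#' The per-epoch mean training loss is recorded in the training log.
#' Deterministic given the config seed.
#'
#' @param model a [PolyspecModel-class] (from [buildModel()])
#' @param features numeric matrix, one row per clone, width inputDim
#' @param labels class labels (polyspecific = positive)
#' @return the trained [PolyspecModel-class]
#' @export
trainModel <- function(model, features, labels) {
  stopifnot(is(model, "PolyspecModel"))
  cfg <- model@config
  y <- .binLabels(labels)
  if (nrow(features) != length(y))
    stop("feature row count must equal label count")
  if (ncol(features) != cfg@inputDim)
    stop(sprintf("feature width %d does not match inputDim %d",
                 ncol(features), cfg@inputDim))
  if (cfg@epochs == 0L) return(model)
  stepsPerEpoch <- ceiling(nrow(features) / cfg@batchSize)
  batches <- balancedMinibatches(y, cfg@batchSize,
                                 cfg@epochs * stepsPerEpoch,
                                 seed = stageSeed(cfg@seed, 1L))
  params <- model@params
  state <- .adamInit(params)
  log_ <- numeric(cfg@epochs)
  withSeed(stageSeed(cfg@seed, 2L), {   # dropout masks
    t <- 0L
    for (ep in seq_len(cfg@epochs)) {
      losses <- numeric(stepsPerEpoch)
      for (st in seq_len(stepsPerEpoch)) {
        t <- t + 1L
        idx <- batches[[t]]
        fw <- .forwardTrain(params, cfg, features[idx, , drop = FALSE])
        params <- fw$params               # running stats updated
        losses[st] <- .bce(fw$p, y[idx])
        if (!is.finite(losses[st]))
          stop(sprintf("non-finite training loss at epoch %d step %d", ep, st))
        grads <- .backward(params, cfg, fw, y[idx])
        ad <- .adamStep(params, grads, state, cfg@learningRate, t)
        params <- ad$params
        state <- ad$state
      }
      log_[ep] <- mean(losses)
    }
  })
  new("PolyspecModel", params = params, config = cfg,
      trainingLog = c(model@trainingLog, log_))
}

## At inference, dense bias + batch norm fuse into one affine map per
## layer: y = z * (gamma / sqrt(rvar + eps)) + (beta + (b - rmean) *
## gamma / sqrt(rvar + eps)). Precomputing these constants makes the many
## repeated forward passes of the permutation-importance loop cheap.
.inferConsts <- function(params, cfg) {
  list(layers = lapply(params$layers, function(ly) {
    scale <- ly$gamma / sqrt(ly$rvar + cfg@bnEps)
    list(W = ly$W, scale = scale,
         shift = ly$beta + (ly$b - ly$rmean) * scale)
  }), Wout = params$Wout, bout = params$bout, alpha = cfg@eluAlpha)
}

## Inference forward pass from the first hidden layer's linear part
## (X %*% W1, bias excluded: it is folded into the affine constants).
## Running batch-norm statistics, no dropout.
.forwardFast <- function(consts, Z1lin) {
  A <- Z1lin
  for (h in seq_along(consts$layers)) {
    ly <- consts$layers[[h]]
    if (h > 1L) A <- A %*% ly$W
    A <- sweep(sweep(A, 2L, ly$scale, `*`), 2L, ly$shift, `+`)
    neg <- A < 0
    A[neg] <- consts$alpha * expm1(A[neg])
  }
  .sigmoid(drop(A %*% consts$Wout) + consts$bout)
}

#' Predict the probability of polyspecificity
#'
#' Deterministic inference: dropout inactive, batch normalization on
#' running statistics. Higher values mean more polyspecific (the positive
#' class).
#'
#' @param model a [PolyspecModel-class]
#' @param features numeric matrix of encoded sequences, width inputDim
#' @return numeric vector of probabilities in (0, 1), one per row
#' @export
predictProba <- function(model, features) {
  stopifnot(is(model, "PolyspecModel"))
  cfg <- model@config
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != cfg@inputDim)
    stop(sprintf("feature width %d does not match inputDim %d",
                 ncol(features), cfg@inputDim))
  consts <- .inferConsts(model@params, cfg)
  .forwardFast(consts, features %*% model@params$layers[[1L]]$W)
}

#' Save and load model checkpoints
#'
#' Checkpoints are a versioned JSON layout: a format version, the full
#' configuration, every layer's flat parameter arrays (weights, biases,
#' batch-norm scale/shift and running statistics) and the training log.
#' Loading reconstructs a model whose predictions match the saved one.
#'
#' @param model a [PolyspecModel-class]
#' @param path checkpoint file path (JSON)
#' @return \code{readModel}: a [PolyspecModel-class]
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "PolyspecModel"))
  cfg <- model@config
  payload <- list(
    format = "polyspec-model",
    format_version = 1L,
    config = list(inputDim = cfg@inputDim, hiddenUnits = cfg@hiddenUnits,
                  dropoutRate = cfg@dropoutRate, eluAlpha = cfg@eluAlpha,
                  learningRate = cfg@learningRate, batchSize = cfg@batchSize,
                  epochs = cfg@epochs, seed = cfg@seed, bnEps = cfg@bnEps,
                  bnMomentum = cfg@bnMomentum),
    layers = lapply(model@params$layers, function(ly)
      list(W = as.vector(ly$W), b = ly$b, gamma = ly$gamma, beta = ly$beta,
           rmean = ly$rmean, rvar = ly$rvar)),
    Wout = as.vector(model@params$Wout),
    bout = model@params$bout,
    trainingLog = model@trainingLog)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "polyspec-model"))
    stop("not a polyspec model checkpoint")
  if (p$format_version != 1L)
    stop(sprintf("unsupported checkpoint format version %s", p$format_version))
  cfg <- do.call(modelConfig, as.list(p$config))
  dims <- c(cfg@inputDim, cfg@hiddenUnits)
  layers <- lapply(seq_along(cfg@hiddenUnits), function(h) {
    ly <- p$layers[[h]]
    list(W = matrix(as.numeric(ly$W), dims[h], dims[h + 1L]),
         b = as.numeric(ly$b), gamma = as.numeric(ly$gamma),
         beta = as.numeric(ly$beta), rmean = as.numeric(ly$rmean),
         rvar = as.numeric(ly$rvar))
  })
  new("PolyspecModel",
      params = list(layers = layers,
                    Wout = matrix(as.numeric(p$Wout), ncol = 1L),
                    bout = as.numeric(p$bout)),
      config = cfg,
      trainingLog = as.numeric(unlist(p$trainingLog)))
}
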