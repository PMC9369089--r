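#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `alpha * (exp(x) - 1)` for `x <= 0`;
#' continuous at 0.
#'
#' @param x Numeric vector/matrix.
#' @param alpha Positive negative-branch scale.
#' @return Object shaped like `x`.
#' @export
elu <- function(x, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  neg <- x <= 0
  x[neg] <- alpha * expm1(x[neg])
  x
}

#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, computed in a numerically stable
#' form; the network's output unit, read as the 6mA probability.
#'
#' @param x Numeric vector/matrix.
#' @return Values in (0,1), shaped like `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' @rdname ConvNetConfig-class
#' @param ... Slot values overriding the defaults (conv 64 x 7 stride
#'   1, batch-norm momentum 0.8 / epsilon 1e-5, ELU alpha 1, dense
#'   16 and 8).
#' @return A [ConvNetConfig-class].
#' @export
convNetConfig <- function(...) {
  args <- list(...)
  int <- c("convFilters", "kernelSize", "stride", "dense1Units",
           "dense2Units")
  for (nm in intersect(names(args), int)) args[[nm]] <- as.integer(args[[nm]])
  for (nm in intersect(names(args), c("bnMomentum", "bnEpsilon",
                                      "eluAlpha")))
    args[[nm]] <- as.numeric(args[[nm]])
  do.call(new, c(list("ConvNetConfig"), args))
}

#' @rdname TrainConfig-class
#' @param ... Slot values overriding the defaults (SGD lr 0.001,
#'   momentum 0.9, patience 10, max 100 epochs, batch 256, 10 percent
#'   stratified validation split, seed 1).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(...) {
  args <- list(...)
  int <- c("patience", "maxEpochs", "batchSize", "seed")
  for (nm in intersect(names(args), int)) args[[nm]] <- as.integer(args[[nm]])
  for (nm in intersect(names(args), c("learningRate", "momentum",
                                      "validationFraction")))
    args[[nm]] <- as.numeric(args[[nm]])
  do.call(new, c(list("TrainConfig"), args))
}

.glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(prod(dims), -lim, lim), dims[1L], dims[2L])
}

#' Build an untrained convolutional classifier
#'
#' Layer order: conv(filters, kernel, stride 1, valid padding) ->
#' batch normalization -> ELU -> flatten -> dense(16, ELU) ->
#' dense(8, ELU) -> dense(1, sigmoid). The 1-D convolution treats the
#' reduced feature vector as a length-`inputDim` signal with one input
#' channel, so the convolved length is `inputDim - kernelSize + 1`.
#' Weight initialization is Glorot-uniform under `seed`, making
#' construction fully reproducible.
#'
#' @param inputDim Length of the reduced feature vector (must be at
#'   least the kernel size).
#' @param config A [ConvNetConfig-class].
#' @param seed Integer seed for weight initialization.
#' @return An untrained [ConvNet-class].
#' @export
buildNetwork <- function(inputDim, config = convNetConfig(), seed = 1L) {
  stopifnot(is(config, "ConvNetConfig"))
  inputDim <- as.integer(inputDim)
  if (inputDim < config@kernelSize)
    stop("inputDim (", inputDim, ") must be at least the kernel size (",
         config@kernelSize, ")", call. = FALSE)
  k <- config@kernelSize
  f <- config@convFilters
  m <- inputDim - k + 1L
  flat <- m * f
  w <- .withSeed(.deriveSeed(seed, "init"), {
    list(
      Wc = .glorot(k, f),
      bc = numeric(f),
      gamma = rep(1, f),
      betaBN = numeric(f),
      runMean = numeric(f),
      runVar = rep(1, f),
      W1 = .glorot(flat, config@dense1Units),
      b1 = numeric(config@dense1Units),
      W2 = .glorot(config@dense1Units, config@dense2Units),
      b2 = numeric(config@dense2Units),
      W3 = .glorot(config@dense2Units, 1L),
      b3 = numeric(1L)
    )
  })
  new("ConvNet", weights = w, config = config,
      trainSettings = trainConfig(), inputDim = inputDim,
      trained = FALSE,
      history = data.frame(epoch = integer(), loss = numeric(),
                           valAccuracy = numeric()),
      selector = NULL)
}

#' Number of trainable parameters of a network
#'
#' @param net A [ConvNet-class].
#' @return Integer count (batch-norm running statistics excluded).
#' @export
parameterCount <- function(net) {
  stopifnot(is(net, "ConvNet"))
  w <- net@weights
  sum(vapply(w[c("Wc", "bc", "gamma", "betaBN", "W1", "b1",
                 "W2", "b2", "W3", "b3")], length, integer(1L)))
}

# im2col: (n x d) batch -> ((m*n) x k) patch matrix, where row
# (s-1)*m + i holds positions i..i+k-1 of sample s.
.im2col <- function(X, k) {
  n <- nrow(X)
  d <- ncol(X)
  m <- d - k + 1L
  idx <- outer(seq_len(k), seq_len(m) - 1L, `+`)   # k x m
  Xbig <- X[, as.vector(idx), drop = FALSE]        # n x (k*m)
  A <- array(t(Xbig), dim = c(k, m * n))
  t(A)
}

# column-broadcast helpers: add / multiply a per-column constant
# without sweep()'s aperm overhead
.colShift <- function(M, v) M + rep(v, each = nrow(M))
.colScale <- function(M, v) M * rep(v, each = nrow(M))

# ELU derivative from the cached activation output: for z <= 0,
# d/dz alpha*(e^z - 1) = alpha*e^z = elu(z) + alpha.
.eluGradFromOut <- function(z, out, alpha) {
  g <- out + alpha
  g[z > 0] <- 1
  g
}

# Forward pass. training=TRUE uses batch statistics (and updates the
# running ones via new = momentum*old + (1-momentum)*batch);
# training=FALSE normalizes with the stored running statistics.
.forward <- function(w, cfg, X, training = FALSE) {
  n <- nrow(X)
  k <- cfg@kernelSize
  f <- cfg@convFilters
  m <- ncol(X) - k + 1L
  Xcol <- .im2col(X, k)                                  # (m*n) x k
  Z <- .colShift(Xcol %*% w$Wc, w$bc)
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    w$runMean <- cfg@bnMomentum * w$runMean + (1 - cfg@bnMomentum) * mu
    w$runVar <- cfg@bnMomentum * w$runVar + (1 - cfg@bnMomentum) * va
  } else {
    mu <- w$runMean
    va <- w$runVar
  }
  sdv <- sqrt(va + cfg@bnEpsilon)
  Zc <- .colShift(Z, -mu)
  Zhat <- .colScale(Zc, 1 / sdv)
  B <- .colShift(.colScale(Zhat, w$gamma), w$betaBN)
  H <- elu(B, cfg@eluAlpha)                              # (m*n) x f
  # flatten: sample s -> its m x f block, channel varying fastest
  Fmat <- t(matrix(t(H), m * f, n))                      # n x (m*f)
  A1 <- .colShift(Fmat %*% w$W1, w$b1)
  H1 <- elu(A1, cfg@eluAlpha)
  A2 <- .colShift(H1 %*% w$W2, w$b2)
  H2 <- elu(A2, cfg@eluAlpha)
  logit <- as.vector(H2 %*% w$W3 + w$b3)
  p <- sigmoid(logit)
  list(p = p, cache = list(Xcol = Xcol, Zc = Zc, Zhat = Zhat, B = B,
                           H = H, mu = mu, sdv = sdv, Fmat = Fmat,
                           A1 = A1, H1 = H1, A2 = A2, H2 = H2,
                           m = m, n = n, f = f),
       weights = w)
}

# Backward pass for mean binary cross-entropy; returns gradients for
# every trainable tensor.
.backward <- function(w, cfg, X, y, fw) {
  cc <- fw$cache
  n <- cc$n; m <- cc$m; f <- cc$f
  dLogit <- matrix((fw$p - y) / n, ncol = 1L)           # n x 1
  gW3 <- crossprod(cc$H2, dLogit)
  gb3 <- sum(dLogit)
  dH2 <- dLogit %*% t(w$W3)
  dA2 <- dH2 * .eluGradFromOut(cc$A2, cc$H2, cfg@eluAlpha)
  gW2 <- crossprod(cc$H1, dA2)
  gb2 <- colSums(dA2)
  dH1 <- dA2 %*% t(w$W2)
  dA1 <- dH1 * .eluGradFromOut(cc$A1, cc$H1, cfg@eluAlpha)
  gW1 <- crossprod(cc$Fmat, dA1)
  gb1 <- colSums(dA1)
  dFmat <- dA1 %*% t(w$W1)                              # n x (m*f)
  dH <- t(matrix(t(dFmat), f, m * n))                   # (m*n) x f
  dB <- dH * .eluGradFromOut(cc$B, cc$H, cfg@eluAlpha)
  ggamma <- colSums(dB * cc$Zhat)
  gbetaBN <- colSums(dB)
  # batch-norm backward, per channel over N = m*n elements
  N <- m * n
  dZhat <- .colScale(dB, w$gamma)
  Zc <- cc$Zc
  dvar <- colSums(dZhat * Zc) * (-0.5) / (cc$sdv^3)
  dmu <- -colSums(dZhat) / cc$sdv - dvar * 2 * colMeans(Zc)
  dZ <- .colScale(dZhat, 1 / cc$sdv) +
    .colScale(Zc, 2 * dvar / N) +
    rep(dmu / N, each = N)
  gWc <- crossprod(cc$Xcol, dZ)
  gbc <- colSums(dZ)
  # scatter patch gradients back onto the input (unused upstream but
  # completes the chain and is exercised by the gradient check)
  dXcol <- dZ %*% t(w$Wc)                               # (m*n) x k
  dX <- matrix(0, n, ncol(X))
  for (j in seq_len(cfg@kernelSize))
    dX[, j:(j + m - 1L)] <- dX[, j:(j + m - 1L)] +
      t(matrix(dXcol[, j], m, n))
  list(Wc = gWc, bc = gbc, gamma = ggamma, betaBN = gbetaBN,
       W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, X = dX)
}

.bceLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

.stratifiedHoldout <- function(y, fraction, seed) {
  .withSeed(seed, {
    val <- integer()
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nv <- max(1L, round(length(idx) * fraction))
      val <- c(val, sample(idx, nv))
    }
    sort(val)
  })
}

#' Train the convolutional classifier
#'
#' Stochastic gradient descent with momentum on mean binary
#' cross-entropy. A stratified fraction of the rows is held out to
#' monitor validation accuracy (calls at threshold 0.5); training
#' stops once that accuracy has not improved for `patience` epochs or
#' at `maxEpochs`, whichever is first, and the weights of the best
#' epoch are restored. All randomness (validation split, shuffling)
#' derives from `cfg@seed`, so identical inputs give identical
#' histories.
#'
#' @param net An untrained [ConvNet-class] from [buildNetwork()].
#' @param X Numeric matrix of reduced feature vectors
#'   (n x `inputDim`).
#' @param y Binary 0/1 labels; both classes must be present.
#' @param cfg A [TrainConfig-class].
#' @param selector Optional [FeatureSelector-class] to attach to the
#'   model so that prediction can verify dimensionality provenance.
#' @return A trained [ConvNet-class] with its `history` filled in.
#' @export
trainNetwork <- function(net, X, y, cfg = trainConfig(), selector = NULL) {
  stopifnot(is(net, "ConvNet"), is(cfg, "TrainConfig"))
  X <- as.matrix(X)
  y <- .stopIfNot01(y)
  if (ncol(X) != net@inputDim)
    stop("X has ", ncol(X), " columns; network expects ", net@inputDim,
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  if (!is.null(selector) && length(selector@selected) != net@inputDim)
    stop("selector retains ", length(selector@selected),
         " features but the network expects ", net@inputDim,
         call. = FALSE)

  valIdx <- .stratifiedHoldout(y, cfg@validationFraction,
                               .deriveSeed(cfg@seed, "split"))
  Xv <- X[valIdx, , drop = FALSE]; yv <- y[valIdx]
  Xt <- X[-valIdx, , drop = FALSE]; yt <- y[-valIdx]
  nt <- nrow(Xt)

  w <- net@weights
  vel <- lapply(w[c("Wc", "bc", "gamma", "betaBN", "W1", "b1",
                    "W2", "b2", "W3", "b3")],
                function(x) x * 0)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     valAccuracy = numeric())
  bestAcc <- -Inf
  bestEpoch <- 0L
  bestW <- w

  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- .withSeed((.deriveSeed(cfg@seed, "shuffle") + epoch) %%
                       2147483647L,
                     sample.int(nt))
    epochLoss <- 0
    nBatches <- 0L
    for (start in seq(1L, nt, by = cfg@batchSize)) {
      rows <- ord[start:min(start + cfg@batchSize - 1L, nt)]
      if (length(rows) < 2L) next  # batch statistics need >= 2 rows
      Xb <- Xt[rows, , drop = FALSE]
      yb <- yt[rows]
      fw <- .forward(w, net@config, Xb, training = TRUE)
      w <- fw$weights  # running batch-norm statistics advanced
      loss <- .bceLoss(fw$p, yb)
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at epoch ", epoch,
             call. = FALSE)
      epochLoss <- epochLoss + loss
      nBatches <- nBatches + 1L
      g <- .backward(w, net@config, Xb, yb, fw)
      for (nm in names(vel)) {
        vel[[nm]] <- cfg@momentum * vel[[nm]] - cfg@learningRate * g[[nm]]
        w[[nm]] <- w[[nm]] + vel[[nm]]
      }
    }
    pv <- .forward(w, net@config, Xv, training = FALSE)$p
    valAcc <- mean(as.integer(pv >= 0.5) == yv)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   loss = epochLoss / max(nBatches, 1L),
                                   valAccuracy = valAcc))
    if (valAcc > bestAcc) {
      bestAcc <- valAcc
      bestEpoch <- epoch
      bestW <- w
    }
    if (epoch - bestEpoch >= cfg@patience) break
  }

  out <- net
  out@weights <- bestW
  out@trainSettings <- cfg
  out@trained <- TRUE
  out@history <- hist
  out@selector <- selector
  validObject(out)
  out
}

#' Predict 6mA probabilities
#'
#' Forward pass in inference mode (running batch-norm statistics);
#' deterministic, so identical rows receive identical scores.
#'
#' @param model A trained [ConvNet-class].
#' @param X Reduced feature matrix with `model@inputDim` columns.
#' @param batchSize Rows per forward batch (memory control only).
#' @return Numeric scores in [0,1], one per row.
#' @export
predictProba <- function(model, X, batchSize = 1024L) {
  stopifnot(is(model, "ConvNet"))
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim)
    stop("X has ", ncol(X), " columns; network expects ",
         model@inputDim, call. = FALSE)
  n <- nrow(X)
  p <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    rows <- start:min(start + batchSize - 1L, n)
    p[rows] <- .forward(model@weights, model@config,
                        X[rows, , drop = FALSE], training = FALSE)$p
  }
  p
}

#' Threshold scores into binary calls
#'
#' A score greater than or equal to the threshold is called 6mA
#' (label 1); below it, non-6mA (label 0). The tie at exact equality
#' is documented as a positive call.
#'
#' @param scores Numeric scores in [0,1].
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 calls.
#' @export
classifyScores <- function(scores, threshold = 0.5) {
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    stop("scores must lie in [0,1]", call. = FALSE)
  as.integer(scores >= threshold)
}

#' Persist / restore a trained model directory
#'
#' `saveModel()` writes a directory holding `config.json` (network and
#' training settings, input dimension), `weights.json` (full-precision
#' weight tensors), `history.csv`, and `selector.json` when a selector
#' is attached. `loadModel()` reconstructs the model; a dimensionality
#' mismatch between weights, config and selector is an error.
#'
#' @param model A trained [ConvNet-class].
#' @param dir Model directory (created if missing).
#' @return `saveModel()` the directory invisibly; `loadModel()` the
#'   restored [ConvNet-class].
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "ConvNet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- model@config
  tcfg <- model@trainSettings
  conf <- list(
    inputDim = model@inputDim, trained = model@trained,
    network = list(convFilters = cfg@convFilters, kernelSize = cfg@kernelSize,
                   stride = cfg@stride, bnMomentum = cfg@bnMomentum,
                   bnEpsilon = cfg@bnEpsilon, eluAlpha = cfg@eluAlpha,
                   dense1Units = cfg@dense1Units, dense2Units = cfg@dense2Units),
    training = list(learningRate = tcfg@learningRate, momentum = tcfg@momentum,
                    patience = tcfg@patience, maxEpochs = tcfg@maxEpochs,
                    batchSize = tcfg@batchSize,
                    validationFraction = tcfg@validationFraction,
                    seed = tcfg@seed))
  jsonlite::write_json(conf, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  ws <- lapply(model@weights, function(x) {
    if (is.matrix(x)) list(dim = dim(x), values = as.vector(x))
    else list(dim = length(x), values = as.vector(x))
  })
  jsonlite::write_json(ws, file.path(dir, "weights.json"), digits = NA)
  utils::write.csv(model@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  if (!is.null(model@selector))
    writeSelector(model@selector, file.path(dir, "selector.json"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cpath <- file.path(dir, "config.json")
  wpath <- file.path(dir, "weights.json")
  for (p in c(cpath, wpath))
    if (!file.exists(p))
      stop("model file missing: ", p, call. = FALSE)
  conf <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  ws <- jsonlite::read_json(wpath, simplifyVector = TRUE)
  cfg <- do.call(convNetConfig, as.list(conf$network))
  tcfg <- do.call(trainConfig, as.list(conf$training))
  weights <- lapply(ws, function(o) {
    d <- as.integer(unlist(o$dim))
    v <- as.numeric(unlist(o$values))
    if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
  })
  need <- c("Wc", "bc", "gamma", "betaBN", "runMean", "runVar",
            "W1", "b1", "W2", "b2", "W3", "b3")
  if (!all(need %in% names(weights)))
    stop("weights file is missing tensors: ",
         paste(setdiff(need, names(weights)), collapse = ", "),
         call. = FALSE)
  inputDim <- as.integer(conf$inputDim)
  m <- inputDim - cfg@kernelSize + 1L
  if (nrow(weights$W1) != m * cfg@convFilters)
    stop("weight shapes do not match the stored config ",
         "(flatten length ", nrow(weights$W1), " vs expected ",
         m * cfg@convFilters, ")", call. = FALSE)
  spath <- file.path(dir, "selector.json")
  sel <- if (file.exists(spath)) readSelector(spath) else NULL
  if (!is.null(sel) && length(sel@selected) != inputDim)
    stop("selector sidecar retains ", length(sel@selected),
         " features but the model expects ", inputDim, call. = FALSE)
  hpath <- file.path(dir, "history.csv")
  hist <- if (file.exists(hpath)) utils::read.csv(hpath)
          else data.frame(epoch = integer(), loss = numeric(),
                          valAccuracy = numeric())
  new("ConvNet", weights = weights, config = cfg, trainSettings = tcfg,
      inputDim = inputDim, trained = isTRUE(conf$trained),
      history = hist, selector = sel)
}
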