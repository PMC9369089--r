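# Elastic-net objective on the standardized, centred problem:
#   J(beta) = ||yc - Xs beta||^2 + lambda1 ||beta||_1 + lambda2 ||beta||_2^2
# The reported coefficient vector is the naive solution rescaled by
# (1 + lambda2/n); the rescaling never changes the nonzero set.
.enetObjective <- function(Xs, yc, beta, lambda1, lambda2) {
  r <- yc - as.vector(Xs %*% beta)
  sum(r^2) + lambda1 * sum(abs(beta)) + lambda2 * sum(beta^2)
}

.softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Cyclic coordinate descent for the objective above. Exact zeros come
# from the soft-threshold, so the selected set is the solver's own
# sparsity pattern, with no magnitude cutoff.
.enetCoordinateDescent <- function(Xs, yc, lambda1, lambda2,
                                   tol = 1e-6, maxIter = 10000L) {
  p <- ncol(Xs)
  xss <- colSums(Xs^2)
  beta <- numeric(p)
  r <- yc
  active <- which(xss > 0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (j in active) {
      bj <- beta[j]
      rho <- sum(Xs[, j] * r) + xss[j] * bj
      bnew <- .softThreshold(rho, lambda1 / 2) / (xss[j] + lambda2)
      if (bnew != bj) {
        r <- r - Xs[, j] * (bnew - bj)
        beta[j] <- bnew
        delta <- max(delta, abs(bnew - bj))
      }
    }
    if (delta < tol || iter >= maxIter) break
  }
  list(beta = beta, iterations = iter, converged = iter < maxIter)
}

#' Fit the elastic-net feature selector
#'
#' Regresses 0/1 labels on the flattened encoding as a penalized least
#' squares problem with an L1 and an L2 penalty, fitted by cyclic
#' coordinate descent on training data only. Features are standardized
#' internally (training mean/sd; the statistics are stored on the
#' model) and the labels centred, so no intercept is penalized. The
#' retained feature set is exactly the solver's nonzero coefficients.
#'
#' With `lambda1 = 0` the problem is ridge regression (ordinary least
#' squares when `lambda2 = 0` too) and is solved in closed form; with
#' `lambda2 = 0` it is the lasso. When both penalties are `NULL`, the
#' default strength is `lambda1 = 0.01 * lambda1max` — where
#' `lambda1max = 2 max|Xs'yc|` is the smallest L1 weight that zeroes
#' every coefficient — with `lambda2 = lambda1` (equal mixing).
#'
#' @param X Numeric design matrix (n x p), e.g. from [encodeDataset()].
#' @param y Binary 0/1 labels of length n; both classes must occur.
#' @param lambda1,lambda2 Nonnegative L1/L2 penalty weights, or `NULL`
#'   for the defaults described above.
#' @param tol Coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep.
#' @param maxIter Maximum number of full sweeps.
#' @return A [FeatureSelector-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 12), 200)
#' y <- as.integer(X[, 3] > 0)
#' fitSelector(X, y)
#' @export
fitSelector <- function(X, y, lambda1 = NULL, lambda2 = NULL,
                        tol = 1e-6, maxIter = 10000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least 2 training rows", call. = FALSE)
  y <- .stopIfNot01(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)

  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2L, center)^2))
  scale[scale == 0] <- 1  # constant columns stay at coefficient zero
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  yMean <- mean(y)
  yc <- y - yMean

  if (is.null(lambda1) || is.null(lambda2)) {
    l1max <- 2 * max(abs(crossprod(Xs, yc)))
    if (is.null(lambda1)) lambda1 <- 0.01 * l1max
    if (is.null(lambda2)) lambda2 <- lambda1
  }
  if (lambda1 < 0 || lambda2 < 0)
    stop("penalty weights must be nonnegative", call. = FALSE)

  if (lambda1 == 0) {
    # ridge / OLS closed form on the non-constant columns
    keep <- apply(Xs, 2L, function(col) any(col != 0))
    beta <- numeric(p)
    A <- crossprod(Xs[, keep, drop = FALSE]) +
      diag(lambda2, sum(keep))
    beta[keep] <- as.vector(solve(A, crossprod(Xs[, keep, drop = FALSE], yc)))
    fit <- list(beta = beta, iterations = 0L, converged = TRUE)
  } else {
    fit <- .enetCoordinateDescent(Xs, yc, lambda1, lambda2, tol, maxIter)
    if (!fit$converged)
      warning("coordinate descent did not converge in ", maxIter,
              " sweeps", call. = FALSE)
  }
  beta <- fit$beta * (1 + lambda2 / n)
  selected <- which(beta != 0)

  new("FeatureSelector",
      beta = beta, lambda1 = lambda1, lambda2 = lambda2,
      n = as.integer(n), selected = as.integer(selected),
      center = center, scale = scale, yMean = yMean,
      converged = fit$converged, iterations = fit$iterations,
      inputDim = as.integer(p),
      featureNames = if (is.null(colnames(X))) character() else colnames(X))
}

#' Reduce a feature matrix to the selector's retained columns
#'
#' Pure column gather in `selectedIndices()` order; no refitting and
#' no rescaling, so `applySelector(m, X)[, k] == X[, selectedIndices(m)[k]]`.
#'
#' @param model A [FeatureSelector-class].
#' @param X Numeric matrix whose column count matches the selector's
#'   input dimensionality.
#' @return Matrix with `nSelected(model)` columns.
#' @export
applySelector <- function(model, X) {
  stopifnot(is(model, "FeatureSelector"))
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim)
    stop("X has ", ncol(X), " columns but the selector expects ",
         model@inputDim, call. = FALSE)
  if (length(model@selected) == 0L)
    stop("selector retained no features; refit with a smaller lambda1",
         call. = FALSE)
  X[, model@selected, drop = FALSE]
}

#' Summary record for a fitted selector
#'
#' @param model A [FeatureSelector-class].
#' @return A list with the retained count, penalty weights, training
#'   size, convergence status, and the retained indices with their
#'   coefficient magnitudes (standardized scale), largest first.
#' @export
selectorReport <- function(model) {
  stopifnot(is(model, "FeatureSelector"))
  if (length(model@selected) == 0L)
    warning("selector retained no features", call. = FALSE)
  mag <- abs(model@beta[model@selected])
  ord <- order(mag, decreasing = TRUE)
  list(
    nSelected = length(model@selected),
    inputDim = model@inputDim,
    lambda1 = model@lambda1,
    lambda2 = model@lambda2,
    n = model@n,
    converged = model@converged,
    iterations = model@iterations,
    selected = model@selected,
    coefficientMagnitudes = stats::setNames(
      mag[ord],
      if (length(model@featureNames))
        model@featureNames[model@selected][ord]
      else as.character(model@selected[ord]))
  )
}

#' Serialize / restore a fitted selector as JSON
#'
#' @param model A [FeatureSelector-class].
#' @param path JSON file path.
#' @return `writeSelector()` the path invisibly; `readSelector()` the
#'   restored [FeatureSelector-class].
#' @export
writeSelector <- function(model, path) {
  stopifnot(is(model, "FeatureSelector"))
  obj <- list(beta = model@beta, lambda1 = model@lambda1,
              lambda2 = model@lambda2, n = model@n,
              selected = model@selected, center = model@center,
              scale = model@scale, yMean = model@yMean,
              converged = model@converged, iterations = model@iterations,
              inputDim = model@inputDim, featureNames = model@featureNames)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSelector
#' @export
readSelector <- function(path) {
  if (!file.exists(path))
    stop("selector file not found: ", path, call. = FALSE)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FeatureSelector",
      beta = as.numeric(o$beta), lambda1 = o$lambda1, lambda2 = o$lambda2,
      n = as.integer(o$n), selected = as.integer(o$selected),
      center = as.numeric(o$center), scale = as.numeric(o$scale),
      yMean = o$yMean, converged = o$converged,
      iterations = as.integer(o$iterations),
      inputDim = as.integer(o$inputDim),
      featureNames = as.character(o$featureNames %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
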