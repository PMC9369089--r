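#' Fit the full 6mA pipeline on a labeled dataset
#'
#' Encodes the sequences (41 x 8 per window, flattened to 328),
#' fits the elastic-net selector on these training data, reduces the
#' design to the retained columns, and trains the convolutional
#' classifier on the reduced features. The returned model carries its
#' selector, so [predictPipeline()] can be applied to raw sequences.
#'
#' @param dataset A [MethSeqSet-class] with both classes present.
#' @param lambda1,lambda2 Selector penalties (see [fitSelector()]).
#' @param selectK Optional compatibility switch: instead of the
#'   solver's nonzero set, retain the `selectK` largest-magnitude
#'   coefficients (e.g. 173 to reproduce a fixed published
#'   dimensionality). Default `NULL` uses the native sparsity.
#' @param netConfig A [ConvNetConfig-class].
#' @param trainCfg A [TrainConfig-class].
#' @return A trained [ConvNet-class] with the fitted
#'   [FeatureSelector-class] attached.
#' @export
trainPipeline <- function(dataset, lambda1 = NULL, lambda2 = NULL,
                          selectK = NULL,
                          netConfig = convNetConfig(),
                          trainCfg = trainConfig()) {
  stopifnot(is(dataset, "MethSeqSet"))
  X <- encodeDataset(dataset)
  y <- classLabels(dataset)
  sel <- fitSelector(X, y, lambda1, lambda2)
  if (!is.null(selectK)) sel <- topKSelector(sel, selectK)
  if (nSelected(sel) < netConfig@kernelSize)
    stop("selector retained ", nSelected(sel), " features, fewer than ",
         "the kernel size (", netConfig@kernelSize, "); decrease lambda1",
         call. = FALSE)
  Xr <- applySelector(sel, X)
  net <- buildNetwork(ncol(Xr), netConfig, seed = trainCfg@seed)
  trainNetwork(net, Xr, y, trainCfg, selector = sel)
}

#' Score raw sequences with a trained pipeline model
#'
#' @param model A trained [ConvNet-class] whose selector sidecar is
#'   attached (as produced by [trainPipeline()] or [loadModel()]).
#' @param x A [MethSeqSet-class], [Biostrings::DNAStringSet] or
#'   character vector of windows.
#' @param threshold Decision threshold for the calls.
#' @return Data frame with columns id, score, call (0/1).
#' @export
predictPipeline <- function(model, x, threshold = 0.5) {
  stopifnot(is(model, "ConvNet"))
  if (is.null(model@selector))
    stop("model has no attached selector; load it with its sidecar",
         call. = FALSE)
  seqs <- if (is(x, "MethSeqSet")) sequences(x)
          else if (is.character(x)) Biostrings::DNAStringSet(toupper(x))
          else x
  X <- encodeDataset(seqs)
  Xr <- applySelector(model@selector, X)
  scores <- predictProba(model, Xr)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(scores))
  data.frame(id = ids, score = scores,
             call = classifyScores(scores, threshold),
             stringsAsFactors = FALSE)
}

#' Restrict a fitted selector to its top-k coefficients
#'
#' Compatibility helper for reproducing a fixed published feature
#' count: keeps the `k` largest |coefficients| of an already-fitted
#' selector and zeroes the rest. The native selection rule remains
#' the solver's exact nonzero set.
#'
#' @param model A [FeatureSelector-class].
#' @param k Number of features to keep; must not exceed the fitted
#'   nonzero count.
#' @return A [FeatureSelector-class] retaining exactly `k` features.
#' @export
topKSelector <- function(model, k) {
  stopifnot(is(model, "FeatureSelector"))
  k <- as.integer(k)
  if (k < 1L || k > length(model@selected))
    stop("k must lie in [1, ", length(model@selected),
         "] (the fitted nonzero count)", call. = FALSE)
  mag <- abs(model@beta)
  keep <- sort(order(mag, decreasing = TRUE)[seq_len(k)])
  beta <- numeric(length(model@beta))
  beta[keep] <- model@beta[keep]
  out <- model
  out@beta <- beta
  out@selected <- as.integer(keep)
  validObject(out)
  out
}
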