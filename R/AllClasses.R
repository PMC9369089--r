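#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   alphabetFrequency width subseq
NULL

#' Labeled 41-bp methylation dataset
#'
#' A container pairing a set of fixed-length DNA windows with binary
#' 6mA labels (1 = methylated adenine at the window centre, 0 = not).
#' All pipeline stages consume this class.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of equal-width windows
#'   over the strict \{A,C,G,T\} alphabet.
#' @slot labels Integer vector of 0/1 labels, one per sequence.
#' @slot datasetName Free-text dataset identifier.
#'
#' @seealso [MethSeqSet()], [loadDataset()], [simulateDataset()]
#' @exportClass MethSeqSet
setClass("MethSeqSet",
  slots = c(
    sequences   = "DNAStringSet",
    labels      = "integer",
    datasetName = "character"
  )
)

setValidity("MethSeqSet", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "number of sequences and labels differ")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  w <- Biostrings::width(object@sequences)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have the same width")
  if (length(object@sequences)) {
    af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    if (any(af[, "other"] > 0))
      msg <- c(msg, "sequences must contain only A, C, G, T")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted elastic-net feature selector
#'
#' Holds the coefficient vector of a linear elastic-net regression of
#' 0/1 labels on the flattened encoding, the penalty weights, the
#' training-set standardization statistics, and the retained feature
#' index set (exactly the nonzero coefficients). The index set is what
#' gets transferred from the training partition to held-out data.
#'
#' @slot beta Coefficients on the standardized scale, after the
#'   naive-elastic-net rescaling by (1 + lambda2/n).
#' @slot lambda1,lambda2 Nonnegative L1 and L2 penalty weights.
#' @slot n Training sample count.
#' @slot selected Strictly increasing 1-based indices of nonzero
#'   coefficients.
#' @slot center,scale Per-feature training mean and standard deviation
#'   used inside the fit.
#' @slot yMean Training label mean (the implicit intercept).
#' @slot converged,iterations Coordinate-descent convergence status.
#' @slot inputDim Expected feature count of matrices passed to
#'   [applySelector()].
#' @slot featureNames Feature (column) names, if the design had any.
#'
#' @seealso [fitSelector()], [applySelector()], [selectorReport()]
#' @exportClass FeatureSelector
setClass("FeatureSelector",
  slots = c(
    beta         = "numeric",
    lambda1      = "numeric",
    lambda2      = "numeric",
    n            = "integer",
    selected     = "integer",
    center       = "numeric",
    scale        = "numeric",
    yMean        = "numeric",
    converged    = "logical",
    iterations   = "integer",
    inputDim     = "integer",
    featureNames = "character"
  )
)

setValidity("FeatureSelector", function(object) {
  msg <- character()
  if (object@lambda1 < 0 || object@lambda2 < 0)
    msg <- c(msg, "lambda1 and lambda2 must be nonnegative")
  s <- object@selected
  if (length(s) && (is.unsorted(s, strictly = TRUE) ||
                    any(s < 1L) || any(s > object@inputDim)))
    msg <- c(msg, "selected indices must be strictly increasing within [1, inputDim]")
  if (!identical(which(object@beta != 0), as.integer(s)))
    msg <- c(msg, "selected indices must be exactly the nonzero coefficients")
  if (length(msg)) msg else TRUE
})

#' Convolutional network architecture settings
#'
#' Topology of the 1-D convolutional classifier: a single convolution
#' (64 filters, kernel 7, stride 1, valid padding) followed by batch
#' normalization (moving-average momentum 0.8, epsilon 1e-5), ELU
#' activation, flattening, two dense layers (16 and 8 units, ELU) and a
#' single sigmoid output unit.
#'
#' @slot convFilters,kernelSize,stride Convolution layer shape.
#' @slot bnMomentum Weight on the running statistic in the moving
#'   average update `new = momentum * old + (1 - momentum) * batch`.
#' @slot bnEpsilon Variance floor added before the normalizing square
#'   root.
#' @slot eluAlpha ELU negative-branch scale (alpha > 0).
#' @slot dense1Units,dense2Units Dense layer widths.
#'
#' @seealso [convNetConfig()], [buildNetwork()]
#' @exportClass ConvNetConfig
setClass("ConvNetConfig",
  slots = c(
    convFilters = "integer",
    kernelSize  = "integer",
    stride      = "integer",
    bnMomentum  = "numeric",
    bnEpsilon   = "numeric",
    eluAlpha    = "numeric",
    dense1Units = "integer",
    dense2Units = "integer"
  ),
  prototype = list(
    convFilters = 64L, kernelSize = 7L, stride = 1L,
    bnMomentum = 0.8, bnEpsilon = 1e-5, eluAlpha = 1.0,
    dense1Units = 16L, dense2Units = 8L
  )
)

setValidity("ConvNetConfig", function(object) {
  msg <- character()
  ints <- c(object@convFilters, object@kernelSize, object@stride,
            object@dense1Units, object@dense2Units)
  if (any(ints < 1L)) msg <- c(msg, "all unit counts must be positive integers")
  if (object@stride != 1L) msg <- c(msg, "only stride 1 is supported")
  if (object@bnMomentum <= 0 || object@bnMomentum >= 1)
    msg <- c(msg, "bnMomentum must lie in (0,1)")
  if (object@eluAlpha <= 0) msg <- c(msg, "eluAlpha must be positive")
  if (object@bnEpsilon <= 0) msg <- c(msg, "bnEpsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Training regime settings
#'
#' Stochastic gradient descent with momentum, binary cross-entropy
#' loss, and early stopping on validation accuracy: training halts
#' once the validation accuracy has not improved for `patience` epochs
#' and the weights of the best epoch are restored.
#'
#' @slot learningRate,momentum SGD step size and momentum.
#' @slot patience Early-stopping patience in epochs (>= 1).
#' @slot maxEpochs Hard cap on epochs.
#' @slot batchSize Mini-batch size.
#' @slot validationFraction Fraction of the training partition held
#'   out (stratified) to monitor validation accuracy.
#' @slot seed Seed controlling initialization, shuffling and the
#'   validation split.
#'
#' @seealso [trainConfig()], [trainNetwork()]
#' @exportClass TrainConfig
setClass("TrainConfig",
  slots = c(
    learningRate       = "numeric",
    momentum           = "numeric",
    patience           = "integer",
    maxEpochs          = "integer",
    batchSize          = "integer",
    validationFraction = "numeric",
    seed               = "integer"
  ),
  prototype = list(
    learningRate = 0.001, momentum = 0.9, patience = 10L,
    maxEpochs = 100L, batchSize = 256L, validationFraction = 0.1,
    seed = 1L
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    msg <- c(msg, "validationFraction must lie in (0,1)")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' One-dimensional convolutional 6mA classifier
#'
#' The network object returned by [buildNetwork()] (untrained) and
#' [trainNetwork()] (trained). Weights are plain numeric matrices;
#' `history` records per-epoch training loss and validation accuracy.
#'
#' @slot weights Named list of weight matrices/vectors, including the
#'   batch-norm running statistics.
#' @slot config A [ConvNetConfig-class].
#' @slot trainSettings A [TrainConfig-class] (as used; defaults before
#'   training).
#' @slot inputDim Length of the reduced feature vector the network
#'   expects.
#' @slot trained Whether [trainNetwork()] has been run.
#' @slot history Data frame with columns epoch, loss, valAccuracy.
#' @slot selector The [FeatureSelector-class] this model expects
#'   upstream, or NULL.
#'
#' @seealso [buildNetwork()], [trainNetwork()], [predictProba()]
#' @exportClass ConvNet
setClass("ConvNet",
  slots = c(
    weights       = "list",
    config        = "ConvNetConfig",
    trainSettings = "TrainConfig",
    inputDim      = "integer",
    trained       = "logical",
    history       = "data.frame",
    selector      = "ANY"
  )
)

setValidity("ConvNet", function(object) {
  if (object@inputDim < object@config@kernelSize)
    return("inputDim must be at least the kernel size")
  if (!is.null(object@selector) && is(object@selector, "FeatureSelector") &&
      length(object@selector@selected) != object@inputDim)
    return("inputDim must equal the selector's retained feature count")
  TRUE
})

#' Confusion-matrix derived performance report
#'
#' Accuracy, sensitivity, specificity and Matthews correlation from
#' the confusion counts at the decision threshold, plus the
#' threshold-free ROC AUC and the area under the precision-recall
#' curve with its no-skill baseline (the positive fraction).
#'
#' @slot counts Named integer vector TP, FP, TN, FN.
#' @slot acc,sn,sp Accuracy, sensitivity, specificity in [0,1].
#' @slot mcc Matthews correlation coefficient in [-1,1].
#' @slot auc ROC AUC in [0,1] (NA when computed from calls only).
#' @slot auprc Area under the precision-recall curve (NA likewise).
#' @slot baselineAUPRC Positive fraction of the evaluated set.
#'
#' @seealso [evaluateScores()], [classificationMetrics()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  slots = c(
    counts        = "integer",
    acc           = "numeric",
    sn            = "numeric",
    sp            = "numeric",
    mcc           = "numeric",
    auc           = "numeric",
    auprc         = "numeric",
    baselineAUPRC = "numeric"
  )
)

#' Stratified k-fold cross-validation result
#'
#' Per-fold [MetricsReport-class] objects for the full
#' encode/select/train/evaluate pipeline, with a mean and standard
#' deviation summary across folds.
#'
#' @slot folds List of per-fold MetricsReport objects.
#' @slot summary Data frame with columns metric, mean, sd.
#' @slot k Number of folds.
#' @slot seed Seed that fixed the fold assignment.
#' @slot featureCounts Integer vector of per-fold retained feature
#'   counts.
#'
#' @seealso [kFoldCV()]
#' @exportClass CVResult
setClass("CVResult",
  slots = c(
    folds         = "list",
    summary       = "data.frame",
    k             = "integer",
    seed          = "integer",
    featureCounts = "integer"
  )
)
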