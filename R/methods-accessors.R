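#' @importFrom stats coef
NULL

#' @rdname MethSeqSet
#' @aliases sequences,MethSeqSet-method
#' @export
setMethod("sequences", "MethSeqSet", function(x) x@sequences)

#' @rdname MethSeqSet
#' @export
setMethod("classLabels", "MethSeqSet", function(x) x@labels)

#' @rdname MethSeqSet
#' @export
setMethod("datasetName", "MethSeqSet", function(x) x@datasetName)

#' @rdname MethSeqSet
#' @export
setMethod("positiveCount", "MethSeqSet", function(x) sum(x@labels == 1L))

#' @rdname MethSeqSet
#' @export
setMethod("negativeCount", "MethSeqSet", function(x) sum(x@labels == 0L))

#' @rdname MethSeqSet
#' @export
setMethod("length", "MethSeqSet", function(x) length(x@labels))

#' Subset a labeled dataset by sequence index
#'
#' @param x A [MethSeqSet-class].
#' @param i Index vector.
#' @param j,...,drop Ignored (matrix-style arguments kept for the
#'   generic's signature).
#' @return A [MethSeqSet-class] with the selected records.
#' @export
setMethod("[", "MethSeqSet", function(x, i, j, ..., drop = TRUE) {
  new("MethSeqSet",
      sequences = x@sequences[i],
      labels = x@labels[i],
      datasetName = x@datasetName)
})

setMethod("show", "MethSeqSet", function(object) {
  w <- unique(Biostrings::width(object@sequences))
  cat("MethSeqSet \"", object@datasetName, "\": ",
      length(object@labels), " sequences (",
      sum(object@labels == 1L), " 6mA / ",
      sum(object@labels == 0L), " non-6mA), width ",
      if (length(w)) w else NA, " bp\n", sep = "")
})

#' @rdname FeatureSelector
#' @export
setMethod("selectedIndices", "FeatureSelector", function(x) x@selected)

#' @rdname FeatureSelector
#' @export
setMethod("nSelected", "FeatureSelector", function(x) length(x@selected))

#' @rdname FeatureSelector
#' @param object A [FeatureSelector-class].
#' @param ... Ignored.
#' @export
setMethod("coef", "FeatureSelector", function(object, ...) object@beta)

setMethod("show", "FeatureSelector", function(object) {
  cat("FeatureSelector: ", length(object@selected), " of ",
      object@inputDim, " features retained\n",
      "  lambda1 = ", format(object@lambda1, digits = 4),
      ", lambda2 = ", format(object@lambda2, digits = 4),
      ", n = ", object@n, "\n",
      "  converged: ", object@converged,
      " (", object@iterations, " sweeps)\n", sep = "")
})

#' @rdname ConvNet
#' @export
setMethod("trainingHistory", "ConvNet", function(x) x@history)

setMethod("show", "ConvNet", function(object) {
  cfg <- object@config
  m <- object@inputDim - cfg@kernelSize + 1L
  cat("ConvNet (", if (object@trained) "trained" else "untrained", ")\n",
      "  input ", object@inputDim,
      " -> conv(", cfg@convFilters, " x ", cfg@kernelSize,
      ") -> bn -> elu -> flatten(", m * cfg@convFilters,
      ") -> dense(", cfg@dense1Units, ") -> dense(", cfg@dense2Units,
      ") -> sigmoid\n", sep = "")
  if (object@trained && nrow(object@history)) {
    best <- which.max(object@history$valAccuracy)
    cat("  ", nrow(object@history), " epochs; best val accuracy ",
        format(object@history$valAccuracy[best], digits = 4),
        " at epoch ", object@history$epoch[best], "\n", sep = "")
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (n = ", sum(object@counts), ")\n", sep = "")
  cat(sprintf("  Acc %.4f  Sn %.4f  Sp %.4f  MCC %.4f\n",
              object@acc, object@sn, object@sp, object@mcc))
  if (!is.na(object@auc))
    cat(sprintf("  AUC %.4f  AUPRC %.4f (baseline %.4f)\n",
                object@auc, object@auprc, object@baselineAUPRC))
})

setMethod("show", "CVResult", function(object) {
  cat(object@k, "-fold cross-validation (seed ", object@seed, ")\n", sep = "")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %.4f+/-%.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat("  retained features per fold:",
      paste(object@featureCounts, collapse = ", "), "\n")
})
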