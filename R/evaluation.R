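#' Confusion counts at a fixed decision
#'
#' @param truth Binary 0/1 ground-truth labels.
#' @param calls Binary 0/1 predicted calls.
#' @return Named integer vector with elements TP, FP, TN, FN.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(truth, calls) {
  truth <- .stopIfNot01(truth, "truth")
  calls <- .stopIfNot01(calls, "calls")
  if (length(truth) != length(calls))
    stop("truth and calls differ in length", call. = FALSE)
  c(TP = sum(truth == 1L & calls == 1L),
    FP = sum(truth == 0L & calls == 1L),
    TN = sum(truth == 0L & calls == 0L),
    FN = sum(truth == 1L & calls == 0L))
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' Acc = (TP+TN)/(TP+TN+FP+FN); Sn = TP/(TP+FN); Sp = TN/(TN+FP);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' An undefined ratio (empty class) yields NA for Sn/Sp; an MCC with a
#' zero denominator is defined as 0, the conventional completion.
#'
#' @param counts Named vector with TP, FP, TN, FN (as from
#'   [confusionCounts()]).
#' @return Named numeric vector (acc, sn, sp, mcc).
#' @export
classificationMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  acc <- (tp + tn) / total
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

# Sweep over unique score thresholds, highest first; returns per-cut
# cumulative TP/FP (ties share a cut).
.scoreCuts <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  tpCum <- cumsum(t == 1L)
  fpCum <- cumsum(t == 0L)
  ends <- which(!duplicated(s, fromLast = TRUE))
  list(tp = tpCum[ends], fp = fpCum[ends],
       P = sum(truth == 1L), N = sum(truth == 0L))
}

#' ROC area under the curve
#'
#' Trapezoidal area under the ROC curve with tied scores grouped into
#' a single threshold, which makes the area equal the Mann-Whitney
#' probability that a random positive outscores a random negative
#' (ties counting one half).
#'
#' @param truth Binary 0/1 labels (both classes required).
#' @param scores Numeric scores, larger meaning more positive.
#' @return AUC in [0,1].
#' @export
rocAUC <- function(truth, scores) {
  truth <- .stopIfNot01(truth, "truth")
  if (length(truth) != length(scores))
    stop("truth and scores differ in length", call. = FALSE)
  cuts <- .scoreCuts(truth, scores)
  if (cuts$P == 0L || cuts$N == 0L)
    stop("AUC needs both classes", call. = FALSE)
  tpr <- c(0, cuts$tp / cuts$P)
  fpr <- c(0, cuts$fp / cuts$N)
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Precision-recall curve and its area
#'
#' Step-interpolated (average-precision) area: the sum over score
#' thresholds of precision times the recall increment, with tied
#' scores grouped. Step interpolation is used rather than trapezoids
#' because linear interpolation in PR space is optimistic; the
#' `interpolation` switch exposes the trapezoidal alternative.
#'
#' @inheritParams rocAUC
#' @param interpolation `"step"` (default, average precision) or
#'   `"trapezoid"`.
#' @return A [PRCurve] result: list with `recall` (non-decreasing),
#'   `precision`, `area`, and `baseline` (the positive fraction).
#' @export
prCurve <- function(truth, scores, interpolation = c("step", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  truth <- .stopIfNot01(truth, "truth")
  if (length(truth) != length(scores))
    stop("truth and scores differ in length", call. = FALSE)
  cuts <- .scoreCuts(truth, scores)
  if (cuts$P == 0L)
    stop("precision-recall needs at least one positive", call. = FALSE)
  recall <- cuts$tp / cuts$P
  precision <- cuts$tp / (cuts$tp + cuts$fp)
  dRec <- diff(c(0, recall))
  area <- if (interpolation == "step") {
    sum(dRec * precision)
  } else {
    prevPrec <- c(1, precision[-length(precision)])
    sum(dRec * (precision + prevPrec) / 2)
  }
  list(recall = recall, precision = precision, area = area,
       baseline = cuts$P / (cuts$P + cuts$N))
}

#' No-skill AUPRC baseline
#'
#' The expected precision-recall area of an uninformative scorer: the
#' positive fraction, positives / total.
#'
#' @param x A [MethSeqSet-class] or a binary 0/1 label vector.
#' @return The positive fraction in (0,1).
#' @export
baselineAUPRC <- function(x) {
  y <- if (is(x, "MethSeqSet")) classLabels(x) else .stopIfNot01(x)
  if (length(y) == 0L) stop("empty label vector", call. = FALSE)
  mean(y == 1L)
}

#' Threshold-based and threshold-free evaluation in one report
#'
#' @param truth Binary 0/1 labels.
#' @param scores Numeric scores in [0,1].
#' @param threshold Decision threshold for the confusion metrics.
#' @return A [MetricsReport-class].
#' @export
evaluateScores <- function(truth, scores, threshold = 0.5) {
  truth <- .stopIfNot01(truth, "truth")
  calls <- classifyScores(scores, threshold)
  counts <- confusionCounts(truth, calls)
  m <- classificationMetrics(counts)
  bothClasses <- length(unique(truth)) == 2L
  new("MetricsReport",
      counts = counts,
      acc = m[["acc"]], sn = m[["sn"]], sp = m[["sp"]], mcc = m[["mcc"]],
      auc = if (bothClasses) rocAUC(truth, scores) else NA_real_,
      auprc = if (any(truth == 1L)) prCurve(truth, scores)$area
              else NA_real_,
      baselineAUPRC = mean(truth == 1L))
}

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin, so per-fold class counts differ by at most 1.
.stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified five-fold cross-validation of the full pipeline
#'
#' For each fold: the elastic-net selector is fitted on the training
#' partition only, the network is trained on the reduced training
#' features, and metrics are computed on the reduced test features
#' with the transferred index set — no test-fold row ever reaches
#' selector fitting or network training. Folds are stratified and
#' seeded.
#'
#' @param dataset A [MethSeqSet-class]; each class must have at least
#'   `k` members.
#' @param k Number of folds (default 5).
#' @param lambda1,lambda2 Selector penalties (see [fitSelector()]).
#' @param netConfig A [ConvNetConfig-class].
#' @param trainCfg A [TrainConfig-class]; its seed is re-derived per
#'   fold.
#' @param seed Root seed for fold assignment and per-fold training.
#' @param threshold Decision threshold.
#' @param instrument Optional function called as
#'   `instrument(stage, fold, rows)` with `stage` in
#'   `c("selector", "train")` and `rows` the row indices handed to
#'   that stage; intended for leakage auditing.
#' @return A [CVResult-class].
#' @export
kFoldCV <- function(dataset, k = 5L, lambda1 = NULL, lambda2 = NULL,
                    netConfig = convNetConfig(), trainCfg = trainConfig(),
                    seed = 1L, threshold = 0.5, instrument = NULL) {
  stopifnot(is(dataset, "MethSeqSet"))
  y <- classLabels(dataset)
  k <- as.integer(k)
  if (min(table(y)) < k)
    stop("each class needs at least ", k, " members for ", k,
         "-fold cross-validation", call. = FALSE)
  X <- encodeDataset(dataset)
  fold <- .stratifiedFolds(y, k, .deriveSeed(seed, "fold"))

  reports <- vector("list", k)
  featureCounts <- integer(k)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    if (!is.null(instrument)) instrument("selector", f, trainIdx)
    sel <- fitSelector(X[trainIdx, , drop = FALSE], y[trainIdx],
                       lambda1, lambda2)
    featureCounts[f] <- nSelected(sel)
    Xtr <- applySelector(sel, X[trainIdx, , drop = FALSE])
    Xte <- applySelector(sel, X[testIdx, , drop = FALSE])
    if (!is.null(instrument)) instrument("train", f, trainIdx)
    tcfg <- trainCfg
    tcfg@seed <- (.deriveSeed(seed, "fold") + f) %% 2147483647L
    net <- buildNetwork(ncol(Xtr), netConfig, seed = tcfg@seed)
    net <- trainNetwork(net, Xtr, y[trainIdx], tcfg, selector = sel)
    p <- predictProba(net, Xte)
    reports[[f]] <- evaluateScores(y[testIdx], p, threshold)
  }

  metricNames <- c("acc", "sn", "sp", "mcc", "auc", "auprc")
  vals <- sapply(reports, function(r)
    c(r@acc, r@sn, r@sp, r@mcc, r@auc, r@auprc))
  rownames(vals) <- metricNames
  summary <- data.frame(metric = metricNames,
                        mean = apply(vals, 1L, mean),
                        sd = apply(vals, 1L, stats::sd),
                        row.names = NULL)
  new("CVResult", folds = reports, summary = summary, k = k,
      seed = as.integer(seed), featureCounts = featureCounts)
}

#' Build a 1:r class-imbalanced dataset
#'
#' Keeps every negative and downsamples the positives, uniformly
#' without replacement under `seed`, to `floor(N/r)` where N is the
#' negative count — the construction consistent with the benchmark
#' splits (e.g. 1966 negatives at 1:5 gives 393 positives, at 1:10
#' gives 196).
#'
#' @param dataset A [MethSeqSet-class].
#' @param ratio Integer r >= 1, negatives per positive.
#' @param seed Seed for the positive draw.
#' @return A [MethSeqSet-class] with counts (floor(N/r), N);
#'   positives first.
#' @export
subsampleRatio <- function(dataset, ratio, seed = 1L) {
  stopifnot(is(dataset, "MethSeqSet"))
  ratio <- as.integer(ratio)
  if (is.na(ratio) || ratio < 1L)
    stop("ratio must be an integer >= 1", call. = FALSE)
  y <- classLabels(dataset)
  posIdx <- which(y == 1L)
  negIdx <- which(y == 0L)
  nKeep <- length(negIdx) %/% ratio
  if (nKeep == 0L)
    stop("too few negatives for a 1:", ratio, " split", call. = FALSE)
  if (nKeep > length(posIdx))
    stop("dataset has only ", length(posIdx), " positives but a 1:",
         ratio, " split needs ", nKeep, call. = FALSE)
  keep <- .withSeed(.deriveSeed(seed, "subsample"),
                    sort(sample(posIdx, nKeep)))
  out <- dataset[c(keep, negIdx)]
  out@datasetName <- paste0(datasetName(dataset), "_1to", ratio)
  out
}
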