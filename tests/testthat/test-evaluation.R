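test_that("confusion counts match their definitions", {
  expect_identical(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
                   c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_identical(confusionCounts(c(1, 0, 1), c(1, 0, 1)),
                   c(TP = 2L, FP = 0L, TN = 1L, FN = 0L))
  set.seed(201)
  y <- rbinom(97, 1, 0.4)
  k <- rbinom(97, 1, 0.5)
  expect_identical(sum(confusionCounts(y, k)), 97L)
  expect_error(confusionCounts(c(1, 0), c(1, 2)), "binary")
  expect_error(confusionCounts(c(1, 0), 1), "length")
})

test_that("worked confusion-metric examples evaluate exactly", {
  m <- classificationMetrics(c(TP = 50L, FP = 10L, TN = 40L, FN = 0L))
  expect_equal(m[["acc"]], 0.9)
  expect_equal(m[["sn"]], 1.0)
  expect_equal(m[["sp"]], 0.8)
  expect_equal(m[["mcc"]], sqrt(2 / 3), tolerance = 1e-12)

  m2 <- classificationMetrics(c(TP = 25L, FP = 25L, TN = 25L, FN = 25L))
  expect_equal(m2[["acc"]], 0.5)
  expect_equal(m2[["mcc"]], 0)

  m3 <- classificationMetrics(c(TP = 30L, FP = 0L, TN = 30L, FN = 0L))
  expect_equal(unname(m3), c(1, 1, 1, 1))

  # zero denominator completes MCC as 0
  m4 <- classificationMetrics(c(TP = 0L, FP = 0L, TN = 10L, FN = 5L))
  expect_equal(m4[["mcc"]], 0)
  expect_error(classificationMetrics(c(TP = 0L, FP = 0L, TN = 0L,
                                       FN = 0L)), "no evaluated")
})

test_that("metrics agree with an independent oracle on random tables", {
  set.seed(202)
  for (i in 1:1000) {
    cts <- as.integer(rmultinom(1, sample(4:400, 1), runif(4, 0.05, 1)))
    got <- classificationMetrics(c(TP = cts[1], FP = cts[2],
                                   TN = cts[3], FN = cts[4]))
    want <- oracleMetrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got[["acc"]], want[["acc"]], tolerance = 1e-12)
    expect_equal(got[["mcc"]], want[["mcc"]], tolerance = 1e-12)
    if (!is.na(want[["sn"]]))
      expect_equal(got[["sn"]], want[["sn"]], tolerance = 1e-12)
    if (!is.na(want[["sp"]]))
      expect_equal(got[["sp"]], want[["sp"]], tolerance = 1e-12)
  }
})

test_that("trapezoid ROC AUC equals the all-pairs probability", {
  # degenerate anchors
  expect_equal(rocAUC(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(rocAUC(c(1, 0), c(0, 1)), 0)

  set.seed(203)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    # discretized scores force ties
    s <- round(runif(n), sample(1:2, 1))
    expect_equal(rocAUC(y, s), oracleAUC(y, s), tolerance = 1e-12)
  }
  expect_error(rocAUC(rep(1, 5), runif(5)), "both classes")
})

test_that("precision-recall area matches exhaustive threshold enumeration", {
  expect_equal(prCurve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$area, 1.0)

  # hand-worked four-point instance: cuts at 0.9, 0.8, 0.7, 0.1 give
  # AP = 0.5 * 1 + 0 + 0.5 * (2/3) + 0 = 5/6
  y4 <- c(1, 0, 1, 0)
  s4 <- c(0.9, 0.8, 0.7, 0.1)
  pc <- prCurve(y4, s4)
  expect_equal(pc$area, 5 / 6, tolerance = 1e-12)
  expect_equal(pc$area, oracleAP(y4, s4), tolerance = 1e-12)
  expect_equal(pc$baseline, 0.5)
  expect_true(all(diff(pc$recall) >= 0))
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))

  set.seed(204)
  for (i in 1:20) {
    n <- sample(8:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) next
    s <- round(runif(n), 2)
    expect_equal(prCurve(y, s)$area, oracleAP(y, s), tolerance = 1e-12)
  }
})

test_that("a random scorer's AUPRC sits at the positive fraction", {
  set.seed(205)
  areas <- replicate(30, {
    y <- rep(c(1L, 0L), c(300, 1700))
    prCurve(y, runif(2000))$area
  })
  expect_lt(abs(mean(areas) - 0.15), 0.01)
})

test_that("the AUPRC baseline is the positive fraction", {
  expect_equal(baselineAUPRC(rep(c(1L, 0L), c(15, 85))), 0.15)
  expect_equal(baselineAUPRC(rep(c(1L, 0L), 50)), 0.5)
  ds <- simulateDataset(20, 60, seed = 1)
  expect_equal(baselineAUPRC(ds), 0.25)
  expect_error(baselineAUPRC(integer()), "empty")
})

test_that("evaluateScores assembles a coherent report", {
  set.seed(206)
  y <- rep(c(1L, 0L), 50)
  s <- ifelse(y == 1, runif(100, 0.4, 1), runif(100, 0, 0.6))
  rep <- evaluateScores(y, s)
  cts <- rep@counts
  expect_equal(rep@acc, (cts[["TP"]] + cts[["TN"]]) / sum(cts))
  expect_equal(rep@auc, rocAUC(y, s))
  expect_equal(rep@auprc, prCurve(y, s)$area)
  expect_equal(rep@baselineAUPRC, 0.5)
  expect_true(rep@mcc >= -1 && rep@mcc <= 1)
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(1L, 0L), 5)
  fold <- sixmApred:::.stratifiedFolds(y, 5L, seed = 301)
  expect_identical(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_identical(sum(fold == f), 2L)
    expect_identical(sum(fold == f & y == 1L), 1L)
  }

  # larger, unbalanced: per-fold class counts within 1 of each other
  set.seed(302)
  y2 <- rbinom(203, 1, 0.3)
  fold2 <- sixmApred:::.stratifiedFolds(y2, 5L, seed = 302)
  posPerFold <- table(fold2[y2 == 1])
  expect_lte(max(posPerFold) - min(posPerFold), 1)
  # disjoint cover
  expect_identical(length(fold2), 203L)
  expect_true(all(fold2 %in% 1:5))
})

test_that("class-ratio subsampling reproduces the printed split counts", {
  fv <- simulateDataset(1966, 1966, seed = 401, name = "fv")
  expect_identical(positiveCount(subsampleRatio(fv, 5)), 393L)
  expect_identical(negativeCount(subsampleRatio(fv, 5)), 1966L)
  expect_identical(positiveCount(subsampleRatio(fv, 10)), 196L)

  rc <- simulateDataset(813, 813, seed = 402, name = "rc")
  expect_identical(positiveCount(subsampleRatio(rc, 5)), 162L)
  expect_identical(positiveCount(subsampleRatio(rc, 10)), 81L)
  expect_identical(negativeCount(subsampleRatio(rc, 10)), 813L)

  # identity ratio keeps the counts
  expect_identical(positiveCount(subsampleRatio(rc, 1)), 813L)

  # reproducible under a fixed seed, different under another
  a <- subsampleRatio(rc, 5, seed = 7)
  b <- subsampleRatio(rc, 5, seed = 7)
  c <- subsampleRatio(rc, 5, seed = 8)
  expect_identical(as.character(sequences(a)), as.character(sequences(b)))
  expect_false(identical(as.character(sequences(a)),
                         as.character(sequences(c))))

  tiny <- simulateDataset(5, 5, seed = 403)
  expect_error(subsampleRatio(tiny, 10), "too few negatives")
  expect_error(subsampleRatio(rc, 0), ">= 1")
})

test_that("cross-validated pipeline learns the planted motif", {
  ds <- simulateDataset(250, 250, seed = 501)
  res <- kFoldCV(ds, k = 5L, seed = 501,
                 trainCfg = trainConfig(maxEpochs = 25L, batchSize = 128L))
  expect_s4_class(res, "CVResult")
  expect_length(res@folds, 5L)
  acc <- res@summary$mean[res@summary$metric == "acc"]
  expect_gte(acc, 0.95)
  expect_true(all(res@featureCounts > 0))
  # per-fold test sets are disjoint and cover the data: every index
  # appears in exactly one fold's confusion total
  expect_identical(sum(vapply(res@folds, function(r) sum(r@counts),
                              numeric(1))), 500)
  expect_error(kFoldCV(simulateDataset(3, 3, seed = 1), k = 5L),
               "at least 5")
})
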