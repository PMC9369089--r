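test_that("activation functions match their closed forms", {
  grid <- seq(-8, 8, by = 0.25)
  expect_equal(elu(grid), ifelse(grid > 0, grid, exp(grid) - 1),
               tolerance = 1e-12)
  expect_identical(elu(0), 0)
  expect_identical(elu(2.5), 2.5)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(-2, alpha = 0.5), 0.5 * (exp(-2) - 1),
               tolerance = 1e-12)
  expect_error(elu(1, alpha = -1), "positive")

  expect_equal(sigmoid(grid), 1 / (1 + exp(-grid)), tolerance = 1e-12)
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75, tolerance = 1e-12)
  expect_equal(sigmoid(grid) + sigmoid(-grid), rep(1, length(grid)),
               tolerance = 1e-12)
})

test_that("network construction follows the shape chain", {
  net <- buildNetwork(173L)
  expect_identical(dim(net@weights$Wc), c(7L, 64L))
  # valid padding: 173 - 7 + 1 = 167 positions, 64 channels
  expect_identical(dim(net@weights$W1), c(167L * 64L, 16L))
  expect_identical(dim(net@weights$W2), c(16L, 8L))
  expect_identical(dim(net@weights$W3), c(8L, 1L))

  # boundary: input length equal to the kernel gives one position
  tiny <- buildNetwork(7L)
  expect_identical(nrow(tiny@weights$W1), 64L)
  expect_error(buildNetwork(6L), "kernel")

  # parameter count is a pure function of input size and config
  expect_identical(parameterCount(buildNetwork(50L, seed = 1)),
                   parameterCount(buildNetwork(50L, seed = 999)))
  # identical seeds give identical weights
  expect_identical(buildNetwork(50L, seed = 4)@weights,
                   buildNetwork(50L, seed = 4)@weights)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  cfg <- convNetConfig(convFilters = 3L, kernelSize = 3L,
                       dense1Units = 4L, dense2Units = 3L)
  net <- buildNetwork(9L, cfg, seed = 2)
  X <- matrix(rnorm(6 * 9), 6)
  y <- c(1, 0, 1, 0, 1, 0)
  fw <- sixmApred:::.forward(net@weights, cfg, X, training = TRUE)
  w <- fw$weights
  g <- sixmApred:::.backward(w, cfg, X, y, fw)
  eps <- 1e-5
  for (nm in c("Wc", "bc", "gamma", "betaBN", "W1", "b1", "W2", "b2",
               "W3", "b3")) {
    set.seed(nchar(nm))
    idx <- sample(length(w[[nm]]), min(4L, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      lp <- sixmApred:::.bceLoss(
        sixmApred:::.forward(wp, cfg, X, training = TRUE)$p, y)
      lm_ <- sixmApred:::.bceLoss(
        sixmApred:::.forward(wm, cfg, X, training = TRUE)$p, y)
      numeric_g <- (lp - lm_) / (2 * eps)
      relerr <- abs(g[[nm]][i] - numeric_g) /
        max(1e-3, abs(g[[nm]][i]) + abs(numeric_g))
      expect_lt(relerr, 1e-4)
    }
  }
})

test_that("batch-norm running statistics follow the moving-average rule", {
  set.seed(43)
  cfg <- convNetConfig()
  net <- buildNetwork(20L, cfg, seed = 3)
  w <- net@weights
  w$runMean <- rnorm(64)
  w$runVar <- runif(64, 0.5, 2)
  X <- matrix(rnorm(8 * 20), 8)
  fw <- sixmApred:::.forward(w, cfg, X, training = TRUE)
  # recompute the convolution's batch statistics independently
  Z <- sixmApred:::.im2col(X, 7L) %*% w$Wc
  Z <- Z + rep(w$bc, each = nrow(Z))
  mu <- colMeans(Z)
  va <- colMeans(Z^2) - mu^2
  expect_equal(fw$weights$runMean, 0.8 * w$runMean + 0.2 * mu,
               tolerance = 1e-12)
  expect_equal(fw$weights$runVar, 0.8 * w$runVar + 0.2 * va,
               tolerance = 1e-12)
  # inference mode leaves the running statistics untouched
  fw2 <- sixmApred:::.forward(w, cfg, X, training = FALSE)
  expect_identical(fw2$weights$runMean, w$runMean)
})

test_that("training learns separable features and is reproducible", {
  set.seed(44)
  n <- 400L; d <- 24L
  y <- rep(c(1L, 0L), n / 2)
  X <- matrix(rnorm(n * d), n)
  X[, 5] <- X[, 5] + 4 * y  # strongly separated direction
  cfg <- trainConfig(maxEpochs = 30L, batchSize = 64L, seed = 9L)
  net <- buildNetwork(d, seed = 9L)
  m1 <- trainNetwork(net, X, y, cfg)
  m2 <- trainNetwork(net, X, y, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(predictProba(m1, X[1:20, ]), predictProba(m2, X[1:20, ]))

  # held-out performance on fresh draws from the same generator
  Xn <- matrix(rnorm(200 * d), 200)
  yn <- rep(c(1L, 0L), 100)
  Xn[, 5] <- Xn[, 5] + 4 * yn
  acc <- mean(classifyScores(predictProba(m1, Xn)) == yn)
  expect_gte(acc, 0.9)

  # scores are probabilities; identical rows get identical scores
  p <- predictProba(m1, Xn)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predictProba(m1, Xn[c(3, 3), ])[1],
                   predictProba(m1, Xn[c(3, 3), ])[2])

  # mean score separates the classes
  expect_gt(mean(p[yn == 1]), mean(p[yn == 0]))
})

test_that("early stopping halts within patience of the best epoch", {
  set.seed(45)
  n <- 200L; d <- 15L
  y <- rep(c(1L, 0L), n / 2)
  X <- matrix(rnorm(n * d), n)
  X[, 2] <- X[, 2] + 1.5 * y
  cfg <- trainConfig(maxEpochs = 50L, patience = 5L, batchSize = 64L,
                     seed = 11L)
  m <- trainNetwork(buildNetwork(d, seed = 11L), X, y, cfg)
  h <- trainingHistory(m)
  expect_lte(nrow(h), 50L)
  best <- which.max(h$valAccuracy)[1]
  expect_lte(nrow(h) - best, 5L)

  expect_error(trainNetwork(buildNetwork(d), X, rep(1L, n), cfg),
               "single class")
  expect_error(trainNetwork(buildNetwork(d), X[, 1:10], y, cfg),
               "columns")
})

test_that("thresholding calls follow the documented tie-break", {
  expect_identical(classifyScores(c(0.51, 0.49, 0.5)), c(1L, 0L, 1L))
  set.seed(46)
  s <- runif(50)
  lo <- classifyScores(s, 0.3)
  hi <- classifyScores(s, 0.7)
  # raising the threshold never converts a negative into a positive
  expect_true(all(hi <= lo))
  expect_error(classifyScores(c(0.2, 1.4)), "0,1")
})

test_that("model directories round-trip bit-stably", {
  set.seed(47)
  d <- 12L
  y <- rep(c(1L, 0L), 60)
  X <- matrix(rnorm(120 * d), 120)
  X[, 3] <- X[, 3] + 2 * y
  sel <- fitSelector(encodeDataset(simulateDataset(10, 10, seed = 3)),
                     classLabels(simulateDataset(10, 10, seed = 3)),
                     5, 5)
  m <- trainNetwork(buildNetwork(d, seed = 5L), X, y,
                    trainConfig(maxEpochs = 5L, batchSize = 32L,
                                seed = 5L))
  dir <- file.path(tempdir(), "mdl")
  saveModel(m, dir)
  back <- loadModel(dir)
  Xnew <- matrix(rnorm(100 * d), 100)
  expect_equal(predictProba(back, Xnew), predictProba(m, Xnew),
               tolerance = 1e-6)
  expect_identical(back@config, m@config)
  expect_equal(trainingHistory(back), trainingHistory(m),
               tolerance = 1e-6)

  # missing weight file is an error naming the file
  dir2 <- file.path(tempdir(), "mdl2")
  dir.create(dir2, showWarnings = FALSE)
  file.copy(file.path(dir, "config.json"), dir2)
  expect_error(loadModel(dir2), "weights.json")

  # a selector of mismatched dimensionality is rejected at load
  writeSelector(sel, file.path(dir, "selector.json"))
  if (nSelected(sel) != d) expect_error(loadModel(dir), "selector")
})
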