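test_that("class weights follow the inverse-frequency rule", {
  expect_equal(classWeights(c(50, 50)), c(1, 1))
  expect_equal(classWeights(c(20, 80)), c(2.5, 0.625))
  # frequency-weighted mean of weights is exactly 1 for any counts
  set.seed(20)
  for (trial in 1:50) {
    counts <- sample(1:500, sample(2:5, 1))
    w <- classWeights(counts)
    expect_equal(sum(counts / sum(counts) * w), 1, tolerance = 1e-12)
  }
  expect_error(classWeights(c(0, 10)), "zero-count")
})

test_that("weighted cross-entropy matches closed forms", {
  # perfect prediction -> zero loss
  expect_equal(weightedCrossEntropy(c(0, 1), c(0, 1), c(1, 1)), 0,
               tolerance = 1e-10)
  # uniform prediction of the true class 2 -> ln 2
  expect_equal(weightedCrossEntropy(c(0, 1), c(0.5, 0.5), c(1, 1)), log(2))
  # linear in the true-class weight
  l1 <- weightedCrossEntropy(c(0, 1), c(0.3, 0.7), c(1, 1))
  l2 <- weightedCrossEntropy(c(0, 1), c(0.3, 0.7), c(1, 2))
  expect_equal(l2, 2 * l1)
  # with unit weights equals the standard cross-entropy
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(2:20, 1)
    p <- matrix(runif(n * 2), n)
    p <- p / rowSums(p)
    y <- sample(0:1, n, replace = TRUE)
    Y <- cbind(1 - y, y)
    plain <- -mean(log(p[cbind(seq_len(n), y + 1)]))
    expect_equal(weightedCrossEntropy(Y, p, c(1, 1)), plain,
                 tolerance = 1e-12)
  }
  expect_error(weightedCrossEntropy(c(0, 1), c(0.6, 0.6), c(1, 1)),
               "normalized")
})

test_that("training separates a toy problem and is seed-reproducible", {
  ws <- toyWindowSet(n = 80, len = 40)
  tc <- trainConfig(max_epochs = 15, batch_size = 16, seed = 3)
  m <- fitModel(ws, config = tinyModelConfig(), tc = tc)
  expect_gte(max(m@history$train_acc), 0.99)
  # same seed -> identical first-epoch loss; different seed differs
  m2 <- fitModel(ws, config = tinyModelConfig(),
                 tc = trainConfig(max_epochs = 1, batch_size = 16, seed = 3))
  expect_equal(m2@history$train_loss[1], m@history$train_loss[1],
               tolerance = 1e-12)
  m3 <- fitModel(ws, config = tinyModelConfig(),
                 tc = trainConfig(max_epochs = 1, batch_size = 16, seed = 4))
  expect_false(isTRUE(all.equal(m3@history$train_loss[1],
                                m@history$train_loss[1])))
})

test_that("early stopping and LR schedule follow the configured patiences", {
  ws <- toyWindowSet(n = 60, len = 40)
  # tiny LR freezes validation accuracy: patience-10 stop by epoch 11
  tc <- trainConfig(max_epochs = 40, batch_size = 16, seed = 5,
                    initial_lr = 1e-12, min_lr = 1e-14)
  m <- fitModel(ws, config = tinyModelConfig(), tc = tc)
  expect_lte(nrow(m@history), 11)
  # LR is reduced by the configured factor after stagnant validation loss
  lrs <- unique(m@history$lr)
  if (length(lrs) > 1)
    expect_equal(lrs[2] / lrs[1], 0.2, tolerance = 1e-9)
  # restored weights correspond to the best validation accuracy epoch
  expect_equal(max(m@history$val_acc),
               m@history$val_acc[which.max(m@history$val_acc)])
})

test_that("training aborts cleanly when a class is missing", {
  ws <- toyWindowSet(n = 40, len = 40)
  ws$label <- rep(1L, 40)
  expect_error(fitModel(ws, config = tinyModelConfig(),
                        tc = trainConfig(max_epochs = 1, seed = 1)),
               "class-absence")
})

test_that("the hyperparameter grid enumerates the full factorial", {
  g <- kernelGrid("cnn_transformer")
  expect_equal(nrow(g), 81)
  expect_equal(sort(unique(g$k1)), c(50, 150, 250))
  gl <- kernelGrid("cnn_lstm")
  expect_equal(nrow(gl), 243)
  expect_true("units" %in% names(gl))
  # lexicographic ordering (tie-break order)
  expect_true(!is.unsorted(g$k1))
  first <- g[1, ]
  expect_equal(as.numeric(first), rep(50, 4))
  expect_error(kernelGrid(kernel_grid = numeric(0)), "empty")
})

test_that("grid search scores combinations by fold-mean accuracy", {
  ws <- toyWindowSet(n = 60, len = 40)
  sp <- chronologicalSplit(ws, n_folds = 3)
  sp$folds <- sp$folds
  grid <- data.frame(k1 = c(5, 3), k2 = 3, k3 = 5, k4 = 3)
  gs <- gridSearch(ws, sp, grid = grid,
                   config_base = tinyModelConfig(),
                   tc = trainConfig(max_epochs = 2, batch_size = 16, seed = 2))
  expect_equal(nrow(gs$table), 2)
  expect_true(all(is.finite(gs$table$mean_acc)))
  expect_true(gs$best$kernels[1] %in% c(5, 3))
  # restricted one-row grid returns that combination
  gs1 <- gridSearch(ws, sp, grid = grid[1, , drop = FALSE],
                    config_base = tinyModelConfig(),
                    tc = trainConfig(max_epochs = 1, batch_size = 16, seed = 2))
  expect_equal(gs1$best$kernels, as.integer(grid[1, ]))
})
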