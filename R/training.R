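#' Inverse-frequency class weights
#'
#' `w_i = N / (c * N_i)` for class counts `N_i`, total `N` and `c` classes:
#' minority classes receive proportionally higher loss weight, and the
#' frequency-weighted mean of the weights is exactly 1 for any counts.
#' Weights are computed on the training split only.
#'
#' @param class_counts positive per-class sample counts.
#' @return numeric weight per class.
#' @export
classWeights <- function(class_counts) {
  stopIfNot(all(class_counts > 0), "zero-count class: cannot weight")
  n <- sum(class_counts)
  c <- length(class_counts)
  n / (c * class_counts)
}

#' Weighted cross-entropy loss
#'
#' `L = -sum_i w_i y_i log(yhat_i)` per sample (one-hot `y`), averaged over
#' the batch; the log argument is clamped at `1e-12`. With unit weights this
#' is the standard cross-entropy.
#'
#' @param y_onehot `n x c` one-hot matrix (or length-`c` vector).
#' @param y_hat predicted probabilities, same shape; rows must sum to 1
#'   within `1e-3`.
#' @param weights length-`c` class weights.
#' @return scalar batch loss.
#' @export
weightedCrossEntropy <- function(y_onehot, y_hat, weights) {
  if (is.null(dim(y_hat))) {
    y_hat <- matrix(y_hat, 1)
    y_onehot <- matrix(y_onehot, 1)
  }
  if (any(abs(rowSums(y_hat) - 1) > 1e-3))
    stop("y_hat rows are not normalized probability vectors", call. = FALSE)
  per <- -rowSums(y_onehot * matrix(weights, nrow(y_hat), ncol(y_hat),
                                    byrow = TRUE) * log(pmax(y_hat, 1e-12)))
  mean(per)
}

#' Training configuration
#'
#' Optimization schedule for [fitModel()]: Adam with the stated betas,
#' initial learning rate 5e-4 reduced by a factor of 0.2 after `lr_patience`
#' epochs without validation-loss improvement (floored at `min_lr`),
#' minibatch size 128, and early stopping after `early_stop_patience` epochs
#' without validation-accuracy improvement with restoration of the
#' best-validation-accuracy weights.
#'
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param initial_lr initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param lr_reduce_factor multiplicative learning-rate decay.
#' @param lr_patience epochs of stagnant validation loss before decay.
#' @param min_lr learning-rate floor.
#' @param early_stop_patience epochs of stagnant validation accuracy before
#'   stopping.
#' @param val_frac chronological tail fraction of the training portion held
#'   out for validation.
#' @param seed RNG seed governing initialization, batch order and dropout.
#' @return configuration list of class `TrainConfig`.
#' @export
trainConfig <- function(max_epochs = 100, batch_size = 128,
                        initial_lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                        lr_reduce_factor = 0.2, lr_patience = 3,
                        min_lr = 1e-6, early_stop_patience = 10,
                        val_frac = 0.1, seed = 1L) {
  stopIfNot(lr_reduce_factor > 0 && lr_reduce_factor < 1,
            "lr_reduce_factor must lie in (0, 1)")
  stopIfNot(lr_patience >= 1 && early_stop_patience >= 1, "patiences must be >= 1")
  structure(list(max_epochs = max_epochs, batch_size = batch_size,
                 initial_lr = initial_lr, beta1 = beta1, beta2 = beta2,
                 lr_reduce_factor = lr_reduce_factor, lr_patience = lr_patience,
                 min_lr = min_lr, early_stop_patience = early_stop_patience,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "TrainConfig")
}

## ---- parameter-tree utilities ------------------------------------------

netTrainables <- function(net) {
  list(branches = lapply(net$branches, function(br)
    lapply(br, function(ly) ly$params)),
    head = net$head)
}

netSetTrainables <- function(net, tr) {
  for (b in 1:2)
    for (i in seq_along(net$branches[[b]]))
      if (!is.null(tr$branches[[b]][[i]]))
        net$branches[[b]][[i]]$params <- tr$branches[[b]][[i]]
  net$head <- tr$head
  net
}

treeZero <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, treeZero))
  p * 0
}

# one Adam update over aligned parameter/gradient/moment trees
adamUpdate <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-7) {
  rec <- function(p, g, m, v) {
    if (is.null(g) || is.null(p)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  # branches are unnamed lists: recurse positionally at the top levels
  for (b in 1:2) {
    for (i in seq_along(p$branches[[b]])) {
      if (is.null(g$branches[[b]][[i]])) next
      r <- rec(p$branches[[b]][[i]], g$branches[[b]][[i]],
               m$branches[[b]][[i]], v$branches[[b]][[i]])
      p$branches[[b]][[i]] <- r$p
      m$branches[[b]][[i]] <- r$m
      v$branches[[b]][[i]] <- r$v
    }
  }
  r <- rec(p$head, g$head, m$head, v$head)
  p$head <- r$p; m$head <- r$m; v$head <- r$v
  list(p = p, m = m, v = v)
}

netEvaluate <- function(net, ws, idx, cw, batch_size = 256) {
  probs <- matrix(0, length(idx), 2)
  for (start in seq.int(1, length(idx), by = batch_size)) {
    ii <- idx[start:min(start + batch_size - 1, length(idx))]
    tt <- wsTensors(ws, ii)
    probs[start:(start + length(ii) - 1), ] <-
      netForward(net, tt$X1, tt$X2, training = FALSE)$probs
  }
  y <- ws$label[idx]
  Y <- cbind(1 - y, y)
  list(probs = probs,
       loss = weightedCrossEntropy(Y, probs, cw),
       acc = mean(max.col(probs) - 1 == y))
}

#' Train a SEM classifier
#'
#' Minibatch Adam on the weighted cross-entropy, with the adaptive
#' learning-rate schedule and accuracy-monitored early stopping described
#' in [trainConfig()]. The chronological tail of the training portion is
#' held out for validation; class weights come from the remaining training
#' windows. The best-validation-accuracy weights are restored on stop.
#' A fixed seed makes the run (initialization, batch order, dropout)
#' exactly reproducible.
#'
#' @param ws a [SemWindowSet-class].
#' @param idx chronological indices of the training portion (default: all
#'   windows).
#' @param config a [modelConfig()].
#' @param tc a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return a trained [SemModel-class] with per-epoch `history`.
#' @export
fitModel <- function(ws, idx = NULL, config = modelConfig(),
                     tc = trainConfig(), verbose = FALSE) {
  idx <- idx %||% seq_len(ncol(ws))
  nVal <- max(1L, round(tc$val_frac * length(idx)))
  stopIfNot(nVal < length(idx), "training portion too small")
  trIdx <- idx[seq_len(length(idx) - nVal)]
  valIdx <- idx[seq.int(length(idx) - nVal + 1, length(idx))]
  counts <- tabulate(ws$label[trIdx] + 1L, nbins = 2L)
  if (any(counts == 0))
    stop("class-absence error: both classes required in the training split",
         call. = FALSE)
  cw <- classWeights(counts)

  withSeed(tc$seed, {
    net <- buildNetwork(config)
    tr <- netTrainables(net)
    m <- treeZero(tr); v <- treeZero(tr)
    lr <- tc$initial_lr
    t <- 0
    hist <- data.frame()
    best <- list(acc = -Inf, net = net, epoch = 0)
    bestValLoss <- Inf
    badAcc <- 0; badLoss <- 0

    for (epoch in seq_len(tc$max_epochs)) {
      # running BN moments restart each epoch: the cumulative batch-statistic
      # average then reflects the current weights, so inference-mode
      # validation is meaningful even after very few epochs
      for (b in 1:2)
        for (i in seq_along(net$branches[[b]]))
          if (net$branches[[b]][[i]]$type == "convbn") {
            d <- length(net$branches[[b]][[i]]$state$mean)
            net$branches[[b]][[i]]$state <-
              list(mean = numeric(d), var = rep(1, d), count = 0)
          }
      perm <- sample(length(trIdx))
      nb <- ceiling(length(perm) / tc$batch_size)
      epLoss <- 0; epAcc <- 0; epN <- 0
      for (bi in seq_len(nb)) {
        sel <- perm[seq.int((bi - 1) * tc$batch_size + 1,
                            min(bi * tc$batch_size, length(perm)))]
        tt <- wsTensors(ws, trIdx[sel])
        B <- length(sel)
        fw <- netForward(net, tt$X1, tt$X2, training = TRUE)
        net <- fw$net
        y <- tt$y
        Y <- cbind(1 - y, y)
        loss <- weightedCrossEntropy(Y, fw$probs, cw)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                       epoch, bi), call. = FALSE)
        epLoss <- epLoss + loss * B
        epAcc <- epAcc + sum(max.col(fw$probs) - 1 == y)
        epN <- epN + B
        dLogits <- (fw$probs - Y) * cw[y + 1] / B
        grads <- netBackward(net, fw, dLogits)
        t <- t + 1
        tr <- netTrainables(net)
        upd <- adamUpdate(tr, grads, m, v, lr, tc$beta1, tc$beta2, t)
        m <- upd$m; v <- upd$v
        net <- netSetTrainables(net, upd$p)
      }
      val <- netEvaluate(net, ws, valIdx, cw)
      hist <- rbind(hist, data.frame(
        epoch = epoch, lr = lr, train_loss = epLoss / epN,
        train_acc = epAcc / epN, val_loss = val$loss, val_acc = val$acc))
      if (verbose)
        message(sprintf("epoch %2d lr %.2g loss %.4f acc %.4f val_loss %.4f val_acc %.4f",
                        epoch, lr, epLoss / epN, epAcc / epN, val$loss, val$acc))
      if (val$acc > best$acc + 1e-12) {
        best <- list(acc = val$acc, net = net, epoch = epoch)
        badAcc <- 0
      } else badAcc <- badAcc + 1
      if (val$loss < bestValLoss - 1e-12) {
        bestValLoss <- val$loss
        badLoss <- 0
      } else badLoss <- badLoss + 1
      if (badLoss >= tc$lr_patience) {
        lr <- max(lr * tc$lr_reduce_factor, tc$min_lr)
        badLoss <- 0
      }
      if (badAcc >= tc$early_stop_patience) break
    }
    methods::new("SemModel", config = unclass(config), params = best$net,
                 trainConfig = unclass(tc), history = hist,
                 classWeights = cw)
  })
}

#' Enumerate the hyperparameter grid
#'
#' All kernel four-tuples for the two convolution layers of each branch
#' (3^4 = 81 combinations at the default grid), crossed with the LSTM unit
#' grid for LSTM variants (243 combinations). Rows are in lexicographic
#' order, which is also the tie-breaking order of [gridSearch()].
#'
#' @param variant architecture name (see [modelConfig()]).
#' @param kernel_grid candidate kernel lengths.
#' @param lstm_grid candidate LSTM unit counts.
#' @return data.frame with columns `k1..k4` (and `units` for LSTM variants).
#' @export
kernelGrid <- function(variant = "cnn_transformer",
                       kernel_grid = c(50, 150, 250),
                       lstm_grid = c(50, 100, 150)) {
  stopIfNot(length(kernel_grid) >= 1, "empty grid")
  g <- expand.grid(k1 = kernel_grid, k2 = kernel_grid, k3 = kernel_grid,
                   k4 = kernel_grid, KEEP.OUT.ATTRS = FALSE)
  if (variant %in% c("cnn_lstm", "cnn_lstm_attn")) {
    stopIfNot(length(lstm_grid) >= 1, "empty LSTM grid")
    g <- merge(g, data.frame(units = lstm_grid))
  }
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Grid search with contiguous five-fold cross-validation
#'
#' Evaluates every kernel (and LSTM unit) combination by training on four
#' contiguous folds of the training portion and validating on the held-out
#' fold, scoring by mean validation accuracy. Ties go to the
#' lexicographically smallest tuple.
#'
#' @param ws a [SemWindowSet-class].
#' @param split a [chronologicalSplit()] result.
#' @param variant architecture name.
#' @param grid combination table (default [kernelGrid()]); restrict it to
#'   keep runtimes small.
#' @param config_base base [modelConfig()] whose kernels/units the grid
#'   overrides.
#' @param tc a [trainConfig()] used for every fold fit.
#' @return list with `best` (a `ModelConfig`) and `table` (per-combination
#'   mean and SD of validation accuracy and F1).
#' @export
gridSearch <- function(ws, split, variant = "cnn_transformer",
                       grid = kernelGrid(variant),
                       config_base = modelConfig(variant),
                       tc = trainConfig()) {
  stopIfNot(nrow(grid) >= 1, "empty grid")
  res <- grid
  res$mean_acc <- NA_real_; res$sd_acc <- NA_real_
  res$mean_f1 <- NA_real_; res$sd_f1 <- NA_real_
  for (ci in seq_len(nrow(grid))) {
    cfg <- config_base
    cfg$kernels <- as.integer(grid[ci, c("k1", "k2", "k3", "k4")])
    if ("units" %in% names(grid)) cfg$lstm_units <- as.integer(grid$units[ci])
    accs <- f1s <- numeric(length(split$folds))
    for (fi in seq_along(split$folds)) {
      hold <- split$folds[[fi]]
      tri <- setdiff(split$train, hold)
      model <- fitModel(ws, tri, cfg, tc)
      probs <- predictProb(model, ws, hold)
      rep <- confusionMetrics(ws$label[hold], max.col(probs) - 1L)
      accs[fi] <- rep$accuracy
      f1s[fi] <- rep$f1
    }
    res$mean_acc[ci] <- mean(accs); res$sd_acc[ci] <- sd(accs)
    res$mean_f1[ci] <- mean(f1s); res$sd_f1[ci] <- sd(f1s)
  }
  bi <- which.max(res$mean_acc)   # first max = lexicographically smallest
  best <- config_base
  best$kernels <- as.integer(res[bi, c("k1", "k2", "k3", "k4")])
  if ("units" %in% names(res)) best$lstm_units <- as.integer(res$units[bi])
  class(best) <- "ModelConfig"
  list(best = best, table = res)
}
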