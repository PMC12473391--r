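#' Model configuration
#'
#' Describes one of the parallel two-branch architectures. All variants
#' share the input contract (two 500-sample modality vectors) and output
#' contract (two-class probabilities): the full CNN-Transformer, a
#' CNN-only baseline (convolution module straight into global average
#' pooling), CNN-LSTM (LSTM sequence modeling after the convolution
#' module, then GAP), and CNN-LSTM with additive attention pooling.
#' Ablation flags remove components from the full model: the Transformer
#' encoder, the convolution module (replaced by a per-timestep linear
#' embedding so the encoder still receives `d_model` features), residual
#' connections, or the feed-forward sub-layers.
#'
#' @param variant architecture: `"cnn_transformer"` (full parallel
#'   bimodal model), `"cnn"`, `"cnn_lstm"`, `"cnn_lstm_attn"`.
#' @param kernels integer vector `(k1, k2, k3, k4)`: conv kernel lengths for
#'   branch 1 (layers 1-2) and branch 2 (layers 3-4); grid-search values
#'   come from \{50, 150, 250\}.
#' @param d_model feature dimension (conv filter count = encoder width).
#' @param heads attention heads; must divide `d_model`.
#' @param n_layers encoder layers.
#' @param d_ff feed-forward inner dimension.
#' @param pool max-pool size after the convolution module.
#' @param lstm_units LSTM width (LSTM variants only), grid \{50, 100, 150\}.
#' @param dropout dropout rate in the classifier head.
#' @param fc1 width of the first fully connected layer.
#' @param no_transformer,no_cnn,no_residual,no_ffn ablation flags
#'   (`"cnn_transformer"` variant only).
#' @return validated configuration list of class `ModelConfig`.
#' @export
modelConfig <- function(variant = c("cnn_transformer", "cnn", "cnn_lstm",
                                    "cnn_lstm_attn"),
                        kernels = c(50, 50, 50, 50),
                        d_model = 64, heads = 2, n_layers = 2, d_ff = 128,
                        pool = 4, lstm_units = 100, dropout = 0.5, fc1 = 64,
                        no_transformer = FALSE, no_cnn = FALSE,
                        no_residual = FALSE, no_ffn = FALSE) {
  variant <- match.arg(variant)
  stopIfNot(length(kernels) == 4 && all(kernels >= 1),
            "kernels must be four positive lengths")
  stopIfNot(d_model %% heads == 0,
            "configuration error: heads must divide d_model")
  if (no_transformer && no_cnn)
    stop("inconsistent ablation flags: cannot remove both the convolution ",
         "module and the Transformer", call. = FALSE)
  if (variant != "cnn_transformer" &&
      (no_transformer || no_cnn || no_residual || no_ffn))
    stop("ablation flags apply to the cnn_transformer variant only",
         call. = FALSE)
  cfg <- list(variant = variant, kernels = as.integer(kernels),
              d_model = as.integer(d_model), heads = as.integer(heads),
              n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
              pool = as.integer(pool), lstm_units = as.integer(lstm_units),
              dropout = dropout, fc1 = as.integer(fc1),
              no_transformer = no_transformer, no_cnn = no_cnn,
              no_residual = no_residual, no_ffn = no_ffn)
  class(cfg) <- "ModelConfig"
  cfg
}

branchKind <- function(cfg) {
  if (cfg$variant == "cnn" ||
      (cfg$variant == "cnn_transformer" && cfg$no_transformer)) "cnn"
  else if (cfg$variant == "cnn_lstm") "lstm"
  else if (cfg$variant == "cnn_lstm_attn") "lstm_attn"
  else "transformer"
}

branchOutDim <- function(cfg) {
  if (branchKind(cfg) %in% c("lstm", "lstm_attn")) cfg$lstm_units
  else cfg$d_model
}

buildBranch <- function(cfg, ka, kb) {
  d <- cfg$d_model
  layers <- list()
  if (cfg$variant == "cnn_transformer" && cfg$no_cnn) {
    # per-timestep linear embedding so the encoder still sees d features
    layers <- c(layers, list(list(type = "convbn", params = convInit(1, 1, d),
                                  state = list(mean = numeric(d), var = rep(1, d), count = 0))))
  } else {
    layers <- c(layers,
                list(list(type = "convbn", params = convInit(ka, 1, d),
                          state = list(mean = numeric(d), var = rep(1, d), count = 0)),
                     list(type = "convbn", params = convInit(kb, d, d),
                          state = list(mean = numeric(d), var = rep(1, d), count = 0))))
  }
  layers <- c(layers, list(list(type = "pool", pool = cfg$pool)))
  kind <- branchKind(cfg)
  if (kind == "transformer") {
    layers <- c(layers, list(list(type = "addpe")))
    for (i in seq_len(cfg$n_layers))
      layers <- c(layers, list(list(
        type = "encoder",
        params = encInit(d, cfg$heads, cfg$d_ff, no_ffn = cfg$no_ffn))))
    layers <- c(layers, list(list(type = "gap")))
  } else if (kind == "cnn") {
    layers <- c(layers, list(list(type = "gap")))
  } else {
    layers <- c(layers, list(list(type = "lstm",
                                  params = lstmInit(d, cfg$lstm_units))))
    if (kind == "lstm")
      layers <- c(layers, list(list(type = "gap")))
    else
      layers <- c(layers, list(list(type = "attnpool",
                                    params = attnPoolInit(cfg$lstm_units))))
  }
  layers
}

buildNetwork <- function(cfg, seed = NULL) {
  withSeed(seed, {
    fin <- 2 * branchOutDim(cfg)
    net <- list(
      config = cfg,
      branches = list(buildBranch(cfg, cfg$kernels[1], cfg$kernels[2]),
                      buildBranch(cfg, cfg$kernels[3], cfg$kernels[4])),
      head = list(
        fc1 = list(W = matrix(glorot(fin, cfg$fc1, c(fin, cfg$fc1)),
                              fin, cfg$fc1),
                   b = numeric(cfg$fc1)),
        fc2 = list(W = matrix(glorot(cfg$fc1, 2, c(cfg$fc1, 2)), cfg$fc1, 2),
                   b = numeric(2)))
    )
    net
  })
}

branchForward <- function(layers, X, cfg, training, record = FALSE) {
  caches <- vector("list", length(layers))
  attn <- list()
  newLayers <- layers
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "convbn") {
      fw <- convbnForward(X, ly$params, ly$state, training)
      newLayers[[i]]$state <- fw$state
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$type == "pool") {
      fw <- poolForward(X, ly$pool)
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$type == "addpe") {
      L <- dim(X)[1]; B <- dim(X)[2]; d <- dim(X)[3]
      pe <- positionalEncoding(L, d)[rep(seq_len(L), B), ]
      dim(pe) <- c(L, B, d)
      X <- X + pe
      caches[[i]] <- NULL
    } else if (ly$type == "encoder") {
      fw <- encForward(X, ly$params, cfg$heads,
                       no_residual = cfg$no_residual, no_ffn = cfg$no_ffn,
                       keepCache = training, keepA = training || record)
      X <- fw$out
      caches[[i]] <- fw$cache
      if (record) attn[[length(attn) + 1]] <- fw$cache$attW
    } else if (ly$type == "lstm") {
      fw <- lstmForward(X, ly$params)
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$type == "gap") {
      fw <- gapForward(X)
      X <- fw$out
      caches[[i]] <- fw$cache
    } else if (ly$type == "attnpool") {
      fw <- attnPoolForward(X, ly$params)
      X <- fw$out
      caches[[i]] <- fw$cache
    }
  }
  list(out = X, caches = caches, layers = newLayers, attn = attn)
}

branchBackward <- function(layers, caches, dOut, cfg) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "convbn") {
      bk <- convbnBackward(d, ly$params, caches[[i]])
      d <- bk$dX
      grads[[i]] <- bk$grads
    } else if (ly$type == "pool") {
      d <- poolBackward(d, caches[[i]])
    } else if (ly$type == "addpe") {
      # identity gradient
    } else if (ly$type == "encoder") {
      bk <- encBackward(d, ly$params, caches[[i]], cfg$heads,
                        no_residual = cfg$no_residual, no_ffn = cfg$no_ffn)
      d <- bk$dX
      grads[[i]] <- bk$grads
    } else if (ly$type == "lstm") {
      bk <- lstmBackward(d, ly$params, caches[[i]])
      d <- bk$dX
      grads[[i]] <- bk$grads
    } else if (ly$type == "gap") {
      d <- gapBackward(d, caches[[i]])
    } else if (ly$type == "attnpool") {
      bk <- attnPoolBackward(d, ly$params, caches[[i]])
      d <- bk$dX
      grads[[i]] <- bk$grads
    }
  }
  grads
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full network forward; X1, X2 are (500, B, 1) arrays
netForward <- function(net, X1, X2, training = FALSE, record = FALSE) {
  cfg <- net$config
  L <- dim(X1)[1]
  if (!identical(dim(X1), dim(X2)))
    stop("shape error: the two modality tensors must agree", call. = FALSE)
  if (L < max(cfg$kernels) || L %% cfg$pool != 0)
    stop(sprintf(paste0("shape error: input length %d incompatible with ",
                        "kernels (max %d) and pool %d"),
                 L, max(cfg$kernels), cfg$pool), call. = FALSE)
  b1 <- branchForward(net$branches[[1]], X1, cfg, training, record)
  b2 <- branchForward(net$branches[[2]], X2, cfg, training, record)
  feat <- cbind(b1$out, b2$out)
  a1 <- pmax(sweep(feat %*% net$head$fc1$W, 2, net$head$fc1$b, "+"), 0)
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(runif(length(a1)) < keep, nrow(a1), ncol(a1)) / keep
  } else mask <- NULL
  aDrop <- if (is.null(mask)) a1 else a1 * mask
  logits <- sweep(aDrop %*% net$head$fc2$W, 2, net$head$fc2$b, "+")
  probs <- softmaxRows(logits)
  net$branches[[1]] <- b1$layers   # carries updated batch-norm moments
  net$branches[[2]] <- b2$layers
  list(probs = probs, logits = logits,
       cache = list(b1 = b1, b2 = b2, feat = feat, a1 = a1, mask = mask,
                    aDrop = aDrop),
       net = net,
       attn = list(branch1 = b1$attn, branch2 = b2$attn))
}

netBackward <- function(net, fwd, dLogits) {
  cc <- fwd$cache
  gW2 <- crossprod(cc$aDrop, dLogits)
  gb2 <- colSums(dLogits)
  dADrop <- dLogits %*% t(net$head$fc2$W)
  dA1 <- if (is.null(cc$mask)) dADrop else dADrop * cc$mask
  dA1[cc$a1 <= 0] <- 0
  gW1 <- crossprod(cc$feat, dA1)
  gb1 <- colSums(dA1)
  dFeat <- dA1 %*% t(net$head$fc1$W)
  p <- ncol(cc$b1$out)
  d1 <- dFeat[, seq_len(p), drop = FALSE]
  d2 <- dFeat[, p + seq_len(ncol(cc$b2$out)), drop = FALSE]
  list(
    branches = list(
      branchBackward(net$branches[[1]], cc$b1$caches, d1, net$config),
      branchBackward(net$branches[[2]], cc$b2$caches, d2, net$config)),
    head = list(fc1 = list(W = gW1, b = gb1), fc2 = list(W = gW2, b = gb2))
  )
}

#' Number of trainable parameters in a model or network
#'
#' @param x a [SemModel-class] (or internal network list).
#' @return integer parameter count.
#' @export
countParams <- function(x) {
  net <- if (methods::is(x, "SemModel")) x@params else x
  n <- 0L
  addTree <- function(t) {
    if (is.list(t)) for (el in t) addTree(el)
    else if (is.numeric(t)) n <<- n + length(t)
  }
  for (br in net$branches)
    for (ly in br) if (!is.null(ly$params)) addTree(ly$params)
  addTree(net$head)
  n
}

# convert window-set columns to (L, B, 1) arrays
wsTensors <- function(ws, idx) {
  x1 <- SummarizedExperiment::assay(ws, "x1")[, idx, drop = FALSE]
  x2 <- SummarizedExperiment::assay(ws, "x2")[, idx, drop = FALSE]
  list(X1 = array(x1, c(nrow(x1), ncol(x1), 1)),
       X2 = array(x2, c(nrow(x2), ncol(x2), 1)),
       y = ws$label[idx])
}

#' Class probabilities for window samples
#'
#' Deterministic inference-mode forward pass (batch normalization uses
#' running moments; dropout off). Per-sample outputs are independent of
#' batch composition.
#'
#' @param model a trained [SemModel-class].
#' @param ws a [SemWindowSet-class].
#' @param idx window indices (default: all).
#' @param batch_size forward batch size.
#' @return `length(idx) x 2` matrix of class probabilities
#'   (columns: non-SEM, SEM).
#' @export
predictProb <- function(model, ws, idx = seq_len(ncol(ws)), batch_size = 256) {
  net <- model@params
  out <- matrix(0, length(idx), 2)
  for (start in seq.int(1, length(idx), by = batch_size)) {
    ii <- idx[start:min(start + batch_size - 1, length(idx))]
    tt <- wsTensors(ws, ii)
    fw <- netForward(net, tt$X1, tt$X2, training = FALSE)
    out[start:(start + length(ii) - 1), ] <- fw$probs
  }
  colnames(out) <- c("NONSEM", "SEM")
  out
}
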