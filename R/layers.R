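# Layer primitives of the CNN-Transformer feature extractor, as pure
# per-sample functions on (length x channels) matrices. The batched
# training engine (engine.R) re-implements these with hand-derived
# gradients; tests assert the two routes agree.

#' Sinusoidal positional encoding
#'
#' Fixed encoding `PE(pos, 2i) = sin(pos / 10000^(2i/d))`,
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))`, positions starting at 0.
#'
#' @param l sequence length (>= 1).
#' @param d feature dimension (even, >= 2).
#' @return `l x d` matrix with entries in `[-1, 1]`.
#' @export
positionalEncoding <- function(l, d) {
  stopIfNot(l >= 1 && d >= 1, "l and d must be >= 1")
  stopIfNot(d %% 2 == 0, "d must be even")
  pos <- seq_len(l) - 1
  i <- seq_len(d %/% 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, l, d)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Convolution layer: 1D convolution, batch norm, ReLU
#'
#' Stride-1, same-padding cross-correlation of a multichannel sequence with
#' a bank of kernels, followed by batch normalization (inference mode:
#' running moments) and ReLU, in that order.
#'
#' @param x `l x C` input matrix (sequence length by channels).
#' @param params list with `W` (`k x C x F` kernel array), `b` (length-`F`
#'   bias) and optionally `bn`, a list with `gamma`, `beta`, `mean`, `var`,
#'   `eps` per filter (identity if missing).
#' @return `l x F` matrix.
#' @export
conv1dBnRelu <- function(x, params) {
  W <- params$W
  k <- dim(W)[1]; Cin <- dim(W)[2]; Fout <- dim(W)[3]
  stopIfNot(ncol(x) == Cin, "kernel width must equal input channel count")
  stopIfNot(k <= nrow(x), "kernel longer than sequence")
  l <- nrow(x)
  padL <- (k - 1) %/% 2
  y <- matrix(0, l, Fout)
  for (f in seq_len(Fout)) y[, f] <- params$b[f]
  for (o in seq_len(k)) {
    s <- o - 1 - padL                       # input offset for this tap
    j <- seq.int(max(1, 1 - s), min(l, l - s))
    if (!length(j)) next
    Wo <- matrix(W[o, , ], Cin, Fout)
    y[j, ] <- y[j, ] + x[j + s, , drop = FALSE] %*% Wo
  }
  if (!is.null(params$bn)) {
    bn <- params$bn
    eps <- bn$eps %||% 1e-5
    y <- sweep(sweep(y, 2, bn$mean, "-"), 2, sqrt(bn$var + eps), "/")
    y <- sweep(sweep(y, 2, bn$gamma, "*"), 2, bn$beta, "+")
  }
  pmax(y, 0)
}

#' Non-overlapping temporal max pooling
#'
#' @param x `l x C` matrix.
#' @param pool pool size (>= 1); output length is `floor(l / pool)`.
#' @return `floor(l/pool) x C` matrix of per-channel window maxima.
#' @export
maxPool <- function(x, pool) {
  stopIfNot(pool >= 1, "pool must be >= 1")
  stopIfNot(pool <= nrow(x), "pool larger than sequence")
  lOut <- nrow(x) %/% pool
  y <- x[seq.int(1, by = pool, length.out = lOut), , drop = FALSE]
  if (pool > 1)
    for (o in 2:pool)
      y <- pmax(y, x[seq.int(o, by = pool, length.out = lOut), , drop = FALSE])
  y
}

#' Scaled dot-product attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V` with max-subtraction softmax
#' stabilization; attention weight rows sum to one.
#'
#' @param Q,K,V query (`l_q x d_k`), key (`l x d_k`) and value (`l x d_v`)
#'   matrices; `K` and `V` must agree in length.
#' @return list with `output` (`l_q x d_v`) and `weights` (`l_q x l`).
#' @export
scaledDotProductAttention <- function(Q, K, V) {
  stopIfNot(ncol(Q) == ncol(K), "Q and K must share dimension d_k")
  stopIfNot(nrow(K) == nrow(V), "K and V must share length")
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  list(output = A %*% V, weights = A)
}

#' Multi-head attention
#'
#' Splits the model dimension over `h` heads, applies scaled dot-product
#' attention per head on learned projections, concatenates the heads and
#' projects back.
#'
#' @param Z `l x d` input sequence.
#' @param params list with arrays `Wq`, `Wk` (`d x d_k x h`), `Wv`
#'   (`d x d_v x h`) and matrix `Wo` (`h*d_v x d`).
#' @param h number of heads; must divide `d`.
#' @return `l x d` matrix. With `attr(, "weights")`: list of per-head
#'   `l x l` attention matrices.
#' @export
multiHeadAttention <- function(Z, params, h = 2) {
  d <- ncol(Z)
  stopIfNot(d %% h == 0,
            "configuration error: head count must divide the feature dimension")
  heads <- vector("list", h)
  weights <- vector("list", h)
  for (i in seq_len(h)) {
    at <- scaledDotProductAttention(Z %*% params$Wq[, , i],
                                    Z %*% params$Wk[, , i],
                                    Z %*% params$Wv[, , i])
    heads[[i]] <- at$output
    weights[[i]] <- at$weights
  }
  out <- do.call(cbind, heads) %*% params$Wo
  attr(out, "weights") <- weights
  out
}

#' Position-wise feed-forward network
#'
#' `max(0, x W1 + b1) W2 + b2`, applied independently at every position.
#'
#' @param x `l x d` matrix.
#' @param params list with `W1` (`d x d_ff`), `b1`, `W2` (`d_ff x d`), `b2`.
#' @return `l x d` matrix.
#' @export
feedForward <- function(x, params) {
  stopIfNot(ncol(x) == nrow(params$W1), "shape mismatch: x vs W1")
  stopIfNot(ncol(params$W1) == nrow(params$W2), "shape mismatch: W1 vs W2")
  h <- pmax(sweep(x %*% params$W1, 2, params$b1, "+"), 0)
  sweep(h %*% params$W2, 2, params$b2, "+")
}

# layer normalization over the feature dimension
layerNorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  xn <- (x - mu) / sqrt(v + eps)
  sweep(sweep(xn, 2, gamma, "*"), 2, beta, "+")
}

#' Transformer encoder layer
#'
#' Post-norm encoder layer: multi-head attention and feed-forward
#' sub-layers, each wrapped in a residual connection followed by layer
#' normalization over the feature dimension:
#' `Z_mid = LN(Z + MHA(Z))`, `O = LN(Z_mid + FFN(Z_mid))`.
#'
#' @param Z `l x d` input sequence.
#' @param params list with `mha` (see [multiHeadAttention()]), `ffn` (see
#'   [feedForward()]), `ln1`, `ln2` (each `gamma`, `beta`), and `h`.
#' @return `l x d` matrix; `attr(, "weights")` carries the per-head
#'   attention matrices.
#' @export
encoderLayer <- function(Z, params) {
  a <- multiHeadAttention(Z, params$mha, params$h)
  w <- attr(a, "weights")
  zMid <- layerNorm(Z + a, params$ln1$gamma, params$ln1$beta)
  o <- layerNorm(zMid + feedForward(zMid, params$ffn),
                 params$ln2$gamma, params$ln2$beta)
  attr(o, "weights") <- w
  o
}

#' Global average pooling over time
#'
#' @param x `l x d` matrix with `l >= 1`.
#' @return length-`d` vector of per-channel temporal means.
#' @export
globalAveragePool <- function(x) {
  stopIfNot(nrow(x) >= 1, "empty sequence")
  colMeans(x)
}
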