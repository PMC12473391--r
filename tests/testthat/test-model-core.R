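# brute-force oracles for each layer primitive, plus the closed-form and
# shape contracts stated for them

bruteConv <- function(x, W, b) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Fout <- dim(W)[3]
  l <- nrow(x)
  padL <- (k - 1) %/% 2
  y <- matrix(0, l, Fout)
  for (f in seq_len(Fout))
    for (j in seq_len(l))
      for (o in seq_len(k)) {
        src <- j + o - 1 - padL
        if (src >= 1 && src <= l)
          y[j, f] <- y[j, f] + sum(x[src, ] * W[o, , f])
      }
  sweep(y, 2, b, "+")
}

test_that("conv layer matches a sliding dot-product oracle", {
  set.seed(10)
  for (trial in 1:20) {
    l <- sample(6:12, 1); Cin <- sample(1:3, 1); Fout <- sample(1:4, 1)
    k <- sample(seq(1, min(5, l), by = 2), 1)
    x <- matrix(rnorm(l * Cin), l, Cin)
    W <- array(rnorm(k * Cin * Fout), c(k, Cin, Fout))
    b <- rnorm(Fout)
    got <- conv1dBnRelu(x, list(W = W, b = b))
    expect_equal(got, pmax(bruteConv(x, W, b), 0), tolerance = 1e-6)
  }
  # identity kernel reduces to ReLU; averaging kernel preserves constants
  x <- matrix(rnorm(20), 20, 1)
  p1 <- list(W = array(1, c(1, 1, 1)), b = 0)
  expect_equal(conv1dBnRelu(x, p1), pmax(x, 0), ignore_attr = TRUE)
  xc <- matrix(2, 9, 1)
  p3 <- list(W = array(1 / 3, c(3, 1, 1)), b = 0)
  y3 <- conv1dBnRelu(xc, p3)
  expect_equal(y3[2:8, 1], rep(2, 7))
  expect_error(conv1dBnRelu(matrix(1, 2, 1), p3), "longer")
})

test_that("max pooling matches a loop oracle", {
  set.seed(11)
  expect_equal(maxPool(matrix(c(1, 3, 2, 5)), 2), matrix(c(3, 5)))
  expect_equal(maxPool(matrix(1, 8, 2), 4), matrix(1, 2, 2))
  for (trial in 1:20) {
    l <- sample(4:20, 1); C <- sample(1:3, 1); p <- sample(2:4, 1)
    x <- matrix(rnorm(l * C), l, C)
    got <- maxPool(x, p)
    lo <- l %/% p
    want <- sapply(seq_len(C), function(c)
      vapply(seq_len(lo), function(j) max(x[((j - 1) * p + 1):(j * p), c]), 0))
    expect_equal(got, matrix(want, lo, C))
  }
  expect_error(maxPool(matrix(1, 2, 1), 5), "pool")
})

test_that("positional encoding follows the sinusoidal closed form", {
  pe <- positionalEncoding(6, 8)
  expect_equal(pe[1, seq(1, 8, by = 2)], rep(0, 4))   # sin 0
  expect_equal(pe[1, seq(2, 8, by = 2)], rep(1, 4))   # cos 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 8)), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positionalEncoding(4, 7), "even")
})

test_that("scaled dot-product attention matches a naive softmax oracle", {
  set.seed(12)
  for (trial in 1:20) {
    l <- sample(2:6, 1); dk <- sample(2:8, 1); dv <- sample(2:8, 1)
    Q <- matrix(rnorm(4 * dk), 4, dk)
    K <- matrix(rnorm(l * dk), l, dk)
    V <- matrix(rnorm(l * dv), l, dv)
    at <- scaledDotProductAttention(Q, K, V)
    S <- Q %*% t(K) / sqrt(dk)
    W <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
    expect_equal(at$weights, matrix(W, 4, l), tolerance = 1e-6)
    expect_equal(at$output, W %*% V, tolerance = 1e-6)
    expect_equal(rowSums(at$weights), rep(1, 4), tolerance = 1e-6)
  }
  # singleton key: weight 1, output = V; identical keys: uniform weights
  at1 <- scaledDotProductAttention(matrix(rnorm(3), 1), matrix(rnorm(3), 1),
                                   matrix(5, 1, 1))
  expect_equal(at1$weights, matrix(1, 1, 1))
  expect_equal(at1$output, matrix(5, 1, 1))
  K2 <- matrix(1, 4, 2)[rep(1, 4), ]
  at2 <- scaledDotProductAttention(matrix(rnorm(2), 1), K2,
                                   matrix(rnorm(8), 4, 2))
  expect_equal(as.numeric(at2$weights), rep(0.25, 4))
  expect_error(scaledDotProductAttention(matrix(1, 1, 2), matrix(1, 2, 3),
                                         matrix(1, 2, 1)), "d_k")
})

mhaParams <- function(d, h, dk = d %/% h) {
  list(Wq = array(rnorm(d * dk * h), c(d, dk, h)),
       Wk = array(rnorm(d * dk * h), c(d, dk, h)),
       Wv = array(rnorm(d * dk * h), c(d, dk, h)),
       Wo = matrix(rnorm(h * dk * d), h * dk, d))
}

test_that("multi-head attention equals the per-head manual computation", {
  set.seed(13)
  for (trial in 1:20) {
    l <- sample(3:7, 1); h <- sample(c(1, 2), 1); d <- h * sample(2:4, 1)
    Z <- matrix(rnorm(l * d), l, d)
    p <- mhaParams(d, h)
    got <- multiHeadAttention(Z, p, h)
    heads <- lapply(seq_len(h), function(i)
      scaledDotProductAttention(Z %*% p$Wq[, , i], Z %*% p$Wk[, , i],
                                Z %*% p$Wv[, , i])$output)
    want <- do.call(cbind, heads) %*% p$Wo
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(dim(got), c(l, d))
  }
  # h = 1 with identity projections reduces to plain attention on Z
  d <- 4; Z <- matrix(rnorm(20), 5, d)
  pid <- list(Wq = array(diag(d), c(d, d, 1)), Wk = array(diag(d), c(d, d, 1)),
              Wv = array(diag(d), c(d, d, 1)), Wo = diag(d))
  expect_equal(multiHeadAttention(Z, pid, 1),
               scaledDotProductAttention(Z, Z, Z)$output,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(multiHeadAttention(Z, pid, 3), "divide")
})

test_that("feed-forward network is position-wise and matches matrix algebra", {
  set.seed(14)
  for (trial in 1:20) {
    l <- sample(2:6, 1); d <- sample(2:5, 1); dff <- sample(3:8, 1)
    x <- matrix(rnorm(l * d), l, d)
    p <- list(W1 = matrix(rnorm(d * dff), d, dff), b1 = rnorm(dff),
              W2 = matrix(rnorm(dff * d), dff, d), b2 = rnorm(d))
    want <- sweep(pmax(sweep(x %*% p$W1, 2, p$b1, "+"), 0) %*% p$W2,
                  2, p$b2, "+")
    expect_equal(feedForward(x, p), want, tolerance = 1e-12)
    # position-wise: changing one row changes only that output row
    x2 <- x; x2[1, ] <- x2[1, ] + 1
    dOut <- feedForward(x2, p) - feedForward(x, p)
    if (l > 1) expect_equal(dOut[-1, , drop = FALSE],
                            matrix(0, l - 1, d), tolerance = 1e-12)
  }
  # identity-extended weights with non-negative input pass through
  d <- 3
  pid <- list(W1 = diag(d), b1 = rep(0, d), W2 = diag(d), b2 = rep(0, d))
  xp <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(feedForward(xp, pid), xp)
  expect_error(feedForward(xp, list(W1 = diag(4), b1 = rep(0, 4),
                                    W2 = diag(4), b2 = rep(0, 4))),
               "shape")
})

test_that("encoder layer composes its sub-operations with post-norm", {
  set.seed(15)
  h <- 2; d <- 6; l <- 5
  Z <- matrix(rnorm(l * d), l, d)
  p <- list(mha = mhaParams(d, h), h = h,
            ffn = list(W1 = matrix(rnorm(d * 12), d, 12), b1 = rnorm(12),
                       W2 = matrix(rnorm(12 * d), 12, d), b2 = rnorm(d)),
            ln1 = list(gamma = runif(d, .5, 1.5), beta = rnorm(d)),
            ln2 = list(gamma = runif(d, .5, 1.5), beta = rnorm(d)))
  got <- encoderLayer(Z, p)
  zMid <- semscan:::layerNorm(Z + multiHeadAttention(Z, p$mha, h),
                              p$ln1$gamma, p$ln1$beta)
  want <- semscan:::layerNorm(zMid + feedForward(zMid, p$ffn),
                              p$ln2$gamma, p$ln2$beta)
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dim(got), dim(Z))
  # pre-scale-shift normalization: zero mean, unit variance per position
  pUnit <- p
  pUnit$ln2 <- list(gamma = rep(1, d), beta = rep(0, d))
  o <- encoderLayer(Z, pUnit)
  expect_equal(rowMeans(o), rep(0, l), tolerance = 1e-9)
  expect_equal(apply(o, 1, function(r) mean(r^2)), rep(1, l),
               tolerance = 1e-3)
  # attention weight rows are stochastic
  for (w in attr(got, "weights")) {
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, l), tolerance = 1e-6)
  }
})

test_that("global average pooling is a channel mean, permutation invariant", {
  expect_equal(globalAveragePool(matrix(c(1, 2, 3))), 2)
  expect_equal(globalAveragePool(matrix(5, 7, 3)), rep(5, 3))
  set.seed(16)
  for (trial in 1:20) {
    x <- matrix(rnorm(40), 10, 4)
    expect_equal(globalAveragePool(x), colMeans(x))
    expect_equal(globalAveragePool(x[sample(10), ]), globalAveragePool(x))
  }
  expect_error(globalAveragePool(matrix(numeric(0), 0, 3)), "empty")
})
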