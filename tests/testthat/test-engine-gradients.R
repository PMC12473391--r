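# Correctness of the batched training engine: the compiled float32 conv
# block is checked against a double-precision reference implementation of
# the same mathematics, and every double-precision layer is checked against
# central finite differences.

refill <- function(skel, values) {   # dim-preserving relist
  pos <- 0
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    out <- values[pos + seq_along(t)]
    pos <<- pos + length(t)
    if (!is.null(dim(t))) dim(out) <- dim(t)
    out
  }
  rec(skel)
}

numGrad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, 0)
}

test_that("fused conv+BN+ReLU matches a double-precision reference", {
  set.seed(4)
  refForward <- function(X, W, b, gamma, beta, eps = 1e-5) {
    L <- dim(X)[1]; B <- dim(X)[2]
    k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
    padL <- (k - 1) %/% 2
    Xm <- X; dim(Xm) <- c(L * B, cin)
    Ym <- matrix(rep(b, each = L * B), L * B, cout)
    for (o in 1:k) {
      s <- o - 1 - padL
      j0 <- max(1, 1 - s); j1 <- min(L, L - s)
      jo <- as.vector(outer(j0:j1, (0:(B - 1)) * L, "+"))
      Ym[jo, ] <- Ym[jo, ] + Xm[jo + s, , drop = FALSE] %*%
        matrix(W[o, , ], cin, cout)
    }
    mu <- colMeans(Ym); v <- colMeans(Ym^2) - mu^2
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(Ym, 2, mu), 2, invstd, "*")
    act <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    relu <- act > 0; act[!relu] <- 0
    list(act = act, xhat = xhat, invstd = invstd, relu = relu, Xm = Xm,
         L = L, B = B)
  }
  refBackward <- function(dY, W, gamma, cc) {
    k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
    padL <- (k - 1) %/% 2
    dA <- dY; dA[!cc$relu] <- 0
    dGamma <- colSums(dA * cc$xhat); dBeta <- colSums(dA)
    dXhat <- sweep(dA, 2, gamma, "*")
    N <- nrow(dA)
    dYm <- sweep(dXhat - matrix(colMeans(dXhat), N, cout, byrow = TRUE) -
                   sweep(cc$xhat, 2, colMeans(dXhat * cc$xhat), "*"),
                 2, cc$invstd, "*")
    dXm <- matrix(0, N, cin); dW <- array(0, dim(W))
    for (o in 1:k) {
      s <- o - 1 - padL
      j0 <- max(1, 1 - s); j1 <- min(cc$L, cc$L - s)
      jo <- as.vector(outer(j0:j1, (0:(cc$B - 1)) * cc$L, "+"))
      dYo <- dYm[jo, , drop = FALSE]
      dXm[jo + s, ] <- dXm[jo + s, ] + dYo %*% t(matrix(W[o, , ], cin, cout))
      dW[o, , ] <- crossprod(cc$Xm[jo + s, , drop = FALSE], dYo)
    }
    list(dX = dXm, dW = dW, db = colSums(dYm), dGamma = dGamma,
         dBeta = dBeta)
  }
  for (trial in 1:5) {
    L <- sample(20:50, 1); B <- sample(2:6, 1)
    cin <- sample(1:4, 1); cout <- sample(2:5, 1)
    k <- sample(c(3, 5, 8), 1)
    X <- array(rnorm(L * B * cin), c(L, B, cin))
    W <- array(rnorm(k * cin * cout) * 0.3, c(k, cin, cout))
    b <- rnorm(cout); gamma <- runif(cout, .5, 1.5); beta <- rnorm(cout)
    ref <- refForward(X, W, b, gamma, beta)
    layer <- list(W = W, b = b, gamma = gamma, beta = beta)
    st <- list(mean = numeric(cout), var = rep(1, cout), count = 0)
    fw <- semscan:::convbnForward(X, layer, st, training = TRUE)
    expect_equal(as.numeric(fw$out), as.numeric(ref$act), tolerance = 1e-4)
    dY <- array(rnorm(L * B * cout), c(L, B, cout))
    dYm <- dY; dim(dYm) <- c(L * B, cout)
    rb <- refBackward(dYm, W, gamma, ref)
    cb <- semscan:::convbnBackward(dY, layer, fw$cache)
    expect_equal(as.numeric(cb$dX), as.numeric(rb$dX), tolerance = 1e-4)
    expect_equal(as.numeric(cb$grads$W), as.numeric(rb$dW), tolerance = 1e-4)
    expect_equal(cb$grads$b, rb$db, tolerance = 1e-4)
    expect_equal(cb$grads$gamma, rb$dGamma, tolerance = 1e-4)
    expect_equal(cb$grads$beta, rb$dBeta, tolerance = 1e-4)
  }
})

test_that("encoder layer gradients match finite differences", {
  set.seed(5)
  L <- 6; B <- 3; d <- 4; h <- 2
  p <- semscan:::encInit(d, h, 8)
  X <- array(rnorm(L * B * d), c(L, B, d))
  tgt <- array(rnorm(L * B * d), c(L, B, d))
  lossOf <- function(p) {
    out <- semscan:::encForward(X, p, h)$out
    sum((out - tgt)^2) / 2
  }
  fw <- semscan:::encForward(X, p, h)
  bk <- semscan:::encBackward(fw$out - tgt, p, fw$cache, h)
  flat <- unlist(p)
  sel <- sample(length(flat), 25)
  gFlat <- unlist(bk$grads[names(p)])
  ng <- numGrad(function(v) {
    f2 <- flat; f2[sel] <- v
    lossOf(refill(p, f2))
  }, flat[sel])
  expect_equal(gFlat[sel], ng, tolerance = 1e-5, ignore_attr = TRUE)
  # input gradient
  xsel <- sample(length(X), 15)
  ngx <- numGrad(function(v) {
    X2 <- X; X2[xsel] <- v
    out <- semscan:::encForward(X2, p, h)$out
    sum((out - tgt)^2) / 2
  }, X[xsel])
  expect_equal(as.numeric(bk$dX)[xsel], ngx, tolerance = 1e-5)
})

test_that("LSTM and attention-pool gradients match finite differences", {
  set.seed(6)
  L <- 7; B <- 3; cin <- 4; u <- 5
  X <- array(rnorm(L * B * cin), c(L, B, cin))
  p <- semscan:::lstmInit(cin, u)
  tgt <- array(rnorm(L * B * u), c(L, B, u))
  fw <- semscan:::lstmForward(X, p)
  bk <- semscan:::lstmBackward(fw$out - tgt, p, fw$cache)
  flat <- unlist(p)
  sel <- sample(length(flat), 20)
  ng <- numGrad(function(v) {
    p2 <- utils::relist(replace(flat, sel, v), p)
    p2 <- list(Wx = matrix(p2$Wx, cin, 4 * u), Wh = matrix(p2$Wh, u, 4 * u),
               b = as.numeric(p2$b))
    sum((semscan:::lstmForward(X, p2)$out - tgt)^2) / 2
  }, flat[sel])
  expect_equal(unlist(bk$grads)[sel], ng, tolerance = 1e-5,
               ignore_attr = TRUE)

  pa <- semscan:::attnPoolInit(u, a = 4)
  H <- array(rnorm(L * B * u), c(L, B, u))
  tgt2 <- matrix(rnorm(B * u), B, u)
  fa <- semscan:::attnPoolForward(H, pa)
  ba <- semscan:::attnPoolBackward(fa$out - tgt2, pa, fa$cache)
  flata <- unlist(pa)
  sela <- sample(length(flata), 15)
  nga <- numGrad(function(v) {
    p2 <- utils::relist(replace(flata, sela, v), pa)
    p2 <- list(Wa = matrix(p2$Wa, u, 4), ba = as.numeric(p2$ba),
               va = as.numeric(p2$va))
    sum((semscan:::attnPoolForward(H, p2)$out - tgt2)^2) / 2
  }, flata[sela])
  expect_equal(unlist(ba$grads)[sela], nga, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("whole-network gradients match finite differences through the head", {
  # double-precision layers only are perturbed (the conv block is covered
  # by its reference test above)
  set.seed(7)
  cfg <- tinyModelConfig()
  net <- semscan:::buildNetwork(cfg, seed = 3)
  L <- 12; B <- 3
  X1 <- array(rnorm(L * B), c(L, B, 1))
  X2 <- array(rnorm(L * B), c(L, B, 1))
  y <- c(0, 1, 1); Y <- cbind(1 - y, y); cw <- c(1.2, 0.9)
  lossOf <- function(net) {
    fw <- semscan:::netForward(net, X1, X2, training = TRUE)
    weightedCrossEntropy(Y, fw$probs, cw)
  }
  fw <- semscan:::netForward(net, X1, X2, training = TRUE)
  dLogits <- (fw$probs - Y) * cw[y + 1] / B
  gr <- semscan:::netBackward(net, fw, dLogits)
  # head weights
  for (nm in c("fc1", "fc2")) {
    p0 <- net$head[[nm]]$W
    sel <- sample(length(p0), 6)
    ng <- numGrad(function(v) {
      n2 <- net
      n2$head[[nm]]$W[sel] <- v
      lossOf(n2)
    }, p0[sel])
    expect_equal(gr$head[[nm]]$W[sel], ng, tolerance = 1e-4)
  }
  # an encoder-layer FFN weight inside branch 1
  encIdx <- which(vapply(net$branches[[1]], `[[`, "", "type") == "encoder")[1]
  W1 <- net$branches[[1]][[encIdx]]$params$ffn$W1
  sel <- sample(length(W1), 6)
  ng <- numGrad(function(v) {
    n2 <- net
    n2$branches[[1]][[encIdx]]$params$ffn$W1[sel] <- v
    lossOf(n2)
  }, W1[sel])
  expect_equal(gr$branches[[1]][[encIdx]]$ffn$W1[sel], ng, tolerance = 1e-3)
})

test_that("batched forward agrees with the pure per-sample layer functions", {
  set.seed(8)
  L <- 16; B <- 4; d <- 4; h <- 2
  X <- array(rnorm(L * B * d), c(L, B, d))
  p <- semscan:::encInit(d, h, 8)
  batched <- semscan:::encForward(X, p, h)$out
  for (b in seq_len(B)) {
    Zb <- matrix(X[, b, ], L, d)
    pure <- encoderLayer(Zb, list(mha = p$mha, ffn = p$ffn, ln1 = p$ln1,
                                  ln2 = p$ln2, h = h))
    expect_equal(matrix(batched[, b, ], L, d), pure, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # pooling and GAP agree too
  pf <- semscan:::poolForward(X, 2)
  gf <- semscan:::gapForward(X)
  for (b in seq_len(B)) {
    Zb <- matrix(X[, b, ], L, d)
    expect_equal(matrix(pf$out[, b, ], L / 2, d), maxPool(Zb, 2))
    expect_equal(as.numeric(gf$out[b, ]), globalAveragePool(Zb))
  }
})
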