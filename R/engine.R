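# Batched forward/backward engine for the parallel bimodal networks.
# Tensors are (length, batch, channels) arrays; the matrix view collapses
# (length, batch) into rows so channel mixing becomes one BLAS call.
# Gradients are hand-derived per layer and verified against numerical
# differentiation in the test suite.

tmat <- function(X) { d <- dim(X); dim(X) <- c(d[1] * d[2], d[3]); X }
tarr <- function(M, L, B) { dim(M) <- c(L, B, ncol(M)); M }

# fast column-wise scale/shift (avoids sweep() overhead in hot paths)
colScale <- function(M, s) M * rep(s, each = nrow(M))
colAdd <- function(M, a) M + rep(a, each = nrow(M))

glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dims)
}

## ---- conv + batch norm + ReLU ------------------------------------------

convInit <- function(k, cin, cout) {
  list(W = glorot(k * cin, k * cout, c(k, cin, cout)),
       b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

convbnForward <- function(X, layer, state, training, eps = 1e-5) {
  L <- dim(X)[1]; B <- dim(X)[2]
  W <- layer$W; k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  Xm <- tmat(X)
  padL <- (k - 1) %/% 2
  fw <- .convBnReluForwardC(Xm, matrix(W, k * cin, cout), layer$b,
                            layer$gamma, layer$beta,
                            state$mean, state$var, L, B, k, padL,
                            training, state$count %||% 0, eps, training)
  list(out = tarr(fw$act, L, B),
       cache = list(Xm = Xm, act = fw$act, xhat = fw$xhat,
                    invstd = fw$invstd, L = L, B = B, k = k, padL = padL,
                    training = training),
       state = if (training) list(mean = as.numeric(fw$newMean),
                                  var = as.numeric(fw$newVar),
                                  count = (state$count %||% 0) + 1)
               else state)
}

convbnBackward <- function(dY, layer, cache) {
  L <- cache$L; B <- cache$B
  W <- layer$W; k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  cb <- .convBnReluBackwardC(tmat(dY), cache$act, cache$xhat,
                             cache$invstd, layer$gamma, cache$Xm,
                             matrix(W, k * cin, cout), L, B, k, cache$padL,
                             cache$training)
  list(dX = tarr(cb$dX, L, B),
       grads = list(W = array(cb$dW, dim(W)), b = as.numeric(cb$db),
                    gamma = as.numeric(cb$dGamma),
                    beta = as.numeric(cb$dBeta)))
}

## ---- max pooling --------------------------------------------------------

poolForward <- function(X, pool) {
  L <- dim(X)[1]; B <- dim(X)[2]
  fw <- .maxPoolForwardC(tmat(X), L, B, pool)
  list(out = tarr(fw$Y, L %/% pool, B),
       cache = list(arg = fw$arg, L = L, B = B))
}

poolBackward <- function(dY, cache) {
  tarr(.maxPoolBackwardC(tmat(dY), cache$arg, cache$L, cache$B),
       cache$L, cache$B)
}

## ---- layer norm ---------------------------------------------------------

lnForward <- function(Xm, gamma, beta, eps = 1e-5, wantCache = TRUE) {
  fw <- .lnForwardC(Xm, gamma, beta, eps, wantCache)
  list(out = fw$out, cache = list(xhat = fw$xhat, invstd = fw$invstd))
}

lnBackward <- function(dY, gamma, cache) {
  bk <- .lnBackwardC(dY, gamma, cache$xhat, cache$invstd)
  list(dX = bk$dX, grads = list(gamma = as.numeric(bk$dGamma),
                                beta = as.numeric(bk$dBeta)))
}

## ---- multi-head attention ----------------------------------------------

mhaInit <- function(d, h) {
  dk <- d %/% h
  list(Wq = glorot(d, dk, c(d, dk, h)),
       Wk = glorot(d, dk, c(d, dk, h)),
       Wv = glorot(d, dk, c(d, dk, h)),
       Wo = matrix(glorot(d, d, c(d, d)), d, d))
}

mhaForward <- function(X, p, h, keepA = TRUE) {
  L <- dim(X)[1]; B <- dim(X)[2]; d <- dim(X)[3]
  dk <- d %/% h
  Xm <- tmat(X)
  Q <- K <- V <- O <- A <- vector("list", h)
  for (i in seq_len(h)) {
    Q[[i]] <- Xm %*% p$Wq[, , i]
    K[[i]] <- Xm %*% p$Wk[, , i]
    V[[i]] <- Xm %*% p$Wv[, , i]
    sf <- .sdpaForwardC(Q[[i]], K[[i]], V[[i]], L, B, keepA)
    A[[i]] <- sf$A
    O[[i]] <- sf$O
  }
  concat <- do.call(cbind, O)
  out <- concat %*% p$Wo
  list(out = tarr(out, L, B),
       cache = list(Xm = Xm, Q = Q, K = K, V = V, A = A, concat = concat,
                    L = L, B = B, dk = dk, h = h))
}

mhaBackward <- function(dY, p, cache) {
  L <- cache$L; B <- cache$B; dk <- cache$dk; h <- cache$h
  dYm <- tmat(dY)
  dWo <- crossprod(cache$concat, dYm)
  dConcat <- dYm %*% t(p$Wo)
  dXm <- matrix(0, nrow(cache$Xm), ncol(cache$Xm))
  dWq <- array(0, dim(p$Wq)); dWk <- array(0, dim(p$Wk)); dWv <- array(0, dim(p$Wv))
  for (i in seq_len(h)) {
    dO <- dConcat[, (i - 1) * dk + seq_len(dk), drop = FALSE]
    sb <- .sdpaBackwardC(dO, cache$Q[[i]], cache$K[[i]], cache$V[[i]],
                         cache$A[[i]], L, B)
    dXm <- dXm + sb$dQ %*% t(p$Wq[, , i]) + sb$dK %*% t(p$Wk[, , i]) +
      sb$dV %*% t(p$Wv[, , i])
    dWq[, , i] <- crossprod(cache$Xm, sb$dQ)
    dWk[, , i] <- crossprod(cache$Xm, sb$dK)
    dWv[, , i] <- crossprod(cache$Xm, sb$dV)
  }
  list(dX = tarr(dXm, L, B),
       grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

## ---- encoder layer ------------------------------------------------------

encInit <- function(d, h, dff, no_ffn = FALSE) {
  p <- list(mha = mhaInit(d, h),
            ln1 = list(gamma = rep(1, d), beta = numeric(d)))
  if (!no_ffn) {
    p$ffn <- list(W1 = matrix(glorot(d, dff, c(d, dff)), d, dff),
                  b1 = numeric(dff),
                  W2 = matrix(glorot(dff, d, c(dff, d)), dff, d),
                  b2 = numeric(d))
    p$ln2 <- list(gamma = rep(1, d), beta = numeric(d))
  }
  p
}

encForward <- function(X, p, h, no_residual = FALSE, no_ffn = FALSE,
                       keepCache = TRUE, keepA = keepCache) {
  L <- dim(X)[1]; B <- dim(X)[2]
  att <- mhaForward(X, p$mha, h, keepA = keepA)
  sum1 <- if (no_residual) tmat(att$out) else tmat(X) + tmat(att$out)
  l1 <- lnForward(sum1, p$ln1$gamma, p$ln1$beta, wantCache = keepCache)
  if (no_ffn) {
    return(list(out = tarr(l1$out, L, B),
                cache = list(att = att$cache, l1 = l1$cache, L = L, B = B,
                             attW = att$cache$A)))
  }
  zMid <- l1$out
  hMid <- .biasReluC(zMid %*% p$ffn$W1, p$ffn$b1)$out
  fOut <- .colAddC(hMid %*% p$ffn$W2, p$ffn$b2)
  sum2 <- if (no_residual) fOut else zMid + fOut
  l2 <- lnForward(sum2, p$ln2$gamma, p$ln2$beta, wantCache = keepCache)
  list(out = tarr(l2$out, L, B),
       cache = list(att = att$cache, l1 = l1$cache, l2 = l2$cache,
                    zMid = zMid, hMid = hMid, L = L, B = B,
                    attW = att$cache$A))
}

encBackward <- function(dY, p, cache, h, no_residual = FALSE, no_ffn = FALSE) {
  L <- cache$L; B <- cache$B
  grads <- list()
  if (no_ffn) {
    lb <- lnBackward(tmat(dY), p$ln1$gamma, cache$l1)
    grads$ln1 <- lb$grads
    dSum1 <- lb$dX
  } else {
    lb2 <- lnBackward(tmat(dY), p$ln2$gamma, cache$l2)
    grads$ln2 <- lb2$grads
    dSum2 <- lb2$dX
    dFout <- dSum2
    dHmid <- dFout %*% t(p$ffn$W2)
    dHmid[cache$hMid <= 0] <- 0
    grads$ffn <- list(W1 = crossprod(cache$zMid, dHmid),
                      b1 = colSums(dHmid),
                      W2 = crossprod(cache$hMid, dFout),
                      b2 = colSums(dFout))
    dZmid <- dHmid %*% t(p$ffn$W1)
    if (!no_residual) dZmid <- dZmid + dSum2
    lb1 <- lnBackward(dZmid, p$ln1$gamma, cache$l1)
    grads$ln1 <- lb1$grads
    dSum1 <- lb1$dX
  }
  mb <- mhaBackward(tarr(dSum1, L, B), p$mha, cache$att)
  grads$mha <- mb$grads
  dX <- mb$dX
  if (!no_residual) dX <- dX + tarr(dSum1, L, B)
  list(dX = dX, grads = grads)
}

## ---- LSTM ---------------------------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

lstmInit <- function(cin, u) {
  list(Wx = matrix(glorot(cin, 4 * u, c(cin, 4 * u)), cin, 4 * u),
       Wh = matrix(glorot(u, 4 * u, c(u, 4 * u)), u, 4 * u),
       b = numeric(4 * u))
}

lstmForward <- function(X, p) {
  L <- dim(X)[1]; B <- dim(X)[2]; cin <- dim(X)[3]
  u <- nrow(p$Wh)
  H <- array(0, c(L, B, u))
  gi <- gf <- gg <- go <- cc <- tc <- array(0, c(B, u, L))
  h <- matrix(0, B, u)
  cprev <- matrix(0, B, u)
  for (t in seq_len(L)) {
    xt <- matrix(X[t, , ], B, cin)
    z <- xt %*% p$Wx + h %*% p$Wh + matrix(p$b, B, 4 * u, byrow = TRUE)
    i <- sigm(z[, seq_len(u), drop = FALSE])
    f <- sigm(z[, u + seq_len(u), drop = FALSE])
    g <- tanh(z[, 2 * u + seq_len(u), drop = FALSE])
    o <- sigm(z[, 3 * u + seq_len(u), drop = FALSE])
    cnew <- f * cprev + i * g
    tcn <- tanh(cnew)
    h <- o * tcn
    H[t, , ] <- h
    gi[, , t] <- i; gf[, , t] <- f; gg[, , t] <- g; go[, , t] <- o
    cc[, , t] <- cnew; tc[, , t] <- tcn
    cprev <- cnew
  }
  list(out = H, cache = list(X = X, gi = gi, gf = gf, gg = gg, go = go,
                             cc = cc, tc = tc, H = H, u = u))
}

lstmBackward <- function(dH, p, cache) {
  X <- cache$X
  L <- dim(X)[1]; B <- dim(X)[2]; cin <- dim(X)[3]
  u <- cache$u
  dWx <- matrix(0, cin, 4 * u); dWh <- matrix(0, u, 4 * u); db <- numeric(4 * u)
  dX <- array(0, dim(X))
  dhNext <- matrix(0, B, u)
  dcNext <- matrix(0, B, u)
  for (t in rev(seq_len(L))) {
    dh <- matrix(dH[t, , ], B, u) + dhNext
    i <- cache$gi[, , t]; f <- cache$gf[, , t]
    g <- cache$gg[, , t]; o <- cache$go[, , t]
    tcn <- cache$tc[, , t]
    dc <- dh * o * (1 - tcn^2) + dcNext
    cprev <- if (t > 1) cache$cc[, , t - 1] else matrix(0, B, u)
    di <- dc * g * i * (1 - i)
    df <- dc * cprev * f * (1 - f)
    dg <- dc * i * (1 - g^2)
    do <- dh * tcn * o * (1 - o)
    dz <- cbind(di, df, dg, do)
    xt <- matrix(X[t, , ], B, cin)
    hprev <- if (t > 1) matrix(cache$H[t - 1, , ], B, u) else matrix(0, B, u)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dX[t, , ] <- dz %*% t(p$Wx)
    dhNext <- dz %*% t(p$Wh)
    dcNext <- dc * f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- pooling heads ------------------------------------------------------

gapForward <- function(X) {
  L <- dim(X)[1]; B <- dim(X)[2]
  group <- rep(seq_len(B), each = L)
  Y <- rowsum(tmat(X), group) / L
  rownames(Y) <- NULL
  list(out = Y, cache = list(L = L, B = B, group = group))
}

gapBackward <- function(dY, cache) {
  tarr(dY[cache$group, , drop = FALSE] / cache$L, cache$L, cache$B)
}

attnPoolInit <- function(u, a = 32) {
  list(Wa = matrix(glorot(u, a, c(u, a)), u, a), ba = numeric(a),
       va = as.numeric(glorot(a, 1, c(a))))
}

attnPoolForward <- function(X, p) {
  L <- dim(X)[1]; B <- dim(X)[2]; u <- dim(X)[3]
  Xm <- tmat(X)
  Tm <- tanh(sweep(Xm %*% p$Wa, 2, p$ba, "+"))
  e <- matrix(Tm %*% p$va, L, B)
  e <- sweep(e, 2, apply(e, 2, max), "-")
  alpha <- sweep(exp(e), 2, colSums(exp(e)), "/")
  av <- as.vector(alpha)
  group <- rep(seq_len(B), each = L)
  out <- rowsum(Xm * av, group)
  rownames(out) <- NULL
  list(out = out,
       cache = list(Xm = Xm, Tm = Tm, alpha = alpha, group = group,
                    L = L, B = B, u = u))
}

attnPoolBackward <- function(dY, p, cache) {
  L <- cache$L; B <- cache$B
  alpha <- cache$alpha
  av <- as.vector(alpha)
  dYrep <- dY[cache$group, , drop = FALSE]
  dXm <- dYrep * av
  # d alpha[l,b] = sum_c dY[b,c] X[l,b,c]
  dAlpha <- matrix(rowSums(dYrep * cache$Xm), L, B)
  # softmax backward per column
  dE <- alpha * sweep(dAlpha, 2, colSums(alpha * dAlpha), "-")
  dVaIn <- as.vector(dE)                      # dE as (L*B)
  dTm <- (dVaIn %o% p$va) * (1 - cache$Tm^2)
  grads <- list(Wa = crossprod(cache$Xm, dTm), ba = colSums(dTm),
                va = as.numeric(crossprod(cache$Tm, dVaIn)))
  dXm <- dXm + dTm %*% t(p$Wa)
  list(dX = tarr(dXm, L, B), grads = grads)
}
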