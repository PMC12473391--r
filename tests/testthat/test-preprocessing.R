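test_that("channel derivation is elementwise sum and difference", {
  der <- deriveChannels(c(1, 2), c(0.5, 1))
  expect_equal(der$HEOG, c(0.5, 1))
  expect_equal(der$HSUM, c(1.5, 3))
  # algebraic identity: Hl = s + e, Hr = -s + e
  s <- rnorm(50); e <- rnorm(50)
  der2 <- deriveChannels(s + e, -s + e)
  expect_equal(der2$HEOG, 2 * s)
  expect_equal(der2$HSUM, 2 * e)
  expect_true(all(deriveChannels(e, e)$HEOG == 0))
  expect_error(deriveChannels(1:3, 1:4), "equal length")
})

test_that("median smoothing matches a brute-force sliding median", {
  set.seed(1)
  bruteMedian <- function(x, w) {
    n <- length(x)
    pl <- w %/% 2; pr <- w - pl - 1
    xp <- c(rev(x[seq_len(pl)]), x, if (pr > 0) rev(x[seq.int(n - pr + 1, n)]))
    vapply(seq_len(n), function(i) {
      win <- sort(xp[i:(i + w - 1)])
      if (w %% 2 == 1) win[(w + 1) / 2] else mean(win[w / 2 + 0:1])
    }, 0)
  }
  for (w in c(3, 4, 7, 10)) {
    x <- rnorm(200)
    expect_equal(medianSmooth(x, w), bruteMedian(x, w))
  }
  # constant unchanged; impulse removed; ramp stays within one step
  expect_equal(medianSmooth(rep(5, 50), 10), rep(5, 50))
  imp <- numeric(100); imp[50] <- 500
  expect_lt(max(abs(medianSmooth(imp, 10))), 1e-9)
  ramp <- seq(0, 1, length.out = 100)
  expect_lt(max(abs(medianSmooth(ramp, 10) - ramp)), diff(ramp)[1] * 5 + 1e-12)
  expect_error(medianSmooth(1:5, 10), "window")
})

test_that("db2 decomposition matches the reference filter bank", {
  # frozen single-level coefficients of the standard db2 symmetric-mode
  # transform on a known signal
  x <- sin(2 * pi * (0:31) / 16) + 0.1 * (0:31)
  st <- semscan:::dwtStep(x)
  aRef <- c(0.1706543641, 0.4487133174, 1.5914319611, 2.0201169457,
            1.6493358462, 0.8619726269, 0.2849394082, 0.4219398485,
            1.3584063730, 2.7114550172, 3.8541736609, 4.2828586455,
            3.9120775460, 3.1247143267, 2.5476811080, 2.6846815483,
            3.6928096292)
  dRef <- c(-0.2955820291, 0.0595306558, 0.0917284704, 0.0701929911,
            0.0075394096, -0.0595306558, -0.0917284704, -0.0701929911,
            -0.0075394096, 0.0595306558, 0.0917284704, 0.0701929911,
            0.0075394096, -0.0595306558, -0.0917284704, -0.0701929911,
            0.2599051599)
  expect_equal(st$a, aRef, tolerance = 1e-9)
  expect_equal(st$d, dRef, tolerance = 1e-9)
  # perfect reconstruction
  set.seed(2)
  y <- rnorm(777)
  sy <- semscan:::dwtStep(y)
  expect_equal(semscan:::idwtStep(sy$a, sy$d, length(y)), y,
               tolerance = 1e-12)
})

test_that("baseline removal keeps alpha, removes DC and drift", {
  n <- 4096; fs <- 500
  t <- (seq_len(n) - 1) / fs
  expect_lt(max(abs(removeBaselineDWT(rep(50, n)))), 0.5)
  s10 <- sin(2 * pi * 10 * t)
  r10 <- removeBaselineDWT(s10)
  expect_equal(sqrt(mean(r10^2)) / sqrt(mean(s10^2)), 1, tolerance = 0.01)
  drift <- sin(2 * pi * 0.05 * t)
  att <- 20 * log10(sqrt(mean(removeBaselineDWT(drift)^2)) /
                      sqrt(mean(drift^2)))
  expect_lt(att, -20)
  # linear operator
  set.seed(3)
  a <- rnorm(2048)
  expect_equal(removeBaselineDWT(3 * a), 3 * removeBaselineDWT(a),
               tolerance = 1e-9)
  expect_error(removeBaselineDWT(rnorm(500), level = 10), "lower level")
})

test_that("baseline removal separates drift from alpha on mixtures", {
  n <- 2^14; fs <- 500
  t <- (seq_len(n) - 1) / fs
  drift <- 30 * sin(2 * pi * 0.05 * t + 1)
  alpha <- 5 * sin(2 * pi * 10 * t)
  out <- removeBaselineDWT(drift + alpha)
  residDrift <- out - alpha
  expect_lt(20 * log10(sqrt(mean(residDrift^2)) / sqrt(mean(drift^2))), -20)
  bandPower <- function(x, f0) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sum(sp[f > f0 - 1 & f < f0 + 1])
  }
  dB <- 10 * log10(bandPower(out, 10) / bandPower(alpha, 10))
  expect_lt(abs(dB), 1)
})

test_that("window decimation keeps every factor-th sample", {
  expect_length(downsampleWindow(rnorm(1500), 3), 500)
  expect_equal(downsampleWindow(0:8, 3), c(0, 3, 6))
  expect_equal(downsampleWindow(rep(7, 9), 3), rep(7, 3))
  expect_error(downsampleWindow(1:10, 3), "divisible")
})

test_that("the preprocessing chain is stable and idempotent where expected", {
  rec <- simulateRecording(smallSimConfig(seed = 2))
  prep <- preprocessRecording(rec, "HSUM")
  expect_equal(channelNames(prep), c("HEOG", "HSUM"))
  expect_equal(nSamples(prep), nSamples(rec))
  expect_identical(intervals(prep), intervals(rec))
  # median of a median-smoothed constant is unchanged
  cst <- medianSmooth(rep(3, 100), 10)
  expect_equal(medianSmooth(cst, 10), cst)
  prep2 <- preprocessRecording(rec, "O2")
  expect_equal(channelNames(prep2), c("HEOG", "O2"))
})
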