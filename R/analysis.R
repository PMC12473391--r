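# FFT-based full convolution with centred ("same") alignment
fftConvSame <- function(x, w) {
  n <- length(x); k <- length(w)
  m <- stats::nextn(n + k - 1, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, m - n))) *
                  stats::fft(c(w, rep(0, m - k))), inverse = TRUE) / m
  y[(k - 1) %/% 2 + seq_len(n)]
}

#' Alpha-band wavelet energy curve
#'
#' Complex-Morlet continuous wavelet transform over the alpha band
#' (default 6-14 Hz in 0.25 Hz steps; Morlet centre frequency 1.0,
#' bandwidth 1.5), reduced to a time-varying energy curve by averaging the
#' coefficient magnitudes across the frequency dimension. Wavelet kernels
#' are L1-normalized so the curve scales linearly with signal amplitude.
#'
#' @param x numeric signal (at least 1 s of samples).
#' @param fs sampling rate in Hz.
#' @param band frequency band (Hz pair) inside `(0, fs/2)`.
#' @param freq_step frequency sampling step in Hz.
#' @param bandwidth,center_freq Morlet shape parameters.
#' @return non-negative numeric vector, same length as `x`.
#' @export
cwtAlphaEnergy <- function(x, fs, band = c(6, 14), freq_step = 0.25,
                           bandwidth = 1.5, center_freq = 1.0) {
  stopIfNot(length(x) >= fs, "need at least 1 s of samples")
  stopIfNot(band[1] > 0 && band[2] < fs / 2 && band[1] < band[2],
            sprintf("band must lie inside (0, %g) Hz", fs / 2))
  freqs <- seq(band[1], band[2], by = freq_step)
  acc <- numeric(length(x))
  for (f in freqs) {
    sigma <- sqrt(bandwidth / 2) * center_freq / f
    t <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
    w <- exp(2i * pi * f * t) * exp(-(t * f / center_freq)^2 / bandwidth)
    w <- w / sum(Mod(w))
    acc <- acc + Mod(fftConvSame(x, w))
  }
  acc / length(freqs)
}

#' Alpha-energy correlation between O2 and HSUM
#'
#' For each non-overlapping `win_s`-second sample, computes the Pearson
#' correlation between the alpha-band wavelet energy curves of the
#' occipital EEG channel and the HSUM surrogate (both baseline-corrected
#' first). Samples whose correlation deviates from the mean by more than
#' twice the standard deviation are removed in a single pass. A high median
#' correlation supports HSUM as a two-electrode surrogate for occipital
#' alpha activity.
#'
#' @param rec a [SemRecording-class] with channels `Hl`, `Hr` and `O2`.
#' @param win_s sample length in seconds (non-overlapping).
#' @param band alpha band in Hz.
#' @param dwt_level baseline-removal decomposition depth.
#' @return list with `r` (kept per-sample correlations), `removed` (count),
#'   `median_r`, `mean_r` and `t_start` of the kept samples.
#' @export
energyCorrelation <- function(rec, win_s = 3, band = c(6, 14),
                              dwt_level = 10) {
  fs <- samplingRate(rec)
  der <- deriveChannels(channel(rec, "Hl"), channel(rec, "Hr"))
  hsum <- removeBaselineDWT(der$HSUM, dwt_level)
  o2 <- removeBaselineDWT(channel(rec, "O2"), dwt_level)
  wlen <- round(win_s * fs)

  iv <- intervals(rec)
  starts <- numeric(0)
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      k <- floor((iv$end_s[i] - iv$start_s[i]) / win_s)
      if (k >= 1) starts <- c(starts, iv$start_s[i] + (0:(k - 1)) * win_s)
    }
  } else {
    starts <- (0:(nSamples(rec) %/% wlen - 1)) * win_s
  }
  if (length(starts) < 3)
    stop("need at least 3 non-overlapping samples", call. = FALSE)
  starts <- sort(starts)

  r <- vapply(starts, function(s) {
    idx <- round(s * fs) + seq_len(wlen)
    c1 <- cwtAlphaEnergy(o2[idx], fs, band)
    c2 <- cwtAlphaEnergy(hsum[idx], fs, band)
    if (sd(c1) == 0 || sd(c2) == 0) return(NA_real_)
    cor(c1, c2)
  }, 0)
  ok <- is.finite(r)
  r <- r[ok]; starts <- starts[ok]
  keep <- trimOutliers2SD(r)
  list(r = r[keep], removed = sum(!keep), median_r = median(r[keep]),
       mean_r = mean(r[keep]), t_start = starts[keep])
}

# single-pass two-standard-deviation trimming rule
trimOutliers2SD <- function(x) abs(x - mean(x)) <= 2 * sd(x)

#' Extract self-attention maps from a trained model
#'
#' Runs one instrumented inference-mode forward pass and captures the
#' attention weight matrices of every encoder layer and head in both
#' modality branches. Instrumentation does not alter the forward
#' computation; each weight row sums to one.
#'
#' @param model a trained [SemModel-class] (Transformer variant).
#' @param ws a [SemWindowSet-class].
#' @param idx a single window index.
#' @return list with `probs` (the class probabilities) and `maps`:
#'   `maps[[branch]][[layer]][[head]]` is an `l x l` attention matrix.
#' @export
extractAttention <- function(model, ws, idx) {
  cfg <- model@config
  if (cfg$variant != "cnn_transformer" || cfg$no_transformer)
    stop("unsupported: attention extraction requires a Transformer variant",
         call. = FALSE)
  stopIfNot(length(idx) == 1, "one window at a time")
  tt <- wsTensors(ws, idx)
  fw <- netForward(model@params, tt$X1, tt$X2, training = FALSE, record = TRUE)
  maps <- lapply(fw$attn, function(branch)
    lapply(branch, function(A)          # A: list over heads of (l, l, B=1)
      lapply(A, function(cube) cube[, , 1])))
  names(maps) <- c("branch1", "branch2")
  list(probs = fw$probs, maps = maps)
}

#' Class-averaged attention maps
#'
#' Element-wise mean of the layer-`layer` attention maps over all windows
#' of each true class, per modality branch and head. Averages of
#' row-stochastic matrices remain row-stochastic.
#'
#' @param model a trained [SemModel-class] (Transformer variant).
#' @param ws a [SemWindowSet-class].
#' @param idx window indices to average over.
#' @param layer encoder layer to summarize (default 2, the final layer).
#' @param batch_size forward batch size.
#' @return nested list: `[[class]][[branch]][[head]]` mean `l x l` matrix,
#'   classes `"SEM"` and `"NONSEM"`.
#' @export
classAverageAttention <- function(model, ws, idx = seq_len(ncol(ws)),
                                  layer = 2, batch_size = 128) {
  cfg <- model@config
  if (cfg$variant != "cnn_transformer" || cfg$no_transformer)
    stop("unsupported: attention extraction requires a Transformer variant",
         call. = FALSE)
  y <- ws$label[idx]
  if (length(unique(y)) < 2)
    stop("both classes required for class-wise averaging", call. = FALSE)
  h <- cfg$heads
  sums <- list()
  counts <- c(SEM = 0, NONSEM = 0)
  for (start in seq.int(1, length(idx), by = batch_size)) {
    ii <- idx[start:min(start + batch_size - 1, length(idx))]
    tt <- wsTensors(ws, ii)
    fw <- netForward(model@params, tt$X1, tt$X2, training = FALSE,
                     record = TRUE)
    for (cls in c("SEM", "NONSEM")) {
      sel <- which(tt$y == if (cls == "SEM") 1 else 0)
      if (!length(sel)) next
      counts[cls] <- counts[cls] + length(sel)
      for (b in 1:2) {
        A <- fw$attn[[b]][[layer]]
        for (hi in seq_len(h)) {
          S <- rowSums(A[[hi]][, , sel, drop = FALSE], dims = 2)
          key <- sprintf("%s.%d.%d", cls, b, hi)
          sums[[key]] <- if (is.null(sums[[key]])) S else sums[[key]] + S
        }
      }
    }
  }
  out <- list()
  for (cls in c("SEM", "NONSEM")) {
    if (counts[cls] == 0)
      stop(sprintf("class %s absent from the selected windows", cls),
           call. = FALSE)
    out[[cls]] <- lapply(1:2, function(b)
      lapply(seq_len(h), function(hi)
        sums[[sprintf("%s.%d.%d", cls, b, hi)]] / counts[cls]))
    names(out[[cls]]) <- c("branch1", "branch2")
  }
  out
}

#' Plot an attention map as a heat map
#'
#' @param m an `l x l` attention matrix.
#' @param main plot title.
#' @export
plotAttention <- function(m, main = "attention") {
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "key position", ylab = "query position", main = main)
}
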