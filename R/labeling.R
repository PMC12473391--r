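# moving-average smoother with reflect padding (odd effective window)
movAvg <- function(x, span_s, fs) {
  w <- max(1L, round(span_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1 || length(x) <= w) return(x)
  p <- (w - 1) %/% 2
  xp <- c(rev(x[seq_len(p)]), x, rev(x[seq.int(length(x) - p + 1, length(x))]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2)[(p + 1):(p + length(x))])
}

detrendLinear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

# dominant frequency (Hz) of a mean-removed signal via zero-padded periodogram
dominantFrequency <- function(x, fs, fmax = 30) {
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(max(length(x), 60 * fs)))
  p <- Mod(fft(c(x, rep(0, nfft - length(x)))))^2
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f > 0 & f <= fmax
  f[keep][which.max(p[keep])]
}

#' Check an epoch against the SEM labeling criteria
#'
#' Executable form of the visual criteria for marking slow eye movements:
#' (1) synchronous slow sinusoidal excursions with opposite phases on the
#' two HEOG channels, (2) dominant frequency in 0.2-0.6 Hz with duration
#' over 2 s, (3) single-channel amplitude 20-200 uV, (4) inter-channel
#' onset difference at most 300 ms, (5) no obvious artifacts.
#'
#' Measurements target the slow excursion, so phase opposition, amplitude
#' and onset are computed on lightly smoothed (0.2 s moving average),
#' linearly detrended copies of the channels; the dominant frequency comes
#' from the zero-padded periodogram peak of the smoothed difference trace.
#' Phase opposition is the Pearson correlation of the two channels
#' (required `<= phase_threshold`); amplitude is half the peak magnitude of
#' the difference trace (i.e. the single-channel excursion peak); onset is
#' the first crossing of 25% of each channel's peak magnitude; the artifact
#' check flags any raw sample beyond `artifact_uv`.
#'
#' @param hl,hr epoch samples of the two HEOG channels (uV), equal length,
#'   at least 1 s.
#' @param fs sampling rate in Hz.
#' @param phase_threshold maximum allowed Hl-Hr correlation (default -0.8).
#' @param artifact_uv artifact ceiling in uV (default 500).
#' @param freq_tol relative tolerance on the frequency band edges (default
#'   0.07). The dominant frequency of a finite, tapered, noisy epoch is
#'   estimated with a small bias near the band edges; the tolerance keeps
#'   the verdict stable for genuine SEM at the nominal bounds while still
#'   rejecting clearly out-of-band activity.
#' @param slope_max saccade guard: maximum allowed edge rate (max slope of
#'   the lightly smoothed difference trace divided by its peak magnitude,
#'   in 1/s; default 12). A sinusoid at or below 0.6 Hz has a normalized
#'   edge rate of at most `2*pi*0.6 ~ 3.8`/s (noise allowance included in
#'   the default), whereas a step-like saccadic deflection - whose dominant
#'   periodogram frequency can alias into the SEM band once the mean is
#'   removed - exceeds 20/s. This implements the requirement that SEM be a
#'   slow excursion, clearly different from the saccade.
#' @return a `CriteriaReport` list: `passed`, per-criterion `verdicts`
#'   (phase_opposition, frequency_band, duration, amplitude,
#'   onset_difference, artifact_free) and `measures` (dominant frequency Hz,
#'   amplitude uV, onset difference ms, Hl-Hr correlation, duration s).
#' @export
checkSemCriteria <- function(hl, hr, fs, phase_threshold = -0.8,
                             artifact_uv = 500, freq_tol = 0.07,
                             slope_max = 12) {
  stopIfNot(length(hl) == length(hr), "epochs must have equal length")
  dur <- length(hl) / fs
  stopIfNot(dur >= 1, "epoch shorter than 1 s")

  hlF <- detrendLinear(movAvg(hl, 0.2, fs))
  hrF <- detrendLinear(movAvg(hr, 0.2, fs))
  heog <- hlF - hrF

  r <- if (sd(hlF) > 0 && sd(hrF) > 0) cor(hlF, hrF) else 0
  domF <- dominantFrequency(heog, fs)
  fast <- detrendLinear(movAvg(hl - hr, 0.05, fs))
  slopeRate <- max(abs(diff(fast))) * fs / max(abs(fast))
  ampUv <- max(abs(heog)) / 2
  # inter-channel onset difference as the cross-correlation lag between the
  # two (sign-aligned) channels; robust to common-mode EEG background that
  # corrupts per-channel threshold crossings
  maxLag <- min(round(0.4 * fs), length(hlF) - 2)
  cc <- stats::ccf(hlF, -hrF, lag.max = maxLag, plot = FALSE)
  onsetMs <- abs(cc$lag[which.max(cc$acf)]) / fs * 1000

  verdicts <- list(
    phase_opposition = is.finite(r) && r <= phase_threshold,
    frequency_band = domF >= 0.2 * (1 - freq_tol) &&
      domF <= 0.6 * (1 + freq_tol) && slopeRate <= slope_max,
    duration = dur > 2,
    amplitude = ampUv >= 20 && ampUv <= 200,
    onset_difference = is.finite(onsetMs) && onsetMs <= 300,
    artifact_free = max(abs(c(hl, hr))) <= artifact_uv
  )
  structure(list(
    passed = all(unlist(verdicts)),
    verdicts = verdicts,
    measures = list(dominant_freq_hz = domF, amplitude_uv = ampUv,
                    onset_diff_ms = onsetMs, hl_hr_correlation = r,
                    duration_s = dur, edge_rate_per_s = slopeRate)
  ), class = "CriteriaReport")
}

#' @export
print.CriteriaReport <- function(x, ...) {
  cat(sprintf("SEM criteria: %s\n", if (x$passed) "PASSED" else "FAILED"))
  for (nm in names(x$verdicts))
    cat(sprintf("  %-17s %s\n", nm, if (x$verdicts[[nm]]) "ok" else "VIOLATED"))
  m <- x$measures
  cat(sprintf("  f=%.3f Hz, amp=%.1f uV, onset diff=%.0f ms, r=%.3f, dur=%.2f s\n",
              m$dominant_freq_hz, m$amplitude_uv, m$onset_diff_ms,
              m$hl_hr_correlation, m$duration_s))
  invisible(x)
}

#' Extract labeled sliding windows from a preprocessed recording
#'
#' Applies a `win_s`-second sliding window with `step_s` step inside each
#' labeled epoch. Windows fully contained in one epoch inherit its label;
#' windows straddling an epoch boundary or an unlabeled gap are discarded.
#' Raw windows (`win_s * fs` samples, 1500 at the defaults) are decimated by
#' `decimate` to the model input length (500).
#'
#' @param rec a preprocessed [SemRecording-class] with the two modality
#'   channels (see [preprocessRecording()]).
#' @param intervals labeled intervals; defaults to `intervals(rec)`.
#' @param win_s window length in seconds (default 3).
#' @param step_s step size in seconds (default 0.1).
#' @param decimate decimation factor applied per window (default 3).
#' @return a [SemWindowSet-class], windows in chronological order.
#' @export
extractWindows <- function(rec, intervals = NULL, win_s = 3, step_s = 0.1,
                           decimate = 3) {
  iv <- validateIntervals(intervals %||% intervals(rec))
  if (!nrow(iv))
    stop("empty-dataset error: no labeled epochs", call. = FALSE)
  fs <- samplingRate(rec)
  wlen <- round(win_s * fs)
  stopIfNot(wlen %% decimate == 0, "window length not divisible by decimate")
  chans <- channelNames(rec)
  stopIfNot(length(chans) >= 2, "recording must carry the two modality channels")
  m1 <- rec@signals[, 1]
  m2 <- rec@signals[, 2]
  n <- nSamples(rec)

  starts <- numeric(0); labels <- integer(0)
  for (i in seq_len(nrow(iv))) {
    e0 <- iv$start_s[i]; e1 <- min(iv$end_s[i], n / fs)
    if (e1 - e0 < win_s - 1e-9) next
    k <- 0:floor((e1 - e0 - win_s) / step_s + 1e-9)
    starts <- c(starts, e0 + k * step_s)
    labels <- c(labels, rep(if (iv$label[i] == "SEM") 1L else 0L, length(k)))
  }
  if (!length(starts))
    stop("empty-dataset error: no window fits inside any labeled epoch",
         call. = FALSE)
  ord <- order(starts)
  starts <- starts[ord]; labels <- labels[ord]

  outLen <- wlen %/% decimate
  x1 <- matrix(0, outLen, length(starts))
  x2 <- matrix(0, outLen, length(starts))
  sel <- seq.int(1, wlen, by = decimate)
  for (j in seq_along(starts)) {
    i0 <- round(starts[j] * fs)
    idx <- i0 + seq_len(wlen)
    x1[, j] <- m1[idx][sel]
    x2[, j] <- m2[idx][sel]
  }
  newSemWindowSet(x1, x2, labels, starts,
                  meta = list(fs = fs, win_s = win_s, step_s = step_s,
                              decimate = decimate,
                              modalities = chans[1:2],
                              subject = subjectId(rec)))
}

#' Chronological train/test split with contiguous CV folds
#'
#' The first `ceiling(train_frac * n)` windows (in time order) form the
#' training portion, the remainder the held-out test set. The training
#' portion is additionally partitioned into `n_folds` contiguous blocks for
#' cross-validation; contiguous (unshuffled) folds avoid leakage between
#' heavily overlapping neighbouring windows.
#'
#' @param ws a [SemWindowSet-class] in chronological order.
#' @param train_frac training fraction (default 0.7).
#' @param n_folds number of contiguous folds over the training portion.
#' @return list with integer index vectors `train`, `test` and a list
#'   `folds` partitioning `train`.
#' @export
chronologicalSplit <- function(ws, train_frac = 0.7, n_folds = 5) {
  n <- ncol(ws)
  nTrain <- ceiling(train_frac * n)
  stopIfNot(nTrain >= 1 && nTrain < n, "train or test portion is empty")
  train <- seq_len(nTrain)
  test <- seq.int(nTrain + 1, n)
  y <- ws$label[train]
  if (length(unique(y)) < 2)
    stop("class-absence error: training portion lacks one of the two classes",
         call. = FALSE)
  bounds <- floor(seq(0, nTrain, length.out = n_folds + 1))
  folds <- lapply(seq_len(n_folds),
                  function(i) seq.int(bounds[i] + 1, bounds[i + 1]))
  list(train = train, test = test, folds = folds)
}
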