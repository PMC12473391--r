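#' Derive HEOG and HSUM channels
#'
#' The difference of the two outer-canthus electrodes isolates (doubled)
#' horizontal eye movement, since conjugate eye movements are opposite-phase
#' on `Hl` and `Hr` while EEG activity is common mode; the sum cancels eye
#' movement and retains the (doubled) EEG-like common mode:
#' `HEOG = Hl - Hr`, `HSUM = Hl + Hr`.
#'
#' @param hl,hr numeric vectors of equal length (uV).
#' @return list with numeric vectors `HEOG` and `HSUM`.
#' @export
deriveChannels <- function(hl, hr) {
  stopIfNot(length(hl) == length(hr), "Hl and Hr must have equal length")
  list(HEOG = hl - hr, HSUM = hl + hr)
}

#' Sliding-window median smoothing
#'
#' Order-statistics smoother used on the HEOG channel to suppress impulsive
#' noise while preserving the slow SEM excursions. For an even window the
#' median is the mean of the two central order statistics; edges use
#' reflect padding so the output has the input's length.
#'
#' @param x numeric vector (uV).
#' @param window window length in samples (default 10).
#' @return smoothed numeric vector, same length as `x`.
#' @export
medianSmooth <- function(x, window = 10) {
  n <- length(x)
  w <- as.integer(window)
  stopIfNot(w >= 1, "window must be >= 1")
  stopIfNot(n >= w, "window longer than signal")
  if (w == 1) return(x)
  pl <- w %/% 2
  pr <- w - pl - 1
  xp <- c(rev(x[seq_len(pl)]), x, if (pr > 0) rev(x[seq.int(n - pr + 1, n)]))
  E <- matrix(0, n, w)
  for (k in seq_len(w)) E[, k] <- xp[seq.int(k, length.out = n)]
  # vectorised odd-even transposition sort across the window columns
  for (pass in seq_len(w)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    for (j in seq.int(start, w - 1, by = 2)) {
      lo <- pmin(E[, j], E[, j + 1])
      E[, j + 1] <- pmax(E[, j], E[, j + 1])
      E[, j] <- lo
    }
  }
  if (w %% 2 == 1) E[, (w + 1) %/% 2]
  else (E[, w %/% 2] + E[, w %/% 2 + 1]) / 2
}

#' Wavelet baseline-drift removal
#'
#' Removes slow baseline drift by subtracting the level-`level`
#' approximation of a Daubechies-2 discrete wavelet decomposition
#' (symmetric signal extension, all detail bands zeroed before
#' reconstruction). At 500 Hz and level 10 the approximation band is
#' roughly 0-0.24 Hz, so drift is removed while alpha-band EEG activity is
#' untouched.
#'
#' @param x numeric vector (uV).
#' @param level decomposition depth (default 10); requires
#'   `length(x) >= 2^level`.
#' @return drift-corrected vector, same length as `x`.
#' @export
removeBaselineDWT <- function(x, level = 10) {
  stopIfNot(level >= 1, "level must be >= 1")
  if (length(x) < 2^level)
    stop(sprintf(paste0("signal length %d is shorter than 2^%d = %d required ",
                        "for a depth-%d decomposition; use a lower level"),
                 length(x), level, 2^level, level), call. = FALSE)
  dec <- dwtDecompose(x, level)
  baseline <- dwtApproxReconstruct(dec)
  x - baseline[seq_along(x)]
}

#' Decimate a window to its model input length
#'
#' Keeps every `factor`-th sample starting at the first. The recordings are
#' band-limited to 30 Hz at acquisition, so decimation from 500 Hz by 3
#' (new Nyquist about 83 Hz) needs no anti-alias filter.
#'
#' @param x numeric vector whose length is divisible by `factor`.
#' @param factor decimation factor (default 3: 1500 raw samples -> 500).
#' @return decimated vector of length `length(x) / factor`.
#' @export
downsampleWindow <- function(x, factor = 3) {
  stopIfNot(length(x) %% factor == 0,
            sprintf("length %d not divisible by factor %d", length(x), factor))
  x[seq.int(1, length(x), by = factor)]
}

#' Apply the per-modality cleaning chain to a recording
#'
#' Derives HEOG/HSUM from `Hl`/`Hr`, median-smooths HEOG (modality 1) and
#' applies wavelet baseline removal to the second modality (`O2` or `HSUM`).
#' Preprocessing runs on the continuous recording, before windowing, to
#' avoid per-window edge artifacts.
#'
#' @param rec a [SemRecording-class] with channels `Hl`, `Hr` (and `O2` if
#'   `modality2 = "O2"`).
#' @param modality2 second modality: `"HSUM"` (default) or `"O2"`.
#' @param median_window median smoother window (samples).
#' @param dwt_level wavelet decomposition depth.
#' @return a [SemRecording-class] with channels `HEOG` and `modality2`,
#'   intervals carried over.
#' @export
preprocessRecording <- function(rec, modality2 = c("HSUM", "O2"),
                                median_window = 10, dwt_level = 10) {
  modality2 <- match.arg(modality2)
  der <- deriveChannels(channel(rec, "Hl"), channel(rec, "Hr"))
  m1 <- medianSmooth(der$HEOG, median_window)
  raw2 <- if (modality2 == "HSUM") der$HSUM else channel(rec, "O2")
  m2 <- removeBaselineDWT(raw2, dwt_level)
  sig <- cbind(m1, m2)
  colnames(sig) <- c("HEOG", modality2)
  methods::new("SemRecording", signals = sig, fs = samplingRate(rec),
               subjectId = subjectId(rec), intervals = intervals(rec),
               eventParams = eventParams(rec))
}
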