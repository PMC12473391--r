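# Minimal EDF (European Data Format) writer/reader for continuous
# multichannel recordings. 16-bit samples, 1-second data records, physical
# dimension uV. Covers the subset of the format this package emits.

padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

writeEdf <- function(rec, path) {
  sig <- rec@signals
  fs <- rec@fs
  n <- nrow(sig)
  stopIfNot(abs(fs - round(fs)) < 1e-9, "EDF export requires an integer fs")
  stopIfNot(n %% fs == 0,
            "EDF export requires a whole number of 1-second records")
  nrec <- n %/% fs
  ns <- ncol(sig)
  physMax <- pmax(apply(abs(sig), 2, max), 1)
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(rec@subjectId, 80),
    padField("semscan recording", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (1 + ns), 8),
    padField("", 44),
    padField(nrec, 8),
    padField(1, 8),
    padField(ns, 4)
  )
  sigHdr <- paste0(
    paste(vapply(colnames(sig), padField, "", width = 16), collapse = ""),
    strrep(padField("", 80), ns),
    strrep(padField("uV", 8), ns),
    paste(vapply(-physMax, padField, "", width = 8), collapse = ""),
    paste(vapply(physMax, padField, "", width = 8), collapse = ""),
    strrep(padField(-digMax, 8), ns),
    strrep(padField(digMax, 8), ns),
    strrep(padField("", 80), ns),
    strrep(padField(fs, 8), ns),
    strrep(padField("", 32), ns)
  )
  writeChar(paste0(hdr, sigHdr), con, eos = NULL)
  dig <- matrix(0L, n, ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round(pmin(pmax(sig[, j] / physMax[j], -1), 1) * digMax))
  for (r in seq_len(nrec)) {
    rows <- seq.int((r - 1) * fs + 1, r * fs)
    for (j in seq_len(ns))
      writeBin(dig[rows, j], con, size = 2, endian = "little")
  }
  invisible(path)
}

readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  subject <- rd(80)
  rd(80); rd(8); rd(8)        # recording id, date, time
  rd(8); rd(44)               # header bytes, reserved
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)            # prefiltering
  npr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)            # reserved
  fs <- npr[1] / recDur
  out <- matrix(0, nrec * npr[1], ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = npr[j], size = 2, endian = "little")
      scale <- (physMax[j] - physMin[j]) / (digMax[j] - digMin[j])
      out[(r - 1) * npr[j] + seq_len(npr[j]), j] <-
        physMin[j] + (d - digMin[j]) * scale
    }
  }
  colnames(out) <- labels
  methods::new("SemRecording", signals = out, fs = fs, subjectId = subject)
}
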