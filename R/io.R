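#' Read a recording from disk
#'
#' CSV files carry columns `time_s` plus one column per channel (channels
#' `Hl`, `Hr` required, `O2` optional), comma-separated with a header row
#' and `.` decimal; the sampling rate is taken from `fs` or inferred from
#' `time_s`. EDF files carry the rate in their header.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"` (default: by file extension).
#' @param fs sampling rate in Hz (CSV only; inferred from `time_s` if `NULL`).
#' @param subject_id subject identifier to attach (CSV only).
#' @return a [SemRecording-class].
#' @export
readRecording <- function(path, format = NULL, fs = NULL, subject_id = "S00") {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("csv", "edf"))
  if (format == "edf") return(readEdf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("Hl", "Hr") %in% names(df)))
    stop("channel error: CSV must contain Hl and Hr columns", call. = FALSE)
  if (is.null(fs)) {
    stopIfNot("time_s" %in% names(df),
              "fs not given and no time_s column to infer it from")
    fs <- 1 / stats::median(diff(df$time_s))
  }
  chans <- setdiff(names(df), "time_s")
  sig <- as.matrix(df[, chans, drop = FALSE])
  if (!all(is.finite(sig)))
    stop("format error: non-finite samples in CSV", call. = FALSE)
  methods::new("SemRecording", signals = sig, fs = fs, subjectId = subject_id)
}

#' Write a recording to disk
#'
#' @param rec a [SemRecording-class].
#' @param path output path.
#' @param format `"csv"` or `"edf"` (default: by file extension).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("csv", "edf"))
  if (format == "edf") return(invisible(writeEdf(rec, path)))
  n <- nSamples(rec)
  df <- data.frame(time_s = (seq_len(n) - 1) / samplingRate(rec))
  for (ch in channelNames(rec)) df[[ch]] <- rec@signals[, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validateIntervals <- function(df) {
  stopIfNot(all(c("start_s", "end_s", "label") %in% names(df)),
            "labels need columns start_s, end_s, label")
  bad <- which(!(df$start_s >= 0 & df$start_s < df$end_s))
  if (length(bad))
    stop(sprintf("validation error: rows with start_s >= end_s or negative start: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  stopIfNot(all(df$label %in% c("SEM", "NONSEM")),
            "labels must be SEM or NONSEM")
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    ov <- which(df$start_s[-1] < df$end_s[-nrow(df)])
    if (length(ov))
      stop(sprintf("validation error: overlapping intervals at rows: %s",
                   paste(ov, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read / write labeled SEM intervals
#'
#' CSV with header `start_s,end_s,label`; labels are `SEM` or `NONSEM` and
#' intervals are half-open `[start_s, end_s)` seconds. Intervals are sorted
#' and validated (non-negative, start before end, non-overlapping) on read
#' and write.
#'
#' @param path file path.
#' @return sorted, validated `data.frame` of intervals.
#' @export
readLabels <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  validateIntervals(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readLabels
#' @param intervals `data.frame` with columns `start_s`, `end_s`, `label`.
#' @export
writeLabels <- function(intervals, path) {
  df <- validateIntervals(intervals)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

windowSetMeta <- function(ws) S4Vectors::metadata(ws)

#' Save / load a window dataset
#'
#' Lossless round trip of a [SemWindowSet-class] through a single Parquet
#' file: sample vectors, labels, ordering and metadata (sampling rate,
#' window length, modality pair, subject) are all preserved bit-exactly.
#'
#' @param ws a [SemWindowSet-class].
#' @param path output `.parquet` path.
#' @return `path` invisibly (`saveWindowSet`); a [SemWindowSet-class]
#'   (`loadWindowSet`).
#' @export
saveWindowSet <- function(ws, path) {
  stopIfNot(methods::is(ws, "SemWindowSet"), "ws must be a SemWindowSet")
  n <- ncol(ws)
  stopIfNot(n > 0, "validation error: refusing to save an empty dataset")
  x1 <- SummarizedExperiment::assay(ws, "x1")
  x2 <- SummarizedExperiment::assay(ws, "x2")
  L <- nrow(x1)
  df <- data.frame(label = as.integer(ws$label), t_start = ws$t_start)
  m1 <- as.data.frame(t(x1)); names(m1) <- sprintf("x1_%03d", seq_len(L))
  m2 <- as.data.frame(t(x2)); names(m2) <- sprintf("x2_%03d", seq_len(L))
  tab <- arrow::arrow_table(cbind(df, m1, m2))
  tab$metadata[["semscan"]] <-
    jsonlite::toJSON(windowSetMeta(ws), auto_unbox = TRUE, digits = NA)
  arrow::write_parquet(tab, path)
  invisible(path)
}

#' @rdname saveWindowSet
#' @export
loadWindowSet <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  tab <- tryCatch(arrow::read_parquet(path, as_data_frame = FALSE),
                  error = function(e)
                    stop(sprintf("load error: corrupt window container: %s",
                                 conditionMessage(e)), call. = FALSE))
  meta <- jsonlite::fromJSON(tab$metadata[["semscan"]] %||% "{}")
  df <- as.data.frame(tab)
  c1 <- grep("^x1_", names(df)); c2 <- grep("^x2_", names(df))
  newSemWindowSet(t(as.matrix(df[, c1])), t(as.matrix(df[, c2])),
                  label = df$label, t_start = df$t_start, meta = meta)
}

# internal constructor
newSemWindowSet <- function(x1, x2, label, t_start, meta = list()) {
  dimnames(x1) <- NULL; dimnames(x2) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x1 = x1, x2 = x2),
    colData = S4Vectors::DataFrame(label = as.integer(label),
                                   t_start = as.numeric(t_start)),
    metadata = meta)
  methods::new("SemWindowSet", se)
}
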