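#' @import methods
#' @importFrom stats rnorm runif fft sd median cor quantile
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Multichannel electrophysiological recording
#'
#' Container for a fixed-rate multichannel recording in microvolts. The two
#' outer-canthus horizontal EOG electrodes `Hl` and `Hr` are the required
#' channels; an occipital EEG channel `O2` is optional. Labeled SEM /
#' non-SEM intervals (and, for simulated recordings, the generating event
#' parameters) travel with the object.
#'
#' @slot signals numeric matrix, samples x channels, in microvolts; column
#'   names are the channel names.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot intervals data.frame with columns `start_s`, `end_s`, `label`
#'   (`"SEM"` / `"NONSEM"`); possibly empty. Intervals are half-open
#'   `[start_s, end_s)` in seconds from recording start.
#' @slot eventParams data.frame of per-SEM-event generator parameters
#'   (empty for recordings read from disk).
#'
#' @seealso [simulateRecording()], [readRecording()]
#' @export
setClass("SemRecording",
  representation(
    signals = "matrix",
    fs = "numeric",
    subjectId = "character",
    intervals = "data.frame",
    eventParams = "data.frame"
  ),
  prototype(
    signals = matrix(numeric(0), 0, 0),
    fs = 500,
    subjectId = "S00",
    intervals = data.frame(start_s = numeric(0), end_s = numeric(0),
                           label = character(0), stringsAsFactors = FALSE),
    eventParams = data.frame()
  )
)

setValidity("SemRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@signals)) msg <- c(msg, "signals must be numeric")
  if (length(object@signals) && !all(is.finite(object@signals)))
    msg <- c(msg, "signals contain non-finite samples (NaN/Inf rejected)")
  if (is.null(colnames(object@signals)) && ncol(object@signals) > 0)
    msg <- c(msg, "signal columns must be named channels")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  iv <- object@intervals
  if (nrow(iv)) {
    if (!all(c("start_s", "end_s", "label") %in% names(iv)))
      msg <- c(msg, "intervals need columns start_s, end_s, label")
    else if (any(iv$start_s >= iv$end_s))
      msg <- c(msg, "intervals must satisfy start_s < end_s")
  }
  if (length(msg)) msg else TRUE
})

#' Windowed two-class SEM dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding fixed-length
#' bimodal window samples. Assay `x1` is modality 1 (median-smoothed HEOG)
#' and assay `x2` modality 2 (baseline-corrected O2 or HSUM), each a
#' `window_length x n_windows` matrix. `colData` carries the binary label
#' (`1` = SEM) and window start time.
#'
#' @seealso [extractWindows()], [saveWindowSet()]
#' @export
setClass("SemWindowSet", contains = "SummarizedExperiment")

setValidity("SemWindowSet", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("x1", "x2") %in% an)) msg <- c(msg, "assays x1 and x2 required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "t_start") %in% names(cd)))
    msg <- c(msg, "colData needs columns label and t_start")
  else if (!all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (non-SEM) or 1 (SEM)")
  if (length(msg)) msg else TRUE
})

#' Trained SEM classifier
#'
#' Holds a network (parallel bimodal architecture), its configuration, the
#' training configuration and per-epoch history.
#'
#' @slot config model configuration list, see [modelConfig()].
#' @slot params nested list of numeric parameter arrays.
#' @slot trainConfig training configuration list, see [trainConfig()].
#' @slot history data.frame of per-epoch training/validation loss and accuracy.
#' @slot classWeights numeric length-2 loss weights (non-SEM, SEM).
#' @export
setClass("SemModel",
  representation(
    config = "list",
    params = "list",
    trainConfig = "list",
    history = "data.frame",
    classWeights = "numeric"
  )
)
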