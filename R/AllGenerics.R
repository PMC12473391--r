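#' @rdname SemRecording-class
#' @param object,x a `SemRecording`
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname SemRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname SemRecording-class
#' @param name channel name
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname SemRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SemRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SemRecording-class
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname SemRecording-class
#' @export
setGeneric("eventParams", function(x) standardGeneric("eventParams"))

#' @export
setMethod("samplingRate", "SemRecording", function(x) x@fs)

#' @export
setMethod("channelNames", "SemRecording", function(x) colnames(x@signals))

#' @export
setMethod("channel", "SemRecording", function(x, name) {
  if (!name %in% colnames(x@signals))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(colnames(x@signals), collapse = ", ")), call. = FALSE)
  x@signals[, name]
})

#' @export
setMethod("nSamples", "SemRecording", function(x) nrow(x@signals))

#' @export
setMethod("subjectId", "SemRecording", function(x) x@subjectId)

#' @export
setMethod("intervals", "SemRecording", function(x) x@intervals)

#' @export
setMethod("eventParams", "SemRecording", function(x) x@eventParams)

#' Duration of a recording in seconds
#' @param x a `SemRecording`
#' @export
recordingDuration <- function(x) nSamples(x) / samplingRate(x)

setMethod("show", "SemRecording", function(object) {
  cat(sprintf("SemRecording '%s': %d channels x %d samples (%.1f s at %g Hz)\n",
              object@subjectId, ncol(object@signals), nrow(object@signals),
              nrow(object@signals) / object@fs, object@fs))
  cat("  channels:", paste(colnames(object@signals), collapse = ", "), "\n")
  iv <- object@intervals
  if (nrow(iv))
    cat(sprintf("  intervals: %d (%d SEM, %d non-SEM)\n", nrow(iv),
                sum(iv$label == "SEM"), sum(iv$label != "SEM")))
})

setMethod("show", "SemModel", function(object) {
  cat(sprintf("SemModel variant '%s'", object@config$variant))
  ab <- unlist(object@config[c("no_transformer", "no_cnn", "no_residual", "no_ffn")])
  if (any(ab)) cat(" [ablation:", paste(names(ab)[ab], collapse = ","), "]")
  cat("\n")
  cat(sprintf("  kernels (%d, %d | %d, %d), d_model %d, heads %d, encoder layers %d\n",
              object@config$kernels[1], object@config$kernels[2],
              object@config$kernels[3], object@config$kernels[4],
              object@config$d_model, object@config$heads, object@config$n_layers))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best val accuracy %.4f\n",
                nrow(object@history), max(object@history$val_acc)))
})
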