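# Accessor generics and show methods.

#' @rdname EEGRecording-class
#' @param object an object.
#' @export
setGeneric("channelData", function(object) standardGeneric("channelData"))
#' @rdname EEGRecording-class
#' @export
setGeneric("triggerChannel", function(object) standardGeneric("triggerChannel"))
#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname TrialSet-class
#' @param object an object.
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))
#' @rdname EpochSet-class
#' @param object an object.
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))
#' @rdname EpochSet-class
#' @export
setGeneric("validFlags", function(object) standardGeneric("validFlags"))
#' @rdname FeatureMatrix-class
#' @param object an object.
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureIndex", function(object) standardGeneric("featureIndex"))
#' @rdname FeatureMatrix-class
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname DecodingResult-class
#' @param object an object.
#' @export
setGeneric("accuracyTable", function(object) standardGeneric("accuracyTable"))

#' @rdname EEGRecording-class
setMethod("channelData", "EEGRecording", function(object) object@data)
#' @rdname EEGRecording-class
setMethod("triggerChannel", "EEGRecording", function(object) object@trig)
#' @rdname EEGRecording-class
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname EEGRecording-class
setMethod("channelLabels", "EEGRecording",
          function(object) rownames(object@data))
#' @rdname TrialSet-class
setMethod("samplingRate", "TrialSet", function(object) object@fs)
#' @rdname TrialSet-class
setMethod("channelLabels", "TrialSet", function(object) object@channelLabels)
#' @rdname TrialSet-class
setMethod("schedule", "TrialSet", function(object) object@schedule)
#' @rdname BehaviouralRecord-class
#' @param object an object.
setMethod("schedule", "BehaviouralRecord", function(object) object@trialTable)
#' @rdname EpochSet-class
setMethod("epochArray", "EpochSet", function(object) object@epochs)
#' @rdname EpochSet-class
setMethod("validFlags", "EpochSet", function(object) object@valid)
#' @rdname EpochSet-class
setMethod("classLabels", "EpochSet", function(object) object@labels)
#' @rdname FeatureMatrix-class
setMethod("featureData", "FeatureMatrix", function(object) object@X)
#' @rdname FeatureMatrix-class
setMethod("featureIndex", "FeatureMatrix", function(object) object@featureIndex)
#' @rdname FeatureMatrix-class
setMethod("classLabels", "FeatureMatrix", function(object) object@y)
#' @rdname DecodingResult-class
setMethod("accuracyTable", "DecodingResult", function(object) object@results)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording", object@participantId, "\n")
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat("  channels:", paste(rownames(object@data), collapse = ", "), "\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples at %g Hz\n",
              d[1], d[2], d[3], object@fs))
  if (nrow(object@schedule))
    cat("  distractor:",
        paste(names(table(object@schedule$distractor)),
              table(object@schedule$distractor), collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs (%g s window, %g s step), %d valid\n",
              d[1], object@window, object@step, sum(object@valid)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d epochs x %d features (variant '%s')\n",
              nrow(object@X), ncol(object@X), object@variant))
  cat("  classes:", paste(names(table(object@y)), table(object@y),
                          collapse = ", "), "\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d cells\n", nrow(object@results)))
  if (nrow(object@results)) {
    agg <- stats::aggregate(accuracy ~ classifier + regime, object@results,
                            mean)
    print(agg, row.names = FALSE)
  }
})

setMethod("show", "WindowModelFit", function(object) {
  cat(sprintf(
    "WindowModelFit: ACC = %.2f * (1 - exp(-%.3f * (T - %.3f))), SSE %.4g\n",
    object@a, object@s, object@i, object@sse))
})

setMethod("show", "BehaviouralRecord", function(object) {
  cat(sprintf("BehaviouralRecord: %d trials x %d targets (%.1f%% correct)\n",
              nrow(object@acc), ncol(object@acc),
              100 * mean(object@acc == 1L)))
})
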