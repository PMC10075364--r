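#' @rdname LfpRecording-class
#' @param object,x an object.
#' @export
setGeneric("lfpData", function(object) standardGeneric("lfpData"))

#' @rdname LfpRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname LfpRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname LfpRecording-class
#' @export
setGeneric("ttlTimes", function(object) standardGeneric("ttlTimes"))

#' @rdname LfpRecording-class
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname Comodulogram-class
#' @param object an object.
#' @export
setGeneric("miMatrix", function(object) standardGeneric("miMatrix"))

#' @rdname TPacSeries-class
#' @param object an object.
#' @export
setGeneric("miValues", function(object) standardGeneric("miValues"))

#' @rdname TPacSeries-class
#' @export
setGeneric("subjectMean", function(object) standardGeneric("subjectMean"))

setMethod("lfpData", "LfpRecording", function(object) object@data)
setMethod("samplingRate", "LfpRecording", function(object) object@fs)
setMethod("samplingRate", "PowerSpectrum", function(object) object@fs)
setMethod("samplingRate", "RipplePower", function(object) object@fs)
setMethod("channelLabels", "LfpRecording", function(object) object@channelLabels)
setMethod("ttlTimes", "LfpRecording", function(object) object@ttl)
setMethod("ttlTimes", "TrackingTrace", function(object) object@ttl)
setMethod("nChannels", "LfpRecording", function(object) nrow(object@data))
setMethod("miMatrix", "Comodulogram", function(object) object@mi)
setMethod("miValues", "TPacSeries", function(object) object@mi)
setMethod("subjectMean", "TPacSeries", function(object) mean(object@mi))

#' @describeIn LfpRecording-class recording duration in seconds.
#' @export
setMethod("length", "LfpRecording", function(x) ncol(x@data))

setMethod("show", "LfpRecording", function(object) {
  cat(sprintf(
    "LfpRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
    nrow(object@data), ncol(object@data),
    ncol(object@data) / object@fs, object@fs))
  tab <- table(object@channelLabels)
  cat("  channels:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  cat(sprintf("  %d TTL pulse(s)\n", length(object@ttl)))
})

setMethod("show", "TrackingTrace", function(object) {
  cat(sprintf(
    "TrackingTrace: %d frames (%.1f s at %g fps), arena %.2f m\n",
    length(object@t), diff(range(object@t)), object@frameRate,
    object@arenaSide))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf(
    "PowerSpectrum: %d bins, %.2f-%.1f Hz (df %.3f Hz), %d segment(s)\n",
    length(object@freq), min(object@freq), max(object@freq),
    if (length(object@freq) > 1) diff(object@freq[1:2]) else NA_real_,
    object@nSegments))
})

setMethod("show", "Comodulogram", function(object) {
  idx <- which(object@mi == max(object@mi), arr.ind = TRUE)[1, ]
  cat(sprintf(
    "Comodulogram: %d phase x %d amplitude bins over %d epoch(s)\n",
    nrow(object@mi), ncol(object@mi), object@nEpochs))
  cat(sprintf("  peak MI %.4f at (%g Hz phase, %g Hz amplitude)\n",
              max(object@mi), object@phaseFreqs[idx[1]],
              object@ampFreqs[idx[2]]))
})

setMethod("show", "TPacSeries", function(object) {
  cat(sprintf(
    "TPacSeries: %d windows of %g s, bands %g-%g Hz / %g-%g Hz, mean MI %.4f\n",
    length(object@mi), object@epochLen,
    object@phaseBand[1], object@phaseBand[2],
    object@ampBand[1], object@ampBand[2], mean(object@mi)))
})

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf(
    "SessionConfig: %d channels at %g Hz, %.0f s total, seed %d\n",
    object@nChannels, object@fs, sum(object@stateSchedule$duration),
    object@seed))
  cat("  schedule:", paste(sprintf("%s %.0fs", object@stateSchedule$state,
                                   object@stateSchedule$duration),
                           collapse = " | "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d SWR event(s), %d labeled frame(s)\n",
    nrow(object@swrEvents), length(object@frameState)))
})

setMethod("show", "RipplePower", function(object) {
  cat(sprintf(
    "RipplePower: %d samples at %g Hz, %d segment(s)\n",
    length(object@power), object@fs, nrow(object@segments)))
})
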