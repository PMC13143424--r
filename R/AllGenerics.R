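#' @rdname Montage-class
#' @param object,x a \code{Montage} or \code{EEGWindow}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Montage-class
#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))

#' @rdname Montage-class
#' @export
setGeneric("channelRanks", function(x) standardGeneric("channelRanks"))

#' @rdname Montage-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGWindow-class
#' @export
setGeneric("windowData", function(x) standardGeneric("windowData"))

#' @rdname EEGWindow-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGWindow-class
#' @export
setGeneric("windowLabel", function(x) standardGeneric("windowLabel"))

#' @rdname EEGWindow-class
#' @export
setGeneric("windowMontage", function(x) standardGeneric("windowMontage"))

setMethod("channelNames", "Montage", function(x) x@names)
setMethod("electrodePositions", "Montage", function(x) {
  p <- x@positions; rownames(p) <- x@names; colnames(p) <- c("x", "y", "z"); p
})
setMethod("channelRanks", "Montage", function(x) x@rank)
setMethod("nChannels", "Montage", function(x) length(x@names))

setMethod("channelNames", "EEGWindow", function(x) x@montage@names)
setMethod("nChannels", "EEGWindow", function(x) nrow(x@data))
setMethod("windowData", "EEGWindow", function(x) x@data)
setMethod("samplingRate", "EEGWindow", function(x) x@rate)
setMethod("windowLabel", "EEGWindow", function(x) x@label)
setMethod("windowMontage", "EEGWindow", function(x) x@montage)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d electrodes on the unit sphere\n",
              length(object@names)))
  nm <- object@names
  cat("  ", paste(utils::head(nm, 10), collapse = " "),
      if (length(nm) > 10) "..." else "", "\n")
})

setMethod("show", "EEGWindow", function(object) {
  cat(sprintf("EEGWindow: %d channels x %d samples @ %g Hz (%.3g s), label %d\n",
              nrow(object@data), ncol(object@data), object@rate,
              object@duration, object@label))
})

setMethod("show", "SRTask", function(object) {
  if (object@mode == "spatial")
    cat(sprintf("SRTask: spatial x%d (%d LR channels)\n",
                object@factor, length(object@lrChannels)))
  else
    cat(sprintf("SRTask: temporal x%d (LR rate %g Hz)\n",
                object@factor, object@lrRate))
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf(
    "NoiseSchedule: T=%d, beta in [%.2e, %.2e], prediction '%s', clip=%s\n",
    object@nSteps, min(object@beta), max(object@beta),
    object@predictionType, object@clipSamples))
})
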