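#' @rdname TrackSet-class
#' @param object,x an object.
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname GroundTruth-class
#' @export
setGeneric("contactIntervals", function(x) standardGeneric("contactIntervals"))

#' @rdname GroundTruth-class
#' @export
setGeneric("decelFactors", function(x) standardGeneric("decelFactors"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameArray", function(x) standardGeneric("frameArray"))

#' @rdname FrameStack-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname LabelImage-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname ScreenResult-class
#' @export
setGeneric("passingPairs", function(x) standardGeneric("passingPairs"))

#' @rdname ScreenResult-class
#' @export
setGeneric("screenCounts", function(x) standardGeneric("screenCounts"))

#' @rdname SDISeries-class
#' @export
setGeneric("sdiSamples", function(x) standardGeneric("sdiSamples"))

#' @rdname SDISeries-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("phaseFrames", function(x, phase) standardGeneric("phaseFrames"))

setMethod("trackTable", "TrackSet", function(x) x@points)
setMethod("trackIds", "TrackSet", function(x) unique(x@points$track_id))
setMethod("trackTable", "GroundTruth", function(x) x@trackSet@points)
setMethod("contactIntervals", "GroundTruth", function(x) x@contacts)
setMethod("decelFactors", "GroundTruth", function(x) x@factors)
setMethod("frameArray", "FrameStack", function(x) x@data)
setMethod("channelRoles", "FrameStack", function(x) x@channels)
setMethod("labelMatrix", "LabelImage", function(x) x@labels)
setMethod("passingPairs", "ScreenResult", function(x) x@pass)
setMethod("screenCounts", "ScreenResult", function(x)
    c(pass = nrow(x@pass), fail = nrow(x@fail),
      unevaluable = nrow(x@unevaluable)))
setMethod("sdiSamples", "SDISeries", function(x) x@samples)
setMethod("modality", "SDISeries", function(x) x@modality)

#' @rdname PhaseSegmentation-class
#' @param phase one of "ph1", "ph2", "ph3".
setMethod("phaseFrames", "PhaseSegmentation", function(x, phase) {
    slot(x, match.arg(phase, c("ph1", "ph2", "ph3")))
})

setMethod("show", "TrackSet", function(object) {
    p <- object@points
    cat(sprintf("TrackSet: %d tracks (%s), %d points, frames %d..%d\n",
        length(unique(p$track_id)),
        paste(sprintf("%s=%d", names(table(p$cell_type[!duplicated(p$track_id)])),
                      table(p$cell_type[!duplicated(p$track_id)])),
              collapse = ", "),
        nrow(p), min(p$frame), max(p$frame)))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d tracks, %d scripted contacts, seed %d\n",
        length(unique(object@trackSet@points$track_id)),
        nrow(object@contacts), object@config@seed))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: T=%d NK=%d cells, %d frames x %gs, arena %g um,\n",
        "  speeds T=%g NK=%g um/s, contact radius %g um, noise %g, seed %d\n"),
        object@nCells[["T"]], object@nCells[["NK"]], object@nFrames,
        object@frameInterval, object@arenaSize,
        object@baseSpeed[["T"]], object@baseSpeed[["NK"]],
        object@contactRadius, object@noiseSdFrac, object@seed))
})

setMethod("show", "PhaseSegmentation", function(object) {
    fmt <- function(v) if (length(v)) sprintf("%d..%d", min(v), max(v)) else "empty"
    cat(sprintf("PhaseSegmentation: Ph1 %s | Ph2 %s | Ph3 %s\n",
        fmt(object@ph1), fmt(object@ph2), fmt(object@ph3)))
})

setMethod("show", "SDISeries", function(object) {
    cat(sprintf("SDISeries %s~%s (%s): %d samples, epsilon %g\n",
        object@pair[1], object@pair[2], object@modality,
        nrow(object@samples), object@epsilon))
})

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("FrameStack: %d frames, channels [%s], %dx%d px (%g um/px)\n",
        d[1], paste(object@channels, collapse = ", "), d[3], d[4],
        object@pixelSize))
})

setMethod("show", "LabelImage", function(object) {
    cat(sprintf("LabelImage: %dx%d px, %d labels\n",
        nrow(object@labels), ncol(object@labels), max(object@labels)))
})

setMethod("show", "ProximityResult", function(object) {
    cat(sprintf("ProximityResult: %d pair-distances, %d close / %d distant (<= %g px)\n",
        length(object@distances), sum(object@labels == "close"),
        sum(object@labels == "distant"), object@threshold))
})

setMethod("show", "ScreenResult", function(object) {
    n <- screenCounts(object)
    cat(sprintf("ScreenResult @ >=%g TPM (%s): %d pass, %d fail, %d unevaluable\n",
        object@threshold, object@direction, n["pass"], n["fail"],
        n["unevaluable"]))
})

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(paste0(
        "PipelineConfig: pixel %g um, frame %g s, contact <= %g um x >= %d fr,\n",
        "  proximity <= %g px (hist bin %g px), SDI eps %g bin %g s, ",
        "TPM thresholds [%s], mode '%s'\n"),
        object@pixelSize, object@frameInterval, object@contactDistance,
        object@minContactFrames, object@proximityThresholdPx, object@histBinPx,
        object@epsilon, object@sdiBinWidth,
        paste(object@lrThresholds, collapse = ", "), object@velocityMode))
})
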