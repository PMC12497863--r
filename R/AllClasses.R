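#' @import methods
NULL

.CELL_TYPES <- c("T", "NK")

#' Simulation configuration
#'
#' Parameters of the synthetic time-lapse generator: two motile cell
#' populations (CD8 T and NK) performing a step-wise random walk in a square
#' arena with reflecting boundaries, with scripted T-NK contact windows
#' during which the T cell's speed is scaled by a per-cell deceleration
#' factor and the partner NK cell is held within the contact radius.
#'
#' @slot nCells named integer, cells per type (`T`, `NK`).
#' @slot arenaSize side length of the square arena (micrometres).
#' @slot nFrames number of frames (>= 3).
#' @slot frameInterval time between frames (seconds).
#' @slot baseSpeed named numeric, free speed per type (micrometres/second).
#' @slot decelFactors per-T-cell speed multiplier applied during its contact
#'   window; recycled to `nCells["T"]`. Values in (0, 1].
#' @slot contactRadius centroid distance defining a scripted contact
#'   (micrometres).
#' @slot noiseSdFrac Gaussian step-length noise, as a fraction of speed.
#' @slot transferPixels pixels of membrane signal moved per contact event;
#'   recycled across events.
#' @slot pixelSize micrometres per pixel when rendering.
#' @slot cellRadius rendered cell radius (micrometres).
#' @slot contactStart first frame of the scripted windows; `NA` draws each
#'   window start uniformly from the middle of the movie.
#' @slot contactLen length of each scripted window (frames).
#' @slot seed integer seed; mandatory, all randomness flows from it.
#' @export
setClass("SimConfig", representation(
    nCells = "integer",
    arenaSize = "numeric",
    nFrames = "integer",
    frameInterval = "numeric",
    baseSpeed = "numeric",
    decelFactors = "numeric",
    contactRadius = "numeric",
    noiseSdFrac = "numeric",
    transferPixels = "integer",
    pixelSize = "numeric",
    cellRadius = "numeric",
    contactStart = "integer",
    contactLen = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!identical(sort(names(object@nCells)), sort(.CELL_TYPES)))
        msg <- c(msg, "nCells must be named with 'T' and 'NK'")
    if (any(object@nCells < 0L))
        msg <- c(msg, "cell counts must be non-negative")
    if (object@nFrames < 3L)
        msg <- c(msg, "nFrames must be >= 3")
    if (object@arenaSize <= 0 || object@frameInterval <= 0 ||
        object@pixelSize <= 0 || object@cellRadius <= 0)
        msg <- c(msg, "lengths and intervals must be positive")
    if (any(object@baseSpeed <= 0))
        msg <- c(msg, "base speeds must be positive")
    if (length(object@decelFactors) &&
        any(object@decelFactors <= 0 | object@decelFactors > 1))
        msg <- c(msg, "deceleration factors must lie in (0, 1]")
    if (object@contactRadius <= 0)
        msg <- c(msg, "contactRadius must be positive")
    if (object@contactRadius >= object@arenaSize)
        msg <- c(msg, "contactRadius must be smaller than the arena")
    if (object@noiseSdFrac < 0)
        msg <- c(msg, "noiseSdFrac must be >= 0")
    if (any(object@transferPixels < 0L))
        msg <- c(msg, "transferPixels must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "an integer seed is mandatory")
    if (!is.na(object@contactStart) && object@contactStart < 1L)
        msg <- c(msg, "contactStart must leave at least one pre-contact frame")
    if (object@contactLen < 1L)
        msg <- c(msg, "contactLen must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Set of cell tracks
#'
#' Time-ordered positions of tracked cells, the substrate of all kinetic
#' analyses. One row per cell per frame.
#'
#' @slot points data.frame with columns `track_id`, `cell_type` ("T" or
#'   "NK"), `frame` (integer, 0-based), `t_s` (seconds), `x_um`, `y_um`.
#' @slot pixelSize micrometres per pixel (for conversion to pixel units).
#' @slot frameInterval seconds between frames.
#' @export
setClass("TrackSet", representation(
    points = "data.frame",
    pixelSize = "numeric",
    frameInterval = "numeric"
))

setValidity("TrackSet", function(object) {
    p <- object@points
    need <- c("track_id", "cell_type", "frame", "t_s", "x_um", "y_um")
    if (!all(need %in% names(p)))
        return(paste("points must have columns:", paste(need, collapse = ", ")))
    if (!all(p$cell_type %in% .CELL_TYPES))
        return("cell_type must be 'T' or 'NK'")
    if (any(!is.finite(p$x_um)) || any(!is.finite(p$y_um)))
        return("coordinates must be finite")
    for (id in unique(p$track_id)) {
        q <- p[p$track_id == id, ]
        if (nrow(q) < 2L)
            return(sprintf("track '%s' has fewer than 2 points", id))
        if (is.unsorted(q$frame, strictly = TRUE))
            return(sprintf("track '%s': frames not strictly increasing", id))
        if (is.unsorted(q$t_s, strictly = TRUE))
            return(sprintf("track '%s': times not strictly increasing", id))
        if (length(unique(q$cell_type)) != 1L)
            return(sprintf("track '%s' has multiple cell types", id))
    }
    TRUE
})

#' Ground truth of a simulation
#'
#' Everything needed to validate the downstream pipeline against the
#' generator: the tracks, the scripted contact intervals, and the per-cell
#' deceleration factors actually applied.
#'
#' @slot trackSet a [TrackSet-class].
#' @slot contacts data.frame with `focal_id`, `partner_id`, `start_frame`,
#'   `end_frame` (inclusive, 0-based).
#' @slot factors named numeric, true deceleration factor per T track.
#' @slot config the [SimConfig-class] that produced it.
#' @export
setClass("GroundTruth", representation(
    trackSet = "TrackSet",
    contacts = "data.frame",
    factors = "numeric",
    config = "SimConfig"
))

#' Phase segmentation of a track around one contact episode
#'
#' Frames before (Ph1), during (Ph2) and after (Ph3) direct contact with a
#' partner cell. Ph1/Ph3 may be empty; Ph2 never is. The three ranges
#' partition the track's frame span contiguously.
#'
#' @slot ph1,ph2,ph3 integer frame vectors.
#' @export
setClass("PhaseSegmentation", representation(
    ph1 = "integer", ph2 = "integer", ph3 = "integer"
))

setValidity("PhaseSegmentation", function(object) {
    if (!length(object@ph2)) return("ph2 must be non-empty")
    all3 <- c(object@ph1, object@ph2, object@ph3)
    if (anyDuplicated(all3)) return("phases must be disjoint")
    if (is.unsorted(all3, strictly = TRUE))
        return("phases must be ordered ph1 < ph2 < ph3")
    TRUE
})

#' Speed-Distance Index series for one cell pair
#'
#' Per-frame SDI = v_rel / (d + epsilon) where v_rel is the magnitude of the
#' difference of the two cells' velocity vectors and d their Euclidean
#' distance. Units are 1/time.
#'
#' @slot pair character(2), focal and partner track ids.
#' @slot modality one of "NK-NK", "NK-T", "T-T".
#' @slot samples data.frame with `frame`, `t_s`, `v_rel`, `d`, `sdi`.
#' @slot epsilon regularizing constant in the units of `d`.
#' @export
setClass("SDISeries", representation(
    pair = "character",
    modality = "character",
    samples = "data.frame",
    epsilon = "numeric"
))

setValidity("SDISeries", function(object) {
    if (object@epsilon <= 0) return("epsilon must be > 0")
    if (!object@modality %in% c("NK-NK", "NK-T", "T-T"))
        return("modality must be one of NK-NK, NK-T, T-T")
    s <- object@samples
    if (any(s$v_rel < 0) || any(s$d < 0) || any(!is.finite(s$sdi)))
        return("v_rel and d must be >= 0 and sdi finite")
    TRUE
})

#' Proximity classification of pairwise distances
#'
#' @slot distances numeric pixel distances.
#' @slot labels "close" (distance <= threshold) or "distant".
#' @slot threshold pixels (default 250 in [classifyProximity()]).
#' @slot histogram data.frame with `bin_start`, `bin_end`, `count`
#'   (half-open bins, fixed width).
#' @export
setClass("ProximityResult", representation(
    distances = "numeric",
    labels = "character",
    threshold = "numeric",
    histogram = "data.frame"
))

#' Two-channel (plus transfer) image stack
#'
#' @slot data numeric array `[frame, channel, row, col]`, non-negative.
#' @slot channels character, role of each channel; some of "T", "NK",
#'   "transfer", unique.
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval seconds.
#' @export
setClass("FrameStack", representation(
    data = "array",
    channels = "character",
    pixelSize = "numeric",
    frameInterval = "numeric"
))

setValidity("FrameStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be [frame, channel, row, col]")
    if (d[1] < 1L) return("at least one frame required")
    if (d[2] != length(object@channels)) return("one role per channel required")
    if (anyDuplicated(object@channels)) return("channel roles must be unique")
    if (any(object@data < 0)) return("intensities must be non-negative")
    TRUE
})

#' Integer label image
#'
#' Connected-component labels per pixel, 0 = background; labels are
#' contiguous positive integers in raster-scan (row-major) order of first
#' occurrence.
#'
#' @slot labels integer matrix.
#' @export
setClass("LabelImage", representation(labels = "matrix"))

setValidity("LabelImage", function(object) {
    lab <- object@labels
    if (any(lab < 0)) return("labels must be >= 0")
    n <- max(lab)
    if (n > 0 && !all(seq_len(n) %in% lab))
        return("labels must be contiguous positive integers")
    TRUE
})

#' Result of a ligand-receptor TPM screen
#'
#' A pair passes at a threshold iff every ligand subunit clears it in the
#' ligand-expressing cell type and every receptor subunit in the
#' receptor-expressing cell type (inclusive). Pairs with any unmeasured
#' gene are unevaluable, never counted as pass or fail.
#'
#' @slot threshold TPM threshold.
#' @slot direction "forward", "reverse" or "either".
#' @slot ligandCell,receptorCell cell-type labels used in the forward
#'   direction.
#' @slot pass,fail,unevaluable data.frames of pairs (same schema as
#'   [parsePairTable()] output).
#' @export
setClass("ScreenResult", representation(
    threshold = "numeric",
    direction = "character",
    ligandCell = "character",
    receptorCell = "character",
    pass = "data.frame",
    fail = "data.frame",
    unevaluable = "data.frame"
))

#' Pipeline configuration
#'
#' Houses the analysis constants: proximity threshold 250 px and histogram
#' bin width 10 px, TPM screen thresholds 2 and 10, contact-detection
#' distance and minimum duration, SDI epsilon and bin width, velocity mode,
#' and the acquisition geometry (pixel size, frame interval).
#'
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval seconds.
#' @slot epsilon SDI regularizer (same units as distance).
#' @slot contactDistance micrometres; centroid distance defining contact.
#' @slot minContactFrames minimum consecutive frames for a contact episode.
#' @slot proximityThresholdPx close/distant cut (pixels).
#' @slot histBinPx distance histogram bin width (pixels).
#' @slot velocityMode "path" or "net".
#' @slot sdiBinWidth seconds per SDI time bin.
#' @slot lrThresholds TPM thresholds for the ligand-receptor screen.
#' @slot seed integer seed.
#' @export
setClass("PipelineConfig", representation(
    pixelSize = "numeric",
    frameInterval = "numeric",
    epsilon = "numeric",
    contactDistance = "numeric",
    minContactFrames = "integer",
    proximityThresholdPx = "numeric",
    histBinPx = "numeric",
    velocityMode = "character",
    sdiBinWidth = "numeric",
    lrThresholds = "numeric",
    seed = "integer"
))

setValidity("PipelineConfig", function(object) {
    if (object@pixelSize <= 0 || object@frameInterval <= 0 ||
        object@epsilon <= 0 || object@contactDistance <= 0 ||
        object@minContactFrames < 1L || object@proximityThresholdPx <= 0 ||
        object@histBinPx <= 0 || object@sdiBinWidth <= 0 ||
        any(object@lrThresholds <= 0))
        return("all configuration values must be positive")
    if (!object@velocityMode %in% c("path", "net"))
        return("velocityMode must be 'path' or 'net'")
    TRUE
})
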