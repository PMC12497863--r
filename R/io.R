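#' Build a pipeline configuration
#'
#' Defaults carry the analysis constants: 250 px proximity threshold, 10 px
#' histogram bins, TPM screen thresholds 2 and 10, path-mode velocities,
#' 1-hour SDI bins, and a 10 um / 2-frame contact definition.
#'
#' @param pixelSize um/px.
#' @param frameInterval s.
#' @param epsilon SDI regularizer.
#' @param contactDistance um.
#' @param minContactFrames frames.
#' @param proximityThresholdPx px.
#' @param histBinPx px.
#' @param velocityMode "path" or "net".
#' @param sdiBinWidth s.
#' @param lrThresholds TPM.
#' @param seed integer.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(pixelSize = 0.5, frameInterval = 30,
                           epsilon = 1e-6, contactDistance = 10,
                           minContactFrames = 2L,
                           proximityThresholdPx = 250, histBinPx = 10,
                           velocityMode = "path", sdiBinWidth = 3600,
                           lrThresholds = c(2, 10), seed = 1L) {
    new("PipelineConfig", pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval),
        epsilon = as.numeric(epsilon),
        contactDistance = as.numeric(contactDistance),
        minContactFrames = as.integer(minContactFrames),
        proximityThresholdPx = as.numeric(proximityThresholdPx),
        histBinPx = as.numeric(histBinPx),
        velocityMode = velocityMode,
        sdiBinWidth = as.numeric(sdiBinWidth),
        lrThresholds = as.numeric(lrThresholds),
        seed = as.integer(seed))
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `readPipelineConfig(writePipelineConfig(x))`
#' reproduces `x` exactly.
#'
#' @param config a [PipelineConfig-class].
#' @param path file path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` the restored [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
    stopifnot(is(config, "PipelineConfig"))
    sl <- slotNames(config)
    vals <- lapply(sl, function(s) slot(config, s))
    names(vals) <- sl
    yaml::write_yaml(vals, path, precision = 17)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

#' Write / read track tables as CSV
#'
#' Schema: `track_id, cell_type, frame, t_s, x_um, y_um`.
#'
#' @param trackSet a [TrackSet-class].
#' @param path file path.
#' @param pixelSize,frameInterval geometry to attach on read.
#' @return `writeTracksCSV` returns `path` invisibly; `readTracksCSV` a
#'   [TrackSet-class].
#' @export
writeTracksCSV <- function(trackSet, path) {
    stopifnot(is(trackSet, "TrackSet"))
    utils::write.csv(trackSet@points, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTracksCSV
#' @export
readTracksCSV <- function(path, pixelSize = 0.5, frameInterval = 30) {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    TrackSet(p, pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are ordered frame-major (all channels of frame 0, then frame 1,
#' ...). Intensities are stored as 32-bit floats; the round trip is
#' lossless for values in [0, 1].
#'
#' @param stack a [FrameStack-class].
#' @param path file path.
#' @param channels,pixelSize,frameInterval metadata to reattach on read.
#' @return `writeFrameStackTIFF` returns `path` invisibly;
#'   `readFrameStackTIFF` a [FrameStack-class].
#' @export
writeFrameStackTIFF <- function(stack, path) {
    stopifnot(is(stack, "FrameStack"))
    d <- dim(stack@data)
    pages <- vector("list", d[1] * d[2])
    k <- 0L
    for (f in seq_len(d[1])) for (c in seq_len(d[2])) {
        k <- k + 1L
        pages[[k]] <- matrix(stack@data[f, c, , ], d[3], d[4])
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    invisible(path)
}

#' @rdname writeFrameStackTIFF
#' @export
readFrameStackTIFF <- function(path, channels = c("T", "NK", "transfer"),
                               pixelSize = 0.5, frameInterval = 30) {
    pages <- tiff::readTIFF(path, all = TRUE)
    nc <- length(channels)
    if (length(pages) %% nc != 0L)
        stop("page count is not a multiple of the channel count")
    nf <- length(pages) %/% nc
    d3 <- nrow(pages[[1]]); d4 <- ncol(pages[[1]])
    arr <- array(0, dim = c(nf, nc, d3, d4))
    k <- 0L
    for (f in seq_len(nf)) for (c in seq_len(nc)) {
        k <- k + 1L
        arr[f, c, , ] <- pages[[k]]
    }
    new("FrameStack", data = arr, channels = channels,
        pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Write a machine-readable run summary
#'
#' Every analysis artifact carries a JSON sidecar with the configuration
#' echo, seed, package version and the run's headline counts, so results
#' are reproducible from the summary alone.
#'
#' @param path output JSON path.
#' @param config a [PipelineConfig-class] (or [SimConfig-class]).
#' @param counts named list/vector of result counts or values.
#' @param warnings named counts of warnings (excluded cells, unevaluable
#'   pairs, ...).
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(path, config, counts = list(), warnings = list()) {
    sl <- slotNames(config)
    cfg <- lapply(sl, function(s) slot(config, s))
    names(cfg) <- sl
    jsonlite::write_json(
        list(package = "SynapseKinetics",
             version = as.character(utils::packageVersion("SynapseKinetics")),
             config = cfg, counts = counts, warnings = warnings),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
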