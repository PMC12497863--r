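#' Euclidean distance between two track points
#'
#' @param a,b one-row data.frames (or lists) with `frame`, `x_um`/`x` and
#'   `y_um`/`y`; must share the same frame.
#' @return the distance, in the coordinates' unit.
#' @export
euclideanDistance <- function(a, b) {
    ax <- if (!is.null(a$x_um)) a$x_um else a$x
    ay <- if (!is.null(a$y_um)) a$y_um else a$y
    bx <- if (!is.null(b$x_um)) b$x_um else b$x
    by <- if (!is.null(b$y_um)) b$y_um else b$y
    if (!is.null(a$frame) && !is.null(b$frame) && a$frame[1] != b$frame[1])
        stop("points must share the same frame")
    sqrt((ax - bx)^2 + (ay - by)^2)
}

.backwardVelocity <- function(track, frame) {
    i <- match(frame, track$frame)
    if (is.na(i) || i == 1L) return(NULL)   # no predecessor
    dt <- track$t_s[i] - track$t_s[i - 1L]
    c((track$x_um[i] - track$x_um[i - 1L]) / dt,
      (track$y_um[i] - track$y_um[i - 1L]) / dt)
}

#' Relative speed of two cells at a frame
#'
#' Per-cell velocity vectors are estimated by backward finite difference
#' (consistent with the phase velocities); the relative speed is the
#' Euclidean norm of their difference. Undefined (NA) at a frame where
#' either track lacks a predecessor point.
#'
#' @param trackA,trackB track data.frames.
#' @param frame the frame to evaluate.
#' @return um/s, or `NA_real_` if undefined.
#' @export
relativeSpeed <- function(trackA, trackB, frame) {
    trackA <- .checkTrack(trackA); trackB <- .checkTrack(trackB)
    va <- .backwardVelocity(trackA, frame)
    vb <- .backwardVelocity(trackB, frame)
    if (is.null(va) || is.null(vb)) return(NA_real_)
    sqrt(sum((va - vb)^2))
}

#' Speed-Distance Index
#'
#' `sdi = v_rel / (d + epsilon)`: high values flag fast directed approach
#' at close range, the signature of synapse formation. The small constant
#' epsilon keeps the index finite at zero distance. Units are 1/time.
#'
#' @param vRel relative speed (>= 0).
#' @param d pairwise distance (>= 0), same length unit as `epsilon`.
#' @param epsilon regularizer (> 0).
#' @return the index (vectorized).
#' @examples
#' sdi(1, 4, 1)   # 0.2
#' @export
sdi <- function(vRel, d, epsilon = 1e-6) {
    if (any(epsilon <= 0)) stop("epsilon must be > 0")
    if (any(vRel < 0, na.rm = TRUE)) stop("vRel must be >= 0")
    if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
    vRel / (d + epsilon)
}

#' SDI series for a cell pair
#'
#' One sample per common frame at which both tracks have a defined
#' backward-difference velocity; the interaction modality (NK-NK, NK-T,
#' T-T) is derived from the tracks' cell types.
#'
#' @param trackA,trackB track data.frames with a `cell_type` column.
#' @param epsilon SDI regularizer, in the distance unit.
#' @return an [SDISeries-class].
#' @export
sdiSeries <- function(trackA, trackB, epsilon = 1e-6) {
    trackA <- .checkTrack(trackA); trackB <- .checkTrack(trackB)
    common <- sort(intersect(trackA$frame, trackB$frame))
    if (length(common) < 2L)
        stop("tracks share fewer than 2 common frames")
    types <- sort(c(trackA$cell_type[1], trackB$cell_type[1]),
                  decreasing = TRUE)  # "T" > "NK" lexicographically
    mod <- switch(paste(types, collapse = "|"),
                  "T|T" = "T-T", "T|NK" = "NK-T", "NK|NK" = "NK-NK",
                  stop("unknown cell types"))
    rows <- lapply(common, function(f) {
        vr <- relativeSpeed(trackA, trackB, f)
        if (is.na(vr)) return(NULL)
        a <- trackA[match(f, trackA$frame), ]
        b <- trackB[match(f, trackB$frame), ]
        d <- euclideanDistance(a, b)
        data.frame(frame = f, t_s = a$t_s, v_rel = vr, d = d,
                   sdi = sdi(vr, d, epsilon))
    })
    samples <- do.call(rbind, rows)
    if (is.null(samples)) stop("no frame has a defined relative speed")
    rownames(samples) <- NULL
    new("SDISeries",
        pair = c(trackA$track_id[1], trackB$track_id[1]),
        modality = mod, samples = samples, epsilon = epsilon)
}

#' Time-binned SDI summaries per interaction modality
#'
#' Samples fall into half-open time bins `[k*w, (k+1)*w)`. Within each bin
#' each pair contributes its mean SDI once (so long series do not dominate);
#' the per-bin, per-modality median and quartiles are taken over those
#' per-pair means. Empty bins are omitted.
#'
#' @param seriesList list of [SDISeries-class].
#' @param binWidth bin width in seconds (> 0).
#' @param origin "absolute" bins on the recorded times; "pair" re-zeroes
#'   each pair at its first sample (time since first observation).
#' @return data.frame with `bin`, `bin_start`, `bin_end`, `modality`,
#'   `median_sdi`, `q1`, `q3`, `n_pairs`.
#' @export
aggregateSDI <- function(seriesList, binWidth, origin = c("absolute", "pair")) {
    origin <- match.arg(origin)
    if (binWidth <= 0) stop("binWidth must be > 0")
    if (!length(seriesList)) {
        return(data.frame(bin = integer(), bin_start = numeric(),
                          bin_end = numeric(), modality = character(),
                          median_sdi = numeric(), q1 = numeric(),
                          q3 = numeric(), n_pairs = integer()))
    }
    perPair <- do.call(rbind, lapply(seriesList, function(s) {
        stopifnot(is(s, "SDISeries"))
        tt <- s@samples$t_s
        if (origin == "pair") tt <- tt - tt[1]
        bin <- floor(tt / binWidth)
        agg <- aggregate(list(sdi = s@samples$sdi), by = list(bin = bin), mean)
        agg$modality <- s@modality
        agg$pair <- paste(s@pair, collapse = "~")
        agg
    }))
    out <- do.call(rbind, lapply(
        split(perPair, list(perPair$bin, perPair$modality), drop = TRUE),
        function(g) {
            q <- quantile(g$sdi, c(0.25, 0.5, 0.75), names = FALSE)
            data.frame(bin = g$bin[1],
                       bin_start = g$bin[1] * binWidth,
                       bin_end = (g$bin[1] + 1) * binWidth,
                       modality = g$modality[1],
                       median_sdi = q[2], q1 = q[1], q3 = q[3],
                       n_pairs = nrow(g))
        }))
    out <- out[order(out$bin, out$modality), ]
    rownames(out) <- NULL
    out
}

#' Classify pairwise distances as close or distant
#'
#' Distances at or below the threshold (default 250 px) are "close",
#' otherwise "distant". A fixed-width histogram (default 10 px bins,
#' half-open `[k*w, (k+1)*w)`) is built alongside; every sample falls in
#' exactly one bin.
#'
#' @param distances non-negative pixel distances.
#' @param threshold close/distant cut in pixels.
#' @param binWidth histogram bin width in pixels.
#' @return a [ProximityResult-class].
#' @examples
#' classifyProximity(c(100, 250, 251))   # close, close, distant
#' @export
classifyProximity <- function(distances, threshold = 250, binWidth = 10) {
    if (any(distances < 0)) stop("distances must be >= 0")
    labels <- ifelse(distances <= threshold, "close", "distant")
    if (length(distances)) {
        idx <- floor(distances / binWidth)
        nb <- max(idx) + 1L
        counts <- tabulate(idx + 1L, nbins = nb)
        hist <- data.frame(bin_start = (seq_len(nb) - 1L) * binWidth,
                           bin_end = seq_len(nb) * binWidth,
                           count = counts)
    } else {
        hist <- data.frame(bin_start = numeric(), bin_end = numeric(),
                           count = integer())
    }
    new("ProximityResult", distances = as.numeric(distances),
        labels = labels, threshold = as.numeric(threshold), histogram = hist)
}
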