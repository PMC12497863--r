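.checkTrack <- function(tr) {
    need <- c("track_id", "frame", "t_s", "x_um", "y_um")
    if (!is.data.frame(tr) || !all(need %in% names(tr)))
        stop("a track needs columns: ", paste(need, collapse = ", "))
    tr[order(tr$frame), , drop = FALSE]
}

#' Detect contact episodes between two tracks
#'
#' Contact is operationalized as centroid distance at or below
#' `contactDistance` sustained for at least `minFrames` consecutive common
#' frames (the study confirms contact visually; this is the reproducible
#' surrogate). Maximal runs are returned; runs separated by one or more
#' non-contact (or missing) frames are distinct episodes.
#'
#' @param trackA,trackB track data.frames (see [getTrack()]).
#' @param contactDistance micrometres.
#' @param minFrames minimum episode length in frames (>= 1).
#' @return data.frame with `focal_id`, `partner_id`, `start_frame`,
#'   `end_frame`, `n_frames` (zero rows if no contact).
#' @examples
#' gt <- simulateTracks(simConfig(seed = 2, nCells = c(T = 1, NK = 1),
#'                                nFrames = 30, noiseSdFrac = 0))
#' tt <- trackTable(gt)
#' detectContacts(getTrack(tt, "T01"), getTrack(tt, "NK01"), 10)
#' @export
detectContacts <- function(trackA, trackB, contactDistance, minFrames = 2L) {
    trackA <- .checkTrack(trackA); trackB <- .checkTrack(trackB)
    if (minFrames < 1L) stop("minFrames must be >= 1")
    common <- intersect(trackA$frame, trackB$frame)
    if (!length(common)) stop("tracks share no common frames")
    common <- sort(common)
    a <- trackA[match(common, trackA$frame), ]
    b <- trackB[match(common, trackB$frame), ]
    d <- sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2)
    inC <- d <= contactDistance
    # split runs where frames are non-consecutive
    grp <- cumsum(c(1L, (diff(common) != 1L) | (diff(inC) != 0L)))
    out <- lapply(split(seq_along(common), grp), function(ix) {
        if (!inC[ix[1]] || length(ix) < minFrames) return(NULL)
        data.frame(focal_id = trackA$track_id[1],
                   partner_id = trackB$track_id[1],
                   start_frame = common[ix[1]],
                   end_frame = common[ix[length(ix)]],
                   n_frames = length(ix), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(focal_id = character(), partner_id = character(),
                          start_frame = integer(), end_frame = integer(),
                          n_frames = integer())
    rownames(out) <- NULL
    out
}

#' Segment a track into Ph1/Ph2/Ph3 around a contact episode
#'
#' Ph1 holds the frames strictly before the episode, Ph2 the episode
#' (inclusive on both ends), Ph3 the frames strictly after; together they
#' partition the track's frame span. An empty Ph1 (contact from the first
#' frame) is legal but flagged by downstream ratio analyses.
#'
#' @param track a track data.frame.
#' @param interval one-row data.frame (or list) with `start_frame` and
#'   `end_frame`.
#' @return a [PhaseSegmentation-class].
#' @export
segmentPhases <- function(track, interval) {
    track <- .checkTrack(track)
    s <- interval$start_frame[1]; e <- interval$end_frame[1]
    if (s > e) stop("interval start must be <= end")
    fr <- track$frame
    if (!(s %in% fr) || !(e %in% fr))
        stop("interval frames must lie within the track")
    new("PhaseSegmentation",
        ph1 = as.integer(fr[fr < s]),
        ph2 = as.integer(fr[fr >= s & fr <= e]),
        ph3 = as.integer(fr[fr > e]))
}

#' Average velocity over a phase
#'
#' "path" (default) divides the summed step displacements by the elapsed
#' time; "net" divides the straight endpoint-to-endpoint displacement by the
#' elapsed time. Phases with fewer than 2 frames have no defined velocity
#' and return `NA` (distinct from a true zero).
#'
#' @param track a track data.frame.
#' @param phase integer frame vector (e.g. from [phaseFrames()]).
#' @param mode "path" or "net".
#' @return micrometres per second, or `NA_real_` if undefined.
#' @examples
#' tr <- data.frame(track_id = "a", frame = 0:3, t_s = 0:3,
#'                  x_um = c(0, 1, 1, 2), y_um = c(0, 0, 1, 1))
#' phaseVelocity(tr, 0:3, "path")   # 1.0
#' phaseVelocity(tr, 0:3, "net")    # sqrt(5)/3
#' @export
phaseVelocity <- function(track, phase, mode = c("path", "net")) {
    mode <- match.arg(mode)
    track <- .checkTrack(track)
    q <- track[track$frame %in% phase, , drop = FALSE]
    if (nrow(q) < 2L) return(NA_real_)
    dtot <- q$t_s[nrow(q)] - q$t_s[1]
    disp <- switch(mode,
        path = sum(sqrt(diff(q$x_um)^2 + diff(q$y_um)^2)),
        net = sqrt((q$x_um[nrow(q)] - q$x_um[1])^2 +
                   (q$y_um[nrow(q)] - q$y_um[1])^2))
    disp / dtot
}

#' Deceleration ratio
#'
#' Mean contact-phase velocity divided by mean pre-contact velocity. A
#' ratio of 0.2 or below marks a five-fold (or greater) slowdown on NK
#' engagement. Undefined when the pre-contact velocity is zero or missing.
#'
#' @param vPh1 pre-contact velocity (um/s), > 0.
#' @param vPh2 contact velocity (um/s), >= 0.
#' @return dimensionless ratio, or `NA_real_` if undefined.
#' @export
decelerationRatio <- function(vPh1, vPh2) {
    ifelse(is.na(vPh1) | is.na(vPh2) | vPh1 <= 0, NA_real_, vPh2 / vPh1)
}

#' Rank cells by increasing deceleration ratio
#'
#' @param results data.frame with `track_id` and `ratio` (all defined);
#'   ties broken lexicographically by `track_id`.
#' @return the input sorted ascending with a 1-based `rank` (cell index)
#'   column.
#' @export
rankByDeceleration <- function(results) {
    if (!nrow(results)) {
        results$rank <- integer()
        return(results)
    }
    if (any(is.na(results$ratio)))
        stop("all ratios must be defined; exclude undefined cells first")
    out <- results[order(results$ratio, results$track_id), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Full contact-kinetics pipeline over a cohort
#'
#' For every T track: detect contact episodes against every NK track,
#' select the principal episode (the longest; ties resolved to the earliest
#' start, then the lexicographically smallest partner), segment phases,
#' compute per-phase velocities and the deceleration ratio. Cells with no
#' detected contact, an empty Ph1, or zero pre-contact velocity are
#' reported with `excluded = TRUE` and a reason, and are omitted from
#' ranking; their number is emitted as a message.
#'
#' @param trackSet a [TrackSet-class] (or points data.frame).
#' @param contactDistance,minFrames see [detectContacts()].
#' @param mode velocity mode, see [phaseVelocity()].
#' @return data.frame with one row per T cell: `track_id`, `partner_id`,
#'   `start_frame`, `end_frame`, `v_ph1`, `v_ph2`, `v_ph3`, `ratio`,
#'   `excluded`, `reason`, `rank` (NA for excluded cells).
#' @examples
#' gt <- simulateTracks(simConfig(seed = 1, nCells = c(T = 4, NK = 4),
#'                                nFrames = 40))
#' contactKinetics(gt@trackSet, contactDistance = 10)
#' @export
contactKinetics <- function(trackSet, contactDistance, minFrames = 2L,
                            mode = c("path", "net")) {
    mode <- match.arg(mode)
    p <- if (is(trackSet, "TrackSet")) trackSet@points else trackSet
    tIds <- unique(p$track_id[p$cell_type == "T"])
    nkIds <- unique(p$track_id[p$cell_type == "NK"])
    if (!length(tIds) || !length(nkIds))
        stop("cohort needs both T and NK tracks")

    rows <- lapply(tIds, function(id) {
        tr <- getTrack(p, id)
        eps <- do.call(rbind, lapply(nkIds, function(nk)
            detectContacts(tr, getTrack(p, nk), contactDistance, minFrames)))
        base <- data.frame(track_id = id, partner_id = NA_character_,
                           start_frame = NA_integer_, end_frame = NA_integer_,
                           v_ph1 = NA_real_, v_ph2 = NA_real_, v_ph3 = NA_real_,
                           ratio = NA_real_, excluded = TRUE,
                           reason = "no contact", stringsAsFactors = FALSE)
        if (is.null(eps) || !nrow(eps)) return(base)
        eps <- eps[order(-eps$n_frames, eps$start_frame, eps$partner_id), ]
        ep <- eps[1, ]
        seg <- segmentPhases(tr, ep)
        v1 <- phaseVelocity(tr, seg@ph1, mode)
        v2 <- phaseVelocity(tr, seg@ph2, mode)
        v3 <- phaseVelocity(tr, seg@ph3, mode)
        r <- decelerationRatio(v1, v2)
        base$partner_id <- ep$partner_id
        base$start_frame <- ep$start_frame; base$end_frame <- ep$end_frame
        base$v_ph1 <- v1; base$v_ph2 <- v2; base$v_ph3 <- v3; base$ratio <- r
        if (!length(seg@ph1) || is.na(v1)) {
            base$reason <- "empty Ph1"
        } else if (v1 <= 0) {
            base$reason <- "zero Ph1 velocity"
        } else if (is.na(r)) {
            base$reason <- "undefined ratio"
        } else {
            base$excluded <- FALSE; base$reason <- ""
        }
        base
    })
    out <- do.call(rbind, rows)
    nEx <- sum(out$excluded)
    if (nEx) message(sprintf(
        "contactKinetics: %d of %d cells excluded from ratio analysis (%s)",
        nEx, nrow(out),
        paste(unique(out$reason[out$excluded]), collapse = "; ")))
    out$rank <- NA_integer_
    inc <- !out$excluded
    if (any(inc)) {
        ranked <- rankByDeceleration(out[inc, c("track_id", "ratio")])
        out$rank[match(ranked$track_id, out$track_id)] <- ranked$rank
    }
    out <- out[order(is.na(out$rank), out$rank, out$track_id), ]
    rownames(out) <- NULL
    out
}
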