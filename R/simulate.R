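#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions the analyses assume: a 100-frame
#' movie of 20 T and 20 NK cells, one scripted contact per T cell during
#' which its speed is scaled by a per-cell deceleration factor (15 cells at
#' 0.1, 5 at 0.5 under the defaults), and 10\% Gaussian step-length noise.
#'
#' @param nCells named integer vector, cells per type.
#' @param arenaSize square arena side (micrometres).
#' @param nFrames frames per movie.
#' @param frameInterval seconds between frames.
#' @param baseSpeed named numeric, free speed per type (um/s).
#' @param decelFactors per-T-cell contact-phase speed multipliers in (0, 1];
#'   recycled to `nCells["T"]`.
#' @param contactRadius scripted contact distance (um).
#' @param noiseSdFrac sd of step-length noise as a fraction of speed.
#' @param transferPixels pixels transferred per contact event (recycled).
#' @param pixelSize um per pixel for rendering.
#' @param cellRadius rendered cell radius (um).
#' @param contactStart 0-based first frame of scripted windows, or `NA` to
#'   draw each start uniformly from the middle third of the movie.
#' @param contactLen window length in frames.
#' @param seed integer seed (mandatory).
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nCells = c(T = 2, NK = 2), nFrames = 20)
#' @export
simConfig <- function(nCells = c(T = 20L, NK = 20L),
                      arenaSize = 400,
                      nFrames = 100L,
                      frameInterval = 30,
                      baseSpeed = c(T = 0.15, NK = 0.10),
                      decelFactors = rep(c(0.1, 0.5),
                                         times = c(ceiling(0.75 * nCells[["T"]]),
                                                   nCells[["T"]] -
                                                     ceiling(0.75 * nCells[["T"]]))),
                      contactRadius = 10,
                      noiseSdFrac = 0.1,
                      transferPixels = 50L,
                      pixelSize = 0.5,
                      cellRadius = 5,
                      contactStart = NA_integer_,
                      contactLen = 30L,
                      seed) {
    if (missing(seed)) stop("'seed' is mandatory: no implicit randomness")
    nCells <- setNames(as.integer(nCells), names(nCells))
    new("SimConfig",
        nCells = nCells, arenaSize = as.numeric(arenaSize),
        nFrames = as.integer(nFrames), frameInterval = as.numeric(frameInterval),
        baseSpeed = baseSpeed,
        decelFactors = if (nCells[["T"]] > 0L)
            rep_len(as.numeric(decelFactors), nCells[["T"]]) else numeric(),
        contactRadius = as.numeric(contactRadius),
        noiseSdFrac = as.numeric(noiseSdFrac),
        transferPixels = as.integer(transferPixels),
        pixelSize = as.numeric(pixelSize), cellRadius = as.numeric(cellRadius),
        contactStart = as.integer(contactStart),
        contactLen = as.integer(contactLen),
        seed = as.integer(seed))
}

#' Construct a TrackSet from a points table
#'
#' @param points data.frame with `track_id`, `cell_type`, `frame`, `t_s`,
#'   `x_um`, `y_um`.
#' @param pixelSize,frameInterval acquisition geometry.
#' @return a validated [TrackSet-class].
#' @export
TrackSet <- function(points, pixelSize = 0.5, frameInterval = 30) {
    points <- points[order(points$track_id, points$frame), , drop = FALSE]
    rownames(points) <- NULL
    new("TrackSet", points = points, pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval))
}

#' Extract one track as a data.frame
#'
#' @param x a [TrackSet-class] (or its points data.frame).
#' @param id track identifier.
#' @return data.frame of the track's points, frame-ordered.
#' @export
getTrack <- function(x, id) {
    p <- if (is(x, "TrackSet")) x@points else x
    q <- p[p$track_id == id, , drop = FALSE]
    if (!nrow(q)) stop(sprintf("no track '%s'", id))
    q[order(q$frame), , drop = FALSE]
}

#' Simulate tracks with scripted T-NK contacts
#'
#' Each cell performs an isotropic step-wise random walk: at every frame a
#' uniform direction is drawn and a step of length
#' `speed * frameInterval * max(0, 1 + N(0, noiseSdFrac))` taken, with
#' reflecting arena boundaries. During its scripted contact window a T
#' cell's speed is multiplied by its deceleration factor and its partner NK
#' cell is held at 0.4 x `contactRadius` from it (pointing toward the arena
#' centre), so ground-truth contact frames satisfy the contact-radius
#' invariant exactly. NK partners are assigned round-robin.
#'
#' @param config a [SimConfig-class].
#' @return a [GroundTruth-class] holding the [TrackSet-class], the scripted
#'   contact intervals and the per-cell true deceleration factors.
#' @examples
#' gt <- simulateTracks(simConfig(seed = 1, nCells = c(T = 3, NK = 3),
#'                                nFrames = 30))
#' contactIntervals(gt)
#' @export
simulateTracks <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    nT <- config@nCells[["T"]]; nNK <- config@nCells[["NK"]]
    if (nT + nNK == 0L) stop("no cells configured")
    nf <- config@nFrames; dt <- config@frameInterval
    arena <- config@arenaSize

    withr::with_seed(config@seed, {
        ids <- c(if (nT) sprintf("T%02d", seq_len(nT)),
                 if (nNK) sprintf("NK%02d", seq_len(nNK)))
        types <- c(rep("T", nT), rep("NK", nNK))
        n <- nT + nNK
        speeds <- config@baseSpeed[types]

        # scripted windows: one per T cell (needs an NK partner and room for
        # a non-empty Ph1 and Ph3)
        contacts <- NULL
        if (nT > 0L && nNK > 0L) {
            if (is.na(config@contactStart)) {
                lo <- max(1L, floor(nf * 0.3)); hi <- max(lo, floor(nf * 0.5))
                starts <- lo + sample.int(hi - lo + 1L, nT, replace = TRUE) - 1L
            } else starts <- rep(config@contactStart, nT)
            ends <- pmin(starts + config@contactLen - 1L, nf - 2L)
            if (any(ends < starts))
                stop("contact window does not fit inside the movie")
            partners <- ((seq_len(nT) - 1L) %% nNK) + 1L
            contacts <- data.frame(
                focal_id = ids[seq_len(nT)],
                partner_id = ids[nT + partners],
                start_frame = starts, end_frame = ends,
                stringsAsFactors = FALSE)
        }

        # fixed tether offsets (recomputed toward centre at run time)
        pos <- cbind(runif(n, 0.1 * arena, 0.9 * arena),
                     runif(n, 0.1 * arena, 0.9 * arena))
        xs <- matrix(NA_real_, nf, n); ys <- matrix(NA_real_, nf, n)

        tether <- function(p) {
            # hold the partner at 0.4 r on the arena-centre side of the T
            # cell, with 0.1 r of positional jitter so the pair keeps a
            # realistic non-zero relative speed during the synapse
            ctr <- c(arena / 2, arena / 2)
            v <- ctr - p
            nv <- sqrt(sum(v^2))
            u <- if (nv < 1e-9) c(1, 0) else v / nv
            a <- runif(1, 0, 2 * pi)
            p + 0.4 * config@contactRadius * u +
                0.1 * config@contactRadius * c(cos(a), sin(a))
        }
        inWindow <- function(i, f) {
            !is.null(contacts) && i <= nT &&
                f >= contacts$start_frame[i] && f <= contacts$end_frame[i]
        }
        reflect <- function(z) {
            # fold back into [0, arena]
            z <- abs(z)
            z <- ifelse(z > arena, 2 * arena - z, z)
            while (any(z < 0 | z > arena)) {
                z <- abs(z); z <- ifelse(z > arena, 2 * arena - z, z)
            }
            z
        }

        for (f in seq_len(nf) - 1L) {    # 0-based frames
            if (f > 0L) {
                theta <- runif(n, 0, 2 * pi)
                noise <- if (config@noiseSdFrac > 0)
                    rnorm(n, 0, config@noiseSdFrac) else numeric(n)
                fac <- rep(1, n)
                for (i in seq_len(nT))
                    if (inWindow(i, f)) fac[i] <- config@decelFactors[i]
                len <- speeds * fac * dt * pmax(0, 1 + noise)
                pos <- pos + len * cbind(cos(theta), sin(theta))
                pos[, 1] <- reflect(pos[, 1]); pos[, 2] <- reflect(pos[, 2])
            }
            # tether scripted NK partners to their T cell; at disengagement
            # the pair separates beyond the contact radius (contact "ended")
            if (!is.null(contacts)) for (i in seq_len(nT)) {
                j <- nT + ((i - 1L) %% nNK) + 1L
                if (inWindow(i, f)) {
                    pos[j, ] <- tether(pos[i, ])
                } else if (f == contacts$end_frame[i] + 1L) {
                    ctr <- c(arena / 2, arena / 2)
                    v <- ctr - pos[i, ]
                    nv <- sqrt(sum(v^2))
                    u <- if (nv < 1e-9) c(1, 0) else v / nv
                    pos[j, ] <- pos[i, ] + 2.5 * config@contactRadius * u
                    pos[j, 1] <- reflect(pos[j, 1])
                    pos[j, 2] <- reflect(pos[j, 2])
                }
            }
            xs[f + 1L, ] <- pos[, 1]; ys[f + 1L, ] <- pos[, 2]
        }

        points <- data.frame(
            track_id = rep(ids, each = nf),
            cell_type = rep(types, each = nf),
            frame = rep(seq_len(nf) - 1L, times = n),
            t_s = rep((seq_len(nf) - 1L) * dt, times = n),
            x_um = as.vector(xs), y_um = as.vector(ys),
            stringsAsFactors = FALSE)

        ts <- TrackSet(points, pixelSize = config@pixelSize,
                       frameInterval = dt)
        new("GroundTruth",
            trackSet = ts,
            contacts = if (is.null(contacts))
                data.frame(focal_id = character(), partner_id = character(),
                           start_frame = integer(), end_frame = integer())
                else contacts,
            factors = if (nT) setNames(config@decelFactors[seq_len(nT)],
                                       ids[seq_len(nT)]) else numeric(),
            config = config)
    })
}
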