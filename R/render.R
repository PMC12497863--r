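.diskPixels <- function(cx, cy, r, nr, nc) {
    # pixel (row, col) is in the disk if its centre lies within r of (cx, cy);
    # x = col, y = row
    rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
    if (!length(rows) || !length(cols)) return(cbind(row = integer(), col = integer()))
    g <- expand.grid(row = rows, col = cols)
    keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
    as.matrix(g[keep, , drop = FALSE])
}

#' Render a simulation into a synthetic image stack
#'
#' Each cell is drawn as a filled disk of the configured radius in its
#' type's channel. For every scripted contact event, `transferPixels`
#' pixels of membrane signal are painted into the transfer channel inside
#' the recipient (NK) cell's mask — the pixels of the mask closest to the
#' donor's centroid — from the event's first frame to its last.
#' Ground-truth label masks (one per cell type per frame, label = cell
#' index within type) are returned alongside.
#'
#' @param truth a [GroundTruth-class] from [simulateTracks()].
#' @param config the matching [SimConfig-class] (defaults to the one stored
#'   in `truth`).
#' @return list with `stack` (a [FrameStack-class], channels T/NK/transfer),
#'   `masks` (list per frame of list(T=, NK=) integer matrices), and
#'   `events` (data.frame: `donor_id`, `recipient_id`, `start_frame`,
#'   `end_frame`, `pixels`).
#' @export
renderFrames <- function(truth, config = truth@config) {
    stopifnot(is(truth, "GroundTruth"), is(config, "SimConfig"))
    px <- config@pixelSize
    npx <- round(config@arenaSize / px)
    rpx <- config@cellRadius / px
    if (2 * rpx >= npx)
        stop("cell diameter exceeds the arena in pixels")
    p <- truth@trackSet@points
    nf <- config@nFrames
    arr <- array(0, dim = c(nf, 3L, npx, npx))
    channels <- c("T", "NK", "transfer")
    masks <- vector("list", nf)

    idsByType <- lapply(c(T = "T", NK = "NK"), function(ct)
        unique(p$track_id[p$cell_type == ct]))

    for (f in seq_len(nf) - 1L) {
        fr <- p[p$frame == f, , drop = FALSE]
        mk <- list(T = matrix(0L, npx, npx), NK = matrix(0L, npx, npx))
        for (ct in c("T", "NK")) {
            chan <- match(ct, channels)
            ids <- idsByType[[ct]]
            plane <- arr[f + 1L, chan, , ]
            for (k in seq_along(ids)) {
                row <- fr[fr$track_id == ids[k], , drop = FALSE]
                if (!nrow(row)) next
                pix <- .diskPixels(row$x_um / px, row$y_um / px, rpx, npx, npx)
                if (nrow(pix)) {
                    plane[pix] <- 1
                    mk[[ct]][pix] <- k
                }
            }
            arr[f + 1L, chan, , ] <- plane
        }
        masks[[f + 1L]] <- mk
    }

    # transfer events: one per scripted contact
    ev <- truth@contacts
    events <- data.frame(donor_id = character(), recipient_id = character(),
                         start_frame = integer(), end_frame = integer(),
                         pixels = integer(), stringsAsFactors = FALSE)
    if (nrow(ev)) {
        npix <- rep_len(config@transferPixels, nrow(ev))
        chanTr <- match("transfer", channels)
        for (e in seq_len(nrow(ev))) {
            donor <- ev$focal_id[e]; recip <- ev$partner_id[e]
            recipIdx <- match(recip, idsByType$NK)
            for (f in ev$start_frame[e]:ev$end_frame[e]) {
                mk <- masks[[f + 1L]]$NK
                inside <- which(mk == recipIdx)
                if (length(inside) < npix[e])
                    stop("recipient mask smaller than transferPixels")
                drow <- p[p$frame == f & p$track_id == donor, ]
                nr <- nrow(mk)
                rows <- (inside - 1L) %% nr + 1L
                cols <- (inside - 1L) %/% nr + 1L
                d2 <- (rows - drow$y_um / px)^2 + (cols - drow$x_um / px)^2
                take <- inside[order(d2)[seq_len(npix[e])]]
                plane <- arr[f + 1L, chanTr, , ]
                plane[take] <- 1
                arr[f + 1L, chanTr, , ] <- plane
            }
            events <- rbind(events, data.frame(
                donor_id = donor, recipient_id = recip,
                start_frame = ev$start_frame[e], end_frame = ev$end_frame[e],
                pixels = npix[e], stringsAsFactors = FALSE))
        }
    }
    list(stack = new("FrameStack", data = arr, channels = channels,
                     pixelSize = px, frameInterval = config@frameInterval),
         masks = masks, events = events)
}
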