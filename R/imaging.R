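#' Segment one fluorescent channel into labeled cell masks
#'
#' Pixels at or above the threshold (Otsu's method on the intensity
#' histogram by default, or a fixed value) are grouped into 8-connected
#' components; components smaller than `minArea` are discarded. Labels are
#' assigned deterministically in raster-scan (row-major) order of each
#' component's first pixel. A blank frame yields zero labels.
#'
#' @param img non-negative numeric matrix (one channel of one frame).
#' @param method "otsu" or "fixed".
#' @param threshold required when `method = "fixed"`; intensity cut.
#' @param minArea minimum component area in pixels.
#' @return a [LabelImage-class].
#' @export
segmentChannel <- function(img, method = c("otsu", "fixed"),
                           threshold = NULL, minArea = 0L) {
    method <- match.arg(method)
    stopifnot(is.matrix(img))
    if (any(img < 0)) stop("intensities must be non-negative")
    mx <- max(img)
    if (mx == 0 || mx == min(img))
        return(new("LabelImage",
                   labels = matrix(0L, nrow(img), ncol(img))))
    thr <- switch(method,
        otsu = EBImage::otsu(EBImage::Image(img / mx)) * mx,
        fixed = {
            if (is.null(threshold)) stop("fixed method needs 'threshold'")
            threshold
        })
    bin <- img >= thr
    lab <- .label8(bin)
    if (minArea > 0L && max(lab) > 0L) {
        areas <- tabulate(lab[lab > 0L])
        keep <- which(areas >= minArea)
        lab[!(lab %in% keep)] <- 0L
        lab <- .relabelRaster(lab)
    }
    new("LabelImage", labels = lab)
}

# 8-connected component labeling: EBImage::bwlabel (4-connected) followed by
# a union-find merge of diagonally touching labels, then raster relabeling.
.label8 <- function(bin) {
    lab <- EBImage::imageData(EBImage::bwlabel(bin * 1))
    storage.mode(lab) <- "integer"
    n <- max(lab)
    if (n > 1L) {
        parent <- seq_len(n)
        find <- function(i) {
            while (parent[i] != i) {
                parent[i] <<- parent[parent[i]]
                i <- parent[i]
            }
            i
        }
        nr <- nrow(lab); nc <- ncol(lab)
        merge2 <- function(a, b) {
            w <- which(a > 0L & b > 0L & a != b)
            for (k in w) {
                ra <- find(a[k]); rb <- find(b[k])
                if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
            }
        }
        merge2(lab[-nr, -nc], lab[-1, -1])   # down-right diagonals
        merge2(lab[-1, -nc], lab[-nr, -1])   # up-right diagonals
        root <- vapply(seq_len(n), find, integer(1))
        lab[lab > 0L] <- root[lab[lab > 0L]]
    }
    .relabelRaster(lab)
}

# renumber labels 1..n by first occurrence in row-major raster order
.relabelRaster <- function(lab) {
    pos <- which(lab > 0L)
    if (!length(pos)) return(lab)
    nr <- nrow(lab)
    rows <- (pos - 1L) %% nr + 1L
    cols <- (pos - 1L) %/% nr + 1L
    raster <- (rows - 1L) * ncol(lab) + cols
    vals <- lab[pos]
    firsts <- tapply(raster, vals, min)
    newId <- integer(max(lab))
    newId[as.integer(names(firsts))] <- rank(firsts, ties.method = "first")
    lab[pos] <- newId[vals]
    lab
}

#' Centroids and areas of a label image
#'
#' The centroid is the unweighted mean of each label's pixel coordinates;
#' `x` is the column and `y` the row index (origin top-left).
#'
#' @param labelImage a [LabelImage-class].
#' @return data.frame with `label`, `x`, `y`, `area`, ordered by label
#'   (zero rows for an empty image).
#' @export
centroids <- function(labelImage) {
    lab <- if (is(labelImage, "LabelImage")) labelImage@labels else labelImage
    pos <- which(lab > 0L)
    if (!length(pos))
        return(data.frame(label = integer(), x = numeric(), y = numeric(),
                          area = integer()))
    nr <- nrow(lab)
    rows <- (pos - 1L) %% nr + 1L
    cols <- (pos - 1L) %/% nr + 1L
    vals <- lab[pos]
    data.frame(label = sort(unique(vals)),
               x = as.numeric(tapply(cols, vals, mean)),
               y = as.numeric(tapply(rows, vals, mean)),
               area = as.integer(tapply(vals, vals, length)))
}

#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-first assignment between consecutive frames:
#' candidate pairs are consumed in order of increasing distance (ties broken
#' by the smaller label in the earlier frame, then in the later frame);
#' pairs beyond `maxDisplacement` are never assigned, and unassigned
#' detections seed new tracks.
#'
#' @param centroidList list (one element per frame, frame 0 first) of
#'   data.frames with `label`, `x`, `y` as from [centroids()].
#' @param maxDisplacement gating distance in pixels (> 0).
#' @return data.frame with `track_id`, `frame` (0-based), `label`, `x`, `y`.
#' @export
linkFrames <- function(centroidList, maxDisplacement) {
    if (maxDisplacement <= 0) stop("maxDisplacement must be > 0")
    if (length(centroidList) < 2L) stop("need at least 2 frames")
    nextId <- 0L
    newTrack <- function() { nextId <<- nextId + 1L; sprintf("L%03d", nextId) }
    cur <- centroidList[[1]]
    cur <- cur[order(cur$label), , drop = FALSE]
    curIds <- vapply(seq_len(nrow(cur)), function(i) newTrack(), character(1))
    rows <- list()
    emit <- function(f, det, ids) {
        if (!nrow(det)) return()
        rows[[length(rows) + 1L]] <<- data.frame(
            track_id = ids, frame = f, label = det$label,
            x = det$x, y = det$y, stringsAsFactors = FALSE)
    }
    emit(0L, cur, curIds)
    for (f in seq_along(centroidList)[-1]) {
        nxt <- centroidList[[f]]
        nxt <- nxt[order(nxt$label), , drop = FALSE]
        nxtIds <- rep(NA_character_, nrow(nxt))
        if (nrow(cur) && nrow(nxt)) {
            cand <- expand.grid(i = seq_len(nrow(cur)), j = seq_len(nrow(nxt)))
            cand$d <- sqrt((cur$x[cand$i] - nxt$x[cand$j])^2 +
                           (cur$y[cand$i] - nxt$y[cand$j])^2)
            cand <- cand[cand$d <= maxDisplacement, , drop = FALSE]
            cand <- cand[order(cand$d, cur$label[cand$i], nxt$label[cand$j]), ,
                         drop = FALSE]
            usedI <- logical(nrow(cur)); usedJ <- logical(nrow(nxt))
            for (k in seq_len(nrow(cand))) {
                i <- cand$i[k]; j <- cand$j[k]
                if (!usedI[i] && !usedJ[j]) {
                    usedI[i] <- TRUE; usedJ[j] <- TRUE
                    nxtIds[j] <- curIds[i]
                }
            }
        }
        for (j in which(is.na(nxtIds))) nxtIds[j] <- newTrack()
        emit(f - 1L, nxt, nxtIds)
        cur <- nxt; curIds <- nxtIds
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$track_id, out$frame), ]
    rownames(out) <- NULL
    out
}

#' Quantify transferred-membrane pixels within recipient masks
#'
#' Counts, per recipient label, the transfer-channel pixels at or above the
#' intensity threshold that fall inside the mask (the "pixel counts of
#' transferred membrane fragments" readout).
#'
#' @param labelImage recipient [LabelImage-class].
#' @param transferImg numeric matrix, same shape; the transfer channel.
#' @param threshold intensity cut for a transfer-positive pixel.
#' @return data.frame with `label`, `area`, `transfer_px`.
#' @export
quantifyTransfer <- function(labelImage, transferImg, threshold = 0.5) {
    lab <- if (is(labelImage, "LabelImage")) labelImage@labels else labelImage
    if (!all(dim(lab) == dim(transferImg)))
        stop("label image and transfer channel shapes differ")
    cen <- centroids(labelImage)
    if (!nrow(cen)) {
        cen$transfer_px <- integer()
        return(cen[, c("label", "area", "transfer_px")])
    }
    hot <- transferImg >= threshold
    cnt <- vapply(cen$label, function(l) sum(hot[lab == l]), integer(1))
    data.frame(label = cen$label, area = cen$area, transfer_px = cnt)
}

#' Average transferred pixels per cell type
#'
#' Summarizes a long per-frame quantification table at three granularities:
#' "cell" (each cell contributes its maximum count over frames, then cells
#' are averaged), "frame" (average over all cell-frames), or "video" (total
#' pixels per type).
#'
#' @param quant data.frame with `frame`, `cell_type`, `label`,
#'   `transfer_px` (e.g. rows of [quantifyTransfer()] with frame/type
#'   columns added).
#' @param by granularity.
#' @return data.frame with `cell_type` and `value`.
#' @export
averageTransfer <- function(quant, by = c("cell", "frame", "video")) {
    by <- match.arg(by)
    split_ <- split(quant, quant$cell_type)
    out <- lapply(names(split_), function(ct) {
        g <- split_[[ct]]
        v <- switch(by,
            cell = mean(tapply(g$transfer_px, g$label, max)),
            frame = mean(g$transfer_px),
            video = sum(g$transfer_px))
        data.frame(cell_type = ct, value = v)
    })
    do.call(rbind, out)
}
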