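# small simulation configurations used across tests

tinyConfig <- function(seed = 1, ...) {
    args <- list(seed = seed,
                 nCells = c(T = 2, NK = 2), nFrames = 30, arenaSize = 200,
                 contactStart = 10L, contactLen = 10L)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

# a hand-built track: data.frame in the canonical schema
makeTrack <- function(id, type, frames, x, y, dt = 1) {
    data.frame(track_id = id, cell_type = type, frame = frames,
               t_s = frames * dt, x_um = x, y_um = y,
               stringsAsFactors = FALSE)
}

# brute-force oracle for phase velocities
bruteVelocity <- function(track, phase, mode) {
    q <- track[track$frame %in% phase, ]
    q <- q[order(q$frame), ]
    if (nrow(q) < 2) return(NA_real_)
    if (mode == "path") {
        tot <- 0
        for (i in 2:nrow(q))
            tot <- tot + sqrt((q$x_um[i] - q$x_um[i - 1])^2 +
                              (q$y_um[i] - q$y_um[i - 1])^2)
    } else {
        tot <- sqrt((q$x_um[nrow(q)] - q$x_um[1])^2 +
                    (q$y_um[nrow(q)] - q$y_um[1])^2)
    }
    tot / (q$t_s[nrow(q)] - q$t_s[1])
}

# brute-force disk pixel count: pixels whose integer centre is within r
bruteDiskArea <- function(cx, cy, r, n) {
    cnt <- 0L
    for (row in 1:n) for (col in 1:n)
        if ((row - cy)^2 + (col - cx)^2 <= r^2) cnt <- cnt + 1L
    cnt
}

# random LR pair set with unique gene symbols (avoids design conflicts)
randomPairs <- function(nPairs, maxSub = 2) {
    k <- 0
    lig <- rec <- character(nPairs)
    for (i in seq_len(nPairs)) {
        nl <- sample(maxSub, 1); nr <- sample(maxSub, 1)
        lig[i] <- paste(sprintf("G%03d", k + seq_len(nl)), collapse = "/")
        k <- k + nl
        rec[i] <- paste(sprintf("G%03d", k + seq_len(nr)), collapse = "/")
        k <- k + nr
    }
    parsePairTable(data.frame(ligand = lig, receptor = rec))
}
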