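straightTrack <- function(d, id = "a", type = "T") {
    # one cell at the origin, another at scripted distances along x
    makeTrack(id, type, seq_along(d) - 1L, d, rep(0, length(d)))
}

test_that("contact episodes are maximal runs above the minimum duration", {
    a <- straightTrack(rep(0, 5), "a")
    b <- straightTrack(c(5, 1, 1, 1, 5), "b", "NK")
    got <- detectContacts(a, b, contactDistance = 2, minFrames = 2)
    expect_equal(nrow(got), 1L)
    expect_equal(got$start_frame, 1L)   # frames 2..4 in 1-based counting
    expect_equal(got$end_frame, 3L)
    expect_equal(got$n_frames, 3L)
})

test_that("no contact, infinite threshold and split runs behave per contract", {
    a <- straightTrack(rep(0, 6), "a")
    far <- straightTrack(rep(10, 6), "b", "NK")
    expect_equal(nrow(detectContacts(a, far, 2)), 0L)
    all6 <- detectContacts(a, far, Inf)
    expect_equal(nrow(all6), 1L)
    expect_equal(c(all6$start_frame, all6$end_frame), c(0L, 5L))
    # two runs separated by one non-contact frame are distinct episodes
    b <- straightTrack(c(1, 1, 9, 1, 1, 9), "b", "NK")
    two <- detectContacts(a, b, 2, minFrames = 2)
    expect_equal(nrow(two), 2L)
    expect_equal(two$start_frame, c(0L, 3L))
    expect_error(detectContacts(a, b, 2, minFrames = 0), "minFrames")
    expect_error(
        detectContacts(a, makeTrack("c", "NK", 100:105, 1:6, 1:6), 2),
        "common frames")
})

test_that("phase segmentation partitions the track span", {
    tr <- makeTrack("a", "T", 0:30, 0:30, rep(0, 31))
    seg <- segmentPhases(tr, list(start_frame = 10, end_frame = 20))
    expect_equal(phaseFrames(seg, "ph1"), 0:9)
    expect_equal(phaseFrames(seg, "ph2"), 10:20)
    expect_equal(phaseFrames(seg, "ph3"), 21:30)
    # contact from the first frame: Ph1 empty but legal
    seg0 <- segmentPhases(tr, list(start_frame = 0, end_frame = 5))
    expect_length(phaseFrames(seg0, "ph1"), 0)
    # contact covering everything: Ph1 and Ph3 empty
    segAll <- segmentPhases(tr, list(start_frame = 0, end_frame = 30))
    expect_length(phaseFrames(segAll, "ph1"), 0)
    expect_length(phaseFrames(segAll, "ph3"), 0)
    expect_equal(phaseFrames(segAll, "ph2"), 0:30)
})

test_that("phase partition is complete on random tracks", {
    withr::with_seed(99, {
        for (i in 1:1000) {
            n <- sample(5:40, 1)
            tr <- makeTrack("a", "T", 0:(n - 1), runif(n), runif(n))
            s <- sort(sample(0:(n - 1), 2))
            seg <- segmentPhases(tr, list(start_frame = s[1], end_frame = s[2]))
            expect_identical(
                c(phaseFrames(seg, "ph1"), phaseFrames(seg, "ph2"),
                  phaseFrames(seg, "ph3")),
                0:(n - 1))
        }
    })
})

test_that("path and net velocities match hand-computed values", {
    line <- makeTrack("a", "T", 0:4, 0:4, rep(0, 5))
    expect_equal(phaseVelocity(line, 0:4, "path"), 1.0)
    expect_equal(phaseVelocity(line, 0:4, "net"), 1.0)
    loop <- makeTrack("a", "T", 0:4, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
    expect_equal(phaseVelocity(loop, 0:4, "path"), 1.0)
    expect_equal(phaseVelocity(loop, 0:4, "net"), 0.0)
    zig <- makeTrack("a", "T", 0:3, c(0, 1, 1, 2), c(0, 0, 1, 1))
    expect_equal(phaseVelocity(zig, 0:3, "path"), 1.0)
    expect_equal(phaseVelocity(zig, 0:3, "net"), sqrt(5) / 3)
    # single-frame phase: undefined, distinct from zero
    expect_true(is.na(phaseVelocity(line, 2, "path")))
})

test_that("velocities match a brute-force oracle on short random tracks", {
    withr::with_seed(7, {
        for (i in 1:50) {
            n <- sample(3:10, 1)
            tr <- makeTrack("a", "T", 0:(n - 1), rnorm(n), rnorm(n),
                            dt = runif(1, 0.5, 3))
            ph <- 0:(n - 1)
            for (m in c("path", "net"))
                expect_equal(phaseVelocity(tr, ph, m), bruteVelocity(tr, ph, m),
                             tolerance = 1e-12)
        }
    })
})

test_that("velocities are scale- and time-equivariant, ratios invariant", {
    withr::with_seed(21, {
        tr <- makeTrack("a", "T", 0:19, cumsum(rnorm(20)), cumsum(rnorm(20)))
        ph1 <- 0:9; ph2 <- 10:19
        v1 <- phaseVelocity(tr, ph1); v2 <- phaseVelocity(tr, ph2)
        for (k in c(0.5, 3, 10)) {
            sc <- tr; sc$x_um <- k * sc$x_um; sc$y_um <- k * sc$y_um
            expect_equal(phaseVelocity(sc, ph1), k * v1)
            expect_equal(decelerationRatio(phaseVelocity(sc, ph1),
                                           phaseVelocity(sc, ph2)),
                         decelerationRatio(v1, v2))
            tm <- tr; tm$t_s <- k * tm$t_s
            expect_equal(phaseVelocity(tm, ph1), v1 / k)
            expect_equal(decelerationRatio(phaseVelocity(tm, ph1),
                                           phaseVelocity(tm, ph2)),
                         decelerationRatio(v1, v2))
        }
    })
})

test_that("deceleration ratio encodes the fold-reduction correspondence", {
    expect_equal(decelerationRatio(1.0, 0.2), 0.2)   # 5-fold slowdown
    expect_equal(decelerationRatio(1.5, 1.5), 1.0)
    expect_equal(decelerationRatio(2.0, 0.0), 0.0)   # full arrest
    expect_true(is.na(decelerationRatio(0, 1)))
    expect_true(is.na(decelerationRatio(NA_real_, 1)))
})

test_that("ranking sorts ascending with deterministic tie-breaks", {
    res <- data.frame(track_id = c("a", "b", "c"), ratio = c(0.5, 0.1, 0.3))
    expect_equal(rankByDeceleration(res)$track_id, c("b", "c", "a"))
    tie <- data.frame(track_id = c("b", "a"), ratio = c(0.2, 0.2))
    expect_equal(rankByDeceleration(tie)$track_id, c("a", "b"))
    expect_equal(rankByDeceleration(tie)$rank, 1:2)
    empty <- data.frame(track_id = character(), ratio = numeric())
    expect_equal(nrow(rankByDeceleration(empty)), 0L)
    expect_error(rankByDeceleration(data.frame(track_id = "a", ratio = NA_real_)),
                 "defined")
})

test_that("cells with empty Ph1 are excluded and counted", {
    gt <- simulateTracks(tinyConfig(seed = 13, contactStart = 1L))
    # contact starting at frame 1 leaves a single-point Ph1: velocity NA
    expect_message(
        kin <- contactKinetics(gt@trackSet, contactDistance = 10),
        "excluded")
    expect_true(all(kin$excluded))
    expect_true(all(is.na(kin$rank)))
})
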