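test_that("euclidean distance matches hand values and is symmetric", {
    a <- list(frame = 0, x = 0, y = 0)
    b <- list(frame = 0, x = 3, y = 4)
    expect_equal(euclideanDistance(a, b), 5)
    expect_equal(euclideanDistance(b, a), 5)
    expect_equal(euclideanDistance(a, a), 0)
    expect_equal(euclideanDistance(list(frame = 0, x = 1, y = 1),
                                   list(frame = 0, x = 4, y = 5)), 5)
    expect_error(euclideanDistance(a, list(frame = 1, x = 0, y = 0)), "frame")
})

test_that("relative speed is the norm of the velocity difference", {
    static <- makeTrack("s", "T", 0:5, rep(0, 6), rep(0, 6))
    moving <- makeTrack("m", "NK", 0:5, 0:5, rep(0, 6))
    diag <- makeTrack("d", "NK", 0:5, rep(0, 6), 0:5)
    expect_equal(relativeSpeed(static, static, 3), 0)
    expect_equal(relativeSpeed(moving, static, 3), 1)
    expect_equal(relativeSpeed(moving, diag, 3), sqrt(2))
    expect_true(is.na(relativeSpeed(moving, static, 0)))  # no predecessor
})

test_that("sdi follows the formula and its limits", {
    expect_equal(sdi(1, 4, 1), 0.2)
    expect_equal(sdi(0, 123), 0)
    expect_equal(sdi(1, 0, 1e-6), 1e6)
    expect_error(sdi(-1, 1), "vRel")
    expect_error(sdi(1, -1), "d must")
    expect_error(sdi(1, 1, 0), "epsilon")
    # monotone: decreasing in d, increasing in v_rel
    d <- seq(0, 50, by = 0.5)
    expect_true(all(diff(sdi(1, d)) < 0))
    v <- seq(0, 5, by = 0.1)
    expect_true(all(diff(sdi(v, 7)) > 0))
    # epsilon-limit: sdi -> v/d as epsilon -> 0
    expect_equal(sdi(2, 5, 1e-12 * 5), 2 / 5, tolerance = 1e-9)
})

test_that("sdi series match brute-force recomputation and symmetry", {
    gt <- simulateTracks(tinyConfig(seed = 31, noiseSdFrac = 0))
    p <- trackTable(gt)
    a <- getTrack(p, "T01"); b <- getTrack(p, "NK01")
    s <- sdiSeries(a, b, epsilon = 1e-6)
    expect_s4_class(s, "SDISeries")
    expect_equal(modality(s), "NK-T")
    sm <- sdiSamples(s)
    expect_equal(nrow(sm), 29L)   # 30 common frames, first has no velocity
    for (i in c(1, 10, 29)) {
        f <- sm$frame[i]
        ia <- match(f, a$frame); ib <- match(f, b$frame)
        va <- c(a$x_um[ia] - a$x_um[ia - 1], a$y_um[ia] - a$y_um[ia - 1]) /
            (a$t_s[ia] - a$t_s[ia - 1])
        vb <- c(b$x_um[ib] - b$x_um[ib - 1], b$y_um[ib] - b$y_um[ib - 1]) /
            (b$t_s[ib] - b$t_s[ib - 1])
        vr <- sqrt(sum((va - vb)^2))
        d <- sqrt((a$x_um[ia] - b$x_um[ib])^2 + (a$y_um[ia] - b$y_um[ib])^2)
        expect_equal(sm$v_rel[i], vr, tolerance = 1e-12)
        expect_equal(sm$sdi[i], vr / (d + 1e-6), tolerance = 1e-12)
    }
    # symmetry in the pair order
    s2 <- sdiSeries(b, a, epsilon = 1e-6)
    expect_equal(sdiSamples(s2)$sdi, sm$sdi)
    expect_equal(modality(s2), "NK-T")
})

test_that("static pairs give zero sdi and modality follows cell types", {
    a <- makeTrack("a", "T", 0:9, rep(0, 10), rep(0, 10))
    b <- makeTrack("b", "T", 0:9, rep(3, 10), rep(4, 10))
    s <- sdiSeries(a, b)
    expect_equal(nrow(sdiSamples(s)), 9L)
    expect_true(all(sdiSamples(s)$sdi == 0))
    expect_equal(modality(s), "T-T")
    nk <- makeTrack("n", "NK", 0:9, rep(1, 10), rep(1, 10))
    expect_equal(modality(sdiSeries(nk, b)), "NK-T")
    nk2 <- makeTrack("n2", "NK", 0:9, rep(2, 10), rep(2, 10))
    expect_equal(modality(sdiSeries(nk, nk2)), "NK-NK")
})

test_that("binned aggregation uses per-pair means and quartile envelopes", {
    const <- function(id, type, c0) {
        tr <- makeTrack(id, type, 0:9, rep(0, 10), rep(0, 10))
        s <- sdiSeries(tr, makeTrack(paste0(id, "p"), type, 0:9,
                                     rep(3, 10), rep(4, 10)))
        s@samples$sdi <- c0   # constant series
        s
    }
    one <- aggregateSDI(list(const("a", "T", 2)), binWidth = 5)
    expect_true(all(one$median_sdi == 2))
    expect_true(all(one$q1 == 2 & one$q3 == 2))   # IQR collapses
    three <- aggregateSDI(list(const("a", "T", 1), const("b", "T", 2),
                               const("c", "T", 3)), binWidth = 5)
    expect_true(all(three$median_sdi == 2))
    expect_true(all(three$n_pairs == 3))
    expect_true(all(three$q1 <= three$median_sdi &
                    three$median_sdi <= three$q3))
    expect_equal(nrow(aggregateSDI(list(), 5)), 0L)
})

test_that("contact-steered NK-T pairs out-rank non-interacting T-T pairs", {
    cfg <- simConfig(seed = 17, nCells = c(T = 6, NK = 6), nFrames = 60,
                     contactStart = 20L, contactLen = 25L)
    gt <- simulateTracks(cfg)
    p <- trackTable(gt)
    ci <- contactIntervals(gt)
    nkT <- lapply(seq_len(nrow(ci)), function(i)
        sdiSeries(getTrack(p, ci$focal_id[i]), getTrack(p, ci$partner_id[i])))
    tIds <- unique(p$track_id[p$cell_type == "T"])
    tt <- list()
    for (i in 1:5) for (j in (i + 1):6)
        tt[[length(tt) + 1]] <- sdiSeries(getTrack(p, tIds[i]),
                                          getTrack(p, tIds[j]))
    w <- cfg@frameInterval * 10
    aggNK <- aggregateSDI(nkT, w)
    aggTT <- aggregateSDI(tt, w)
    # compare bins covering the scripted contact era
    era <- aggNK$bin_start >= 20 * cfg@frameInterval &
           aggNK$bin_end <= 45 * cfg@frameInterval
    for (b in aggNK$bin[era]) {
        mNK <- aggNK$median_sdi[aggNK$bin == b]
        mTT <- aggTT$median_sdi[aggTT$bin == b]
        if (length(mTT)) expect_gt(mNK, mTT)
    }
})

test_that("proximity labels split at the threshold inclusively", {
    pr <- classifyProximity(c(100, 250, 251))
    expect_equal(pr@labels, c("close", "close", "distant"))
    z <- classifyProximity(rep(0, 7))
    expect_true(all(z@labels == "close"))
    expect_equal(z@histogram$count[1], 7L)
    expect_error(classifyProximity(c(-1, 5)), ">= 0")
})

test_that("histogram counts are conserved for any bin width", {
    withr::with_seed(12, {
        d <- c(rnorm(500, 80, 20), rnorm(500, 400, 60))
        d <- abs(d)
        for (w in c(5, 10, 37)) {
            pr <- classifyProximity(d, threshold = 250, binWidth = w)
            expect_equal(sum(pr@histogram$count), 1000L)
        }
        pr <- classifyProximity(d)
        expect_equal(sum(pr@labels == "close"), sum(d <= 250))
        # every bin's count matches direct tallying
        h <- pr@histogram
        for (i in sample(nrow(h), 10))
            expect_equal(h$count[i],
                         sum(d >= h$bin_start[i] & d < h$bin_end[i]))
    })
})
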