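exprTable <- function(...) {
    v <- list(...)
    do.call(rbind, lapply(names(v), function(cell) {
        data.frame(gene = names(v[[cell]]), cell_type = cell,
                   tpm = unname(v[[cell]]), stringsAsFactors = FALSE)
    }))
}

test_that("pair tables parse complexes, singletons and duplicates", {
    p <- parsePairTable(data.frame(ligand = "ITGAL/ITGB2", receptor = "CD226"))
    expect_equal(p$ligand_subunits[[1]], c("ITGAL", "ITGB2"))
    expect_equal(p$receptor_subunits[[1]], "CD226")
    p2 <- parsePairTable(data.frame(ligand = "TNF", receptor = "TNFRSF1A"))
    expect_equal(p2$ligand_subunits[[1]], "TNF")
    dup <- data.frame(ligand = c("TNF", "TNF"), receptor = c("FAS", "FAS"))
    expect_warning(pd <- parsePairTable(dup), "duplicate")
    expect_equal(nrow(pd), 1L)
    expect_message(
        pe <- parsePairTable(data.frame(ligand = c("", "TNF"),
                                        receptor = c("FAS", "FAS"))),
        "rejected")
    expect_equal(nrow(pe), 1L)
})

test_that("the all-subunits rule gates complexes at each threshold", {
    pairs <- parsePairTable(data.frame(ligand = "ITGAL/ITGB2",
                                       receptor = "CD226"))
    expr <- exprTable(CD8T = c(ITGAL = 15, ITGB2 = 12, CD226 = 1),
                      NK = c(ITGAL = 1, ITGB2 = 1, CD226 = 9))
    r10 <- screenPairs(pairs, expr, 10, direction = "forward")
    expect_equal(nrow(passingPairs(r10)), 0L)   # CD226 at 9 < 10
    r2 <- screenPairs(pairs, expr, 2, direction = "forward")
    expect_equal(nrow(passingPairs(r2)), 1L)
    # inclusive boundary: all subunits exactly at the threshold pass
    exprEq <- exprTable(CD8T = c(ITGAL = 10, ITGB2 = 10, CD226 = 10),
                        NK = c(ITGAL = 10, ITGB2 = 10, CD226 = 10))
    expect_equal(nrow(passingPairs(
        screenPairs(pairs, exprEq, 10, direction = "forward"))), 1L)
})

test_that("missing genes are unevaluable, never pass or fail", {
    pairs <- parsePairTable(data.frame(ligand = c("TNF", "GZMA"),
                                       receptor = c("TNFRSF1A", "F2R")))
    expr <- exprTable(CD8T = c(TNF = 50, TNFRSF1A = 50, GZMA = 50),
                      NK = c(TNF = 50, TNFRSF1A = 50, GZMA = 50))  # no F2R
    r <- screenPairs(pairs, expr, 10)
    n <- screenCounts(r)
    expect_equal(unname(n["pass"]), 1L)
    expect_equal(unname(n["unevaluable"]), 1L)
    expect_equal(unname(n["fail"]), 0L)
    expect_error(screenPairs(pairs, expr, 10, ligandCell = "B cell"),
                 "unknown cell type")
    expect_error(screenPairs(pairs, expr, 0), "threshold")
})

test_that("direction symmetry: swapping cells transposes the result", {
    pairs <- randomPairs(8)
    design <- rep(c("pass10", "fail"), 4)
    expr <- synthExpression(pairs, design, seed = 5)
    # make expression asymmetric across cell types
    expr$tpm[expr$cell_type == "NK"] <-
        rev(expr$tpm[expr$cell_type == "NK"])
    fw <- screenPairs(pairs, expr, 10, "CD8T", "NK", direction = "forward")
    swapped <- expr
    swapped$cell_type <- ifelse(expr$cell_type == "NK", "CD8T", "NK")
    rv <- screenPairs(pairs, swapped, 10, "CD8T", "NK", direction = "reverse")
    expect_equal(passingPairs(fw)$ligand, passingPairs(rv)$ligand)
    expect_equal(screenCounts(fw), screenCounts(rv))
})

test_that("screen matches an exhaustive brute-force check on small tables", {
    withr::with_seed(61, {
        for (rep in 1:10) {
            pairs <- randomPairs(sample(3:20, 1))
            genes <- unique(unlist(c(pairs$ligand_subunits,
                                     pairs$receptor_subunits)))
            expr <- data.frame(
                gene = rep(genes, 2),
                cell_type = rep(c("CD8T", "NK"), each = length(genes)),
                tpm = runif(2 * length(genes), 0, 30))
            thr <- sample(c(2, 10), 1)
            got <- screenPairs(pairs, expr, thr, direction = "forward")
            lookup <- function(g, c)
                expr$tpm[expr$gene == g & expr$cell_type == c][1]
            brute <- vapply(seq_len(nrow(pairs)), function(i) {
                ok <- TRUE
                for (g in pairs$ligand_subunits[[i]])
                    ok <- ok && lookup(g, "CD8T") >= thr
                for (g in pairs$receptor_subunits[[i]])
                    ok <- ok && lookup(g, "NK") >= thr
                ok
            }, logical(1))
            expect_equal(sort(passingPairs(got)$ligand),
                         sort(pairs$ligand[brute]))
        }
    })
})

test_that("passing sets are monotone in the threshold", {
    withr::with_seed(71, {
        for (rep in 1:25) {
            pairs <- randomPairs(10)
            genes <- unique(unlist(c(pairs$ligand_subunits,
                                     pairs$receptor_subunits)))
            expr <- data.frame(
                gene = rep(genes, 2),
                cell_type = rep(c("CD8T", "NK"), each = length(genes)),
                tpm = runif(2 * length(genes), 0, 40))
            p10 <- passingPairs(screenPairs(pairs, expr, 10))$ligand
            p2 <- passingPairs(screenPairs(pairs, expr, 2))$ligand
            expect_true(all(p10 %in% p2))
        }
    })
})

test_that("weakening one subunit removes exactly the pairs containing it", {
    pairs <- randomPairs(6)
    expr <- synthExpression(pairs, rep("pass10", 6), seed = 3)
    g <- pairs$ligand_subunits[[2]][1]
    weak <- expr
    weak$tpm[weak$gene == g] <- 1
    before <- passingPairs(screenPairs(pairs, expr, 10))$ligand
    after <- passingPairs(screenPairs(pairs, weak, 10))$ligand
    hasG <- vapply(seq_len(nrow(pairs)), function(i)
        g %in% c(pairs$ligand_subunits[[i]], pairs$receptor_subunits[[i]]),
        logical(1))
    expect_setequal(setdiff(before, after), pairs$ligand[hasG])
})

test_that("threshold-category counting validates and counts", {
    expect_equal(countByThreshold(data.frame(tpm2 = c(TRUE, TRUE, TRUE),
                                             tpm10 = c(TRUE, FALSE, TRUE))),
                 c(tpm2 = 3L, tpm10 = 2L))
    expect_equal(countByThreshold(data.frame(tpm2 = logical(),
                                             tpm10 = logical())),
                 c(tpm2 = 0L, tpm10 = 0L))
    expect_error(countByThreshold(data.frame(tpm2 = FALSE, tpm10 = TRUE)),
                 "inconsistent")
})

test_that("the packaged crosstalk table counts 16 and 9", {
    t1 <- lrPairsTable1()
    expect_equal(nrow(t1), 16L)
    expect_equal(countByThreshold(t1), c(tpm2 = 16L, tpm10 = 9L))
})
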