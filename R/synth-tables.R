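#' Synthesize a TPM expression table matching a screen design
#'
#' Each pair is assigned one of three outcomes: `"pass10"` (all subunits
#' drawn in [10, 100], so the pair passes both thresholds), `"pass2"`
#' (passes at >= 2 TPM only: one limiting subunit in [2, 10), the rest at or
#' above 2) or `"fail"` (one subunit below 2). Band constraints accumulate
#' per gene across pairs and are intersected; an empty intersection is a
#' contradictory design and raises an error naming the gene. Genes receive
#' the same TPM in both cell types, so the screen outcome is
#' direction-independent. By construction,
#' `screenPairs()` applied to the result reproduces the design exactly.
#'
#' @param pairs output of [parsePairTable()].
#' @param design character vector, one of "pass10", "pass2", "fail" per
#'   pair.
#' @param seed integer seed.
#' @param cellTypes the two cell-type labels to emit.
#' @return data.frame with `gene`, `cell_type`, `tpm`.
#' @export
synthExpression <- function(pairs, design, seed,
                            cellTypes = c("CD8T", "NK")) {
    stopifnot(nrow(pairs) == length(design),
              all(design %in% c("pass10", "pass2", "fail")))
    genes <- unique(unlist(c(pairs$ligand_subunits, pairs$receptor_subunits)))
    lo <- setNames(rep(NA_real_, length(genes)), genes)
    hi <- setNames(rep(NA_real_, length(genes)), genes)
    narrow <- function(g, l, h) {
        nl <- max(lo[g], l, na.rm = TRUE)
        nh <- min(hi[g], h, na.rm = TRUE)
        if (nl >= nh)
            stop(sprintf("contradictory design for gene '%s'", g))
        lo[g] <<- nl; hi[g] <<- nh
    }
    subunitsOf <- function(i)
        c(pairs$ligand_subunits[[i]], pairs$receptor_subunits[[i]])
    # pass constraints first: they bound genes from below
    for (i in which(design == "pass10"))
        for (g in subunitsOf(i)) narrow(g, 10, 100)
    for (i in which(design == "pass2"))
        for (g in subunitsOf(i)) narrow(g, 2, 100)
    # then pick limiting subunits for pass2 (needs one gene in [2,10)) and
    # fail (needs one gene in [0,2))
    pickLimiting <- function(i, l, h, what) {
        for (g in subunitsOf(i)) {
            curLo <- if (is.na(lo[g])) 0 else lo[g]
            curHi <- if (is.na(hi[g])) Inf else hi[g]
            if (max(curLo, l) < min(curHi, h)) {
                narrow(g, l, h)
                return(invisible(NULL))
            }
        }
        stop(sprintf(
            "contradictory design: pair %d ('%s'-'%s') cannot %s — every subunit is pinned above the band",
            i, pairs$ligand[i], pairs$receptor[i], what))
    }
    for (i in which(design == "pass2")) pickLimiting(i, 2, 10, "stay below 10 TPM")
    for (i in which(design == "fail")) pickLimiting(i, 0, 2, "fail at 2 TPM")

    withr::with_seed(as.integer(seed), {
        tpm <- vapply(genes, function(g) {
            l <- if (is.na(lo[g])) 10 else lo[g]
            h <- if (is.na(hi[g])) 100 else hi[g]
            runif(1, l, h)
        }, numeric(1))
    })
    data.frame(gene = rep(genes, times = length(cellTypes)),
               cell_type = rep(cellTypes, each = length(genes)),
               tpm = rep(unname(tpm), times = length(cellTypes)),
               stringsAsFactors = FALSE)
}

#' Synthesize a phospho-flow table with known fold changes
#'
#' Monoculture phospho (pX) and total (X) percent-positive fractions are
#' drawn, the co-culture phospho/total ratio is set to the monoculture
#' ratio times the configured true fold change, and multiplicative Gaussian
#' noise is applied to each percentage. Noise pushing a percentage outside
#' (0, 100] is resampled (with a warning); recovery error vanishes as
#' `noiseSd` goes to 0.
#'
#' @param trueFold named numeric vector of fold changes (> 0), one per
#'   marker.
#' @param noiseSd sd of the multiplicative noise (fraction).
#' @param seed integer seed.
#' @param population cell population label.
#' @return data.frame with `marker`, `population`, `condition`, `pX`, `X`.
#' @export
synthFlow <- function(trueFold, noiseSd = 0, seed, population = "CD8T") {
    stopifnot(all(trueFold > 0), !is.null(names(trueFold)))
    withr::with_seed(as.integer(seed), {
        n <- length(trueFold)
        XMono <- runif(n, 60, 90)
        pMono <- runif(n, 5, 20)
        XCo <- runif(n, 60, 90)
        pCo <- (pMono / XMono) * trueFold * XCo
        if (any(pCo > 100))
            stop("configured fold changes push co-culture pX above 100%")
        addNoise <- function(v) {
            if (noiseSd == 0) return(v)
            out <- v * (1 + rnorm(length(v), 0, noiseSd))
            bad <- which(out <= 0 | out > 100)
            if (length(bad)) {
                warning("noise pushed percentages outside (0,100]; resampled")
                for (i in bad) {
                    for (k in 1:100) {
                        cand <- v[i] * (1 + rnorm(1, 0, noiseSd))
                        if (cand > 0 && cand <= 100) { out[i] <- cand; break }
                    }
                    if (out[i] <= 0 || out[i] > 100) out[i] <- v[i]
                }
            }
            out
        }
        data.frame(
            marker = rep(names(trueFold), 2),
            population = population,
            condition = rep(c("monoculture", "co-culture"), each = n),
            pX = c(addNoise(pMono), addNoise(pCo)),
            X = c(addNoise(XMono), addNoise(XCo)),
            stringsAsFactors = FALSE)
    })
}
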