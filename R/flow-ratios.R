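#' Phospho/total fold change, co-culture over monoculture
#'
#' The heatmap statistic for phospho-signaling: the co-culture
#' phospho-to-total ratio normalized to the monoculture ratio,
#' `(pX_co / X_co) / (pX_mono / X_mono)`. Values above 1 mean the partner
#' cell type increased the marker's phosphorylated share. Accepts
#' percent-positive fractions or MFI — any positive readout for which the
#' within-condition ratio is meaningful.
#'
#' @param pXco,Xco phospho and total readouts in co-culture (> 0).
#' @param pXmono,Xmono phospho and total readouts in monoculture (> 0).
#' @return dimensionless fold change (vectorized).
#' @examples
#' phosphoFoldChange(40, 80, 20, 80)   # 2
#' @export
phosphoFoldChange <- function(pXco, Xco, pXmono, Xmono) {
    vals <- list(pXco = pXco, Xco = Xco, pXmono = pXmono, Xmono = Xmono)
    for (nm in names(vals))
        if (any(!is.finite(vals[[nm]]) | vals[[nm]] <= 0))
            stop(sprintf("'%s' must be finite and > 0", nm))
    (pXco / Xco) / (pXmono / Xmono)
}

#' Fold-change table from long-format flow measurements
#'
#' @param flow data.frame with `marker`, `population`, `condition`
#'   ("monoculture"/"co-culture"), `pX`, `X` — the schema written by
#'   [synthFlow()].
#' @param log2 also emit the log2-transformed value (heatmap display
#'   convention); the raw ratio stays the canonical value.
#' @return data.frame with `marker`, `population`, `fold_change` (and
#'   `log2_fold_change` if requested).
#' @export
foldChangeTable <- function(flow, log2 = FALSE) {
    need <- c("marker", "population", "condition", "pX", "X")
    stopifnot(all(need %in% names(flow)))
    out <- do.call(rbind, lapply(
        split(flow, list(flow$marker, flow$population), drop = TRUE),
        function(g) {
            mono <- g[g$condition == "monoculture", ]
            co <- g[g$condition == "co-culture", ]
            if (nrow(mono) != 1L || nrow(co) != 1L)
                stop(sprintf(
                    "marker '%s' (%s): need exactly one row per condition",
                    g$marker[1], g$population[1]))
            data.frame(marker = g$marker[1], population = g$population[1],
                       fold_change = phosphoFoldChange(co$pX, co$X,
                                                       mono$pX, mono$X),
                       stringsAsFactors = FALSE)
        }))
    if (log2) out$log2_fold_change <- base::log2(out$fold_change)
    out <- out[order(out$population, out$marker), ]
    rownames(out) <- NULL
    out
}
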