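#' Parse a ligand-receptor pair table
#'
#' Multi-subunit complexes are encoded by joining gene symbols with a
#' separator (e.g. "ITGAL/ITGB2"). Symbols are upper-cased and de-duplicated
#' within a side; duplicate pairs are dropped with a warning; rows with an
#' empty gene field are rejected with a logged reason.
#'
#' @param rows data.frame with columns `ligand`, `receptor` and optionally
#'   `role`.
#' @param sep subunit separator ("/" or "-" depending on the table dialect).
#' @return data.frame with `ligand`, `receptor`, `role` plus list-columns
#'   `ligand_subunits`, `receptor_subunits`.
#' @examples
#' parsePairTable(data.frame(ligand = "ITGAL/ITGB2", receptor = "CD226"))
#' @export
parsePairTable <- function(rows, sep = "/") {
    stopifnot(all(c("ligand", "receptor") %in% names(rows)))
    if (is.null(rows$role)) rows$role <- ""
    splitSide <- function(s) {
        u <- toupper(trimws(strsplit(as.character(s), sep, fixed = TRUE)[[1]]))
        unique(u[nzchar(u)])
    }
    keep <- logical(nrow(rows))
    lig <- rec <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
        lig[[i]] <- splitSide(rows$ligand[i])
        rec[[i]] <- splitSide(rows$receptor[i])
        if (!length(lig[[i]]) || !length(rec[[i]])) {
            message(sprintf("parsePairTable: row %d rejected (empty gene field)", i))
        } else keep[i] <- TRUE
    }
    out <- data.frame(
        ligand = vapply(lig, paste, "", collapse = sep)[keep],
        receptor = vapply(rec, paste, "", collapse = sep)[keep],
        role = as.character(rows$role)[keep],
        stringsAsFactors = FALSE)
    out$ligand_subunits <- lig[keep]
    out$receptor_subunits <- rec[keep]
    key <- paste(out$ligand, out$receptor)
    if (anyDuplicated(key)) {
        warning(sprintf("parsePairTable: %d duplicate pair(s) dropped",
                        sum(duplicated(key))))
        out <- out[!duplicated(key), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

.tpmLookup <- function(expr, gene, cell) {
    i <- which(expr$gene == gene & expr$cell_type == cell)
    if (!length(i)) NA_real_ else expr$tpm[i[1]]
}

# tri-state pass/fail/unevaluable for one direction
.screenOne <- function(pair, expr, threshold, ligandCell, receptorCell) {
    tl <- vapply(pair$ligand_subunits[[1]], .tpmLookup, numeric(1),
                 expr = expr, cell = ligandCell)
    tr <- vapply(pair$receptor_subunits[[1]], .tpmLookup, numeric(1),
                 expr = expr, cell = receptorCell)
    v <- c(tl, tr)
    if (anyNA(v)) return("unevaluable")
    if (all(v >= threshold)) "pass" else "fail"
}

#' Screen ligand-receptor pairs against a TPM expression table
#'
#' A pair passes iff every ligand subunit reaches the threshold (inclusive)
#' in the ligand cell type and every receptor subunit in the receptor cell
#' type — the all-subunits rule for complexes. Direction "forward" requires
#' the ligand in `ligandCell`, "reverse" swaps the cell types, and "either"
#' (default, matching the bidirectional crosstalk framing) passes a pair
#' that passes in at least one direction. Pairs containing a gene absent
#' from the table are "unevaluable" and never counted as pass or fail.
#'
#' @param pairs output of [parsePairTable()].
#' @param expr data.frame with `gene`, `cell_type`, `tpm` (TPM >= 0; a
#'   missing gene is an explicit miss, never a silent 0).
#' @param threshold TPM threshold (> 0).
#' @param ligandCell,receptorCell cell-type labels in `expr`.
#' @param direction "either", "forward" or "reverse".
#' @return a [ScreenResult-class].
#' @export
screenPairs <- function(pairs, expr, threshold,
                        ligandCell = "CD8T", receptorCell = "NK",
                        direction = c("either", "forward", "reverse")) {
    direction <- match.arg(direction)
    if (threshold <= 0) stop("threshold must be > 0")
    stopifnot(all(c("gene", "cell_type", "tpm") %in% names(expr)))
    if (!all(c(ligandCell, receptorCell) %in% expr$cell_type))
        stop("unknown cell type: ",
             paste(setdiff(c(ligandCell, receptorCell), expr$cell_type),
                   collapse = ", "))
    state <- vapply(seq_len(nrow(pairs)), function(i) {
        pr <- pairs[i, , drop = FALSE]
        fw <- .screenOne(pr, expr, threshold, ligandCell, receptorCell)
        if (direction == "forward") return(fw)
        rv <- .screenOne(pr, expr, threshold, receptorCell, ligandCell)
        if (direction == "reverse") return(rv)
        if (fw == "pass" || rv == "pass") "pass"
        else if (fw == "fail" && rv == "fail") "fail"
        else "unevaluable"
    }, character(1))
    new("ScreenResult", threshold = as.numeric(threshold),
        direction = direction, ligandCell = ligandCell,
        receptorCell = receptorCell,
        pass = pairs[state == "pass", , drop = FALSE],
        fail = pairs[state == "fail", , drop = FALSE],
        unevaluable = pairs[state == "unevaluable", , drop = FALSE])
}

#' Count passing pairs per threshold category
#'
#' @param flags data.frame with logical columns `tpm2` and `tpm10` (pair
#'   passes at >= 2 / >= 10 TPM). A pair passing at 10 but not at 2 is a
#'   contradiction and raises an error.
#' @return named integer vector `c(tpm2 = ..., tpm10 = ...)`.
#' @examples
#' countByThreshold(data.frame(tpm2 = c(TRUE, TRUE), tpm10 = c(TRUE, FALSE)))
#' @export
countByThreshold <- function(flags) {
    stopifnot(all(c("tpm2", "tpm10") %in% names(flags)))
    bad <- which(flags$tpm10 & !flags$tpm2)
    if (length(bad))
        stop("inconsistent flags (pass at >=10 but not >=2) in row(s): ",
             paste(bad, collapse = ", "))
    c(tpm2 = sum(flags$tpm2), tpm10 = sum(flags$tpm10))
}

#' The packaged crosstalk pair table
#'
#' The published table of 16 key ligand-receptor interactions between
#' activated CD8 T and NK cells, with pass flags at the >= 2 and >= 10 TPM
#' thresholds and a functional role per pair (16 pass at >= 2 TPM, 9 at
#' >= 10 TPM).
#'
#' @return data.frame with `ligand`, `receptor`, `tpm2`, `tpm10`, `role`.
#' @export
lrPairsTable1 <- function() {
    f <- system.file("extdata", "table1_lr_pairs.csv",
                     package = "SynapseKinetics", mustWork = TRUE)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    d$tpm2 <- d$tpm2 == "YES"
    d$tpm10 <- d$tpm10 == "YES"
    d
}
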