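#' Build an LD reference from a genotype dosage panel
#'
#' @param panel numeric matrix of dosages (individuals in rows, SNPs in named
#'   columns, values in \[0,2\]). r² between two variants is the squared
#'   Pearson correlation of their dosage columns.
#' @return an [LDReference-class].
#' @export
ldFromPanel <- function(panel) {
    if (is.null(colnames(panel))) stop("panel columns must be named by SNP id")
    new("LDReference", panel = as.matrix(panel), pairs = numeric())
}

#' Build an LD reference from an explicit pair table
#'
#' @param pairTable data.frame with columns `SNP_A`, `SNP_B`, `R2` (r² in
#'   \[0,1\]). Symmetry is enforced by storing both orderings.
#' @return an [LDReference-class].
#' @export
ldFromTable <- function(pairTable) {
    stopifnot(all(c("SNP_A", "SNP_B", "R2") %in% names(pairTable)))
    if (any(pairTable$R2 < 0 | pairTable$R2 > 1))
        stop("r2 values must lie in [0, 1]")
    if (nrow(pairTable) == 0L)
        return(new("LDReference", panel = matrix(numeric(), 0, 0),
                   pairs = numeric()))
    keys <- c(paste0(pairTable$SNP_A, "|", pairTable$SNP_B),
              paste0(pairTable$SNP_B, "|", pairTable$SNP_A))
    vals <- rep(pairTable$R2, 2)
    new("LDReference", panel = matrix(numeric(), 0, 0), pairs = setNames(vals, keys))
}

#' Pairwise r² lookup
#'
#' Returns r² between two variants; a variant with itself gives 1, and pairs
#' absent from the reference are treated as independent (r² = 0) with a
#' one-time warning per call site.
#'
#' @param ld an [LDReference-class].
#' @param snpA,snpB variant ids (vectorized, recycled).
#' @param warnMissing emit a warning when a pair is absent (default TRUE).
#' @return numeric vector of r² values.
#' @export
ldR2 <- function(ld, snpA, snpB, warnMissing = TRUE) {
    n <- max(length(snpA), length(snpB))
    snpA <- rep_len(snpA, n); snpB <- rep_len(snpB, n)
    out <- numeric(n)
    same <- snpA == snpB
    out[same] <- 1
    idx <- which(!same)
    if (length(idx) == 0L) return(out)
    missing <- FALSE
    if (ncol(ld@panel) > 0L) {
        have <- colnames(ld@panel)
        for (i in idx) {
            if (snpA[i] %in% have && snpB[i] %in% have) {
                r <- suppressWarnings(cor(ld@panel[, snpA[i]], ld@panel[, snpB[i]]))
                out[i] <- if (is.na(r)) 0 else r^2
            } else missing <- TRUE
        }
    } else {
        keys <- paste0(snpA[idx], "|", snpB[idx])
        hit <- ld@pairs[keys]
        miss <- is.na(hit)
        out[idx] <- ifelse(miss, 0, hit)
        missing <- any(miss)
    }
    if (missing && warnMissing)
        warning("variant pair(s) absent from LD reference treated as r2 = 0")
    out
}

#' Greedy LD clumping of summary statistics
#'
#' P-value-ordered greedy selection: records are visited by ascending P (ties
#' broken by smaller position), and a record is retained iff its r² with every
#' already-retained record on the same chromosome within `windowBp` base pairs
#' (inclusive) is strictly below `r2Max`. Retained records keep their input
#' content; order of the output follows the input.
#'
#' @param records summary-statistics data.frame (needs `SNP CHR BP P`).
#' @param ld an [LDReference-class].
#' @param r2Max r² exclusion threshold (default 0.2).
#' @param windowBp window half-width in base pairs (default 250000, i.e.
#'   variants with |position difference| <= 250 kb are compared).
#' @return the retained records, input order preserved.
#' @export
ldClump <- function(records, ld, r2Max = 0.2, windowBp = 250000) {
    if (nrow(records) == 0L) return(records)
    ord <- order(records$P, records$BP)
    accepted <- integer(0)
    for (i in ord) {
        nearby <- accepted[records$CHR[accepted] == records$CHR[i] &
                           abs(records$BP[accepted] - records$BP[i]) <= windowBp]
        ok <- TRUE
        if (length(nearby)) {
            r2 <- ldR2(ld, records$SNP[i], records$SNP[nearby], warnMissing = FALSE)
            ok <- all(r2 < r2Max)
        }
        if (ok) accepted <- c(accepted, i)
    }
    out <- records[sort(accepted), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Window-based LD pruning of summary statistics
#'
#' Position-ordered pairwise pruning: any two variants on the same chromosome
#' within `windowBp` base pairs (inclusive) whose r² is >= `r2Max` cannot both
#' survive, and the later-position member of a violating pair is always the
#' one removed. The retained set is defined inductively in position order — a
#' variant survives iff every earlier *surviving* variant within the window
#' has r² < `r2Max` with it — which makes the output deterministic and a
#' fixed point of the removal rule (no surviving pair violates it). Because
#' the drop rule is position-deterministic the result does not depend on how
#' a scan window slides; `stepSnps` is accepted for interface compatibility
#' with the conventional (window, step, r²) parameter triple but cannot
#' change the result.
#'
#' @param records summary-statistics data.frame (needs `SNP CHR BP`).
#' @param ld an [LDReference-class].
#' @param windowBp window width in base pairs (default 250000).
#' @param stepSnps conventional step-size parameter; result-invariant.
#' @param r2Max r² removal threshold (default 0.1; removal at `r2 >= r2Max`).
#' @return the retained records, input order preserved.
#' @export
ldPrune <- function(records, ld, windowBp = 250000, stepSnps = 5, r2Max = 0.1) {
    if (nrow(records) == 0L) return(records)
    keepAll <- logical(nrow(records))
    for (chr in unique(records$CHR)) {
        idx <- which(records$CHR == chr)
        idx <- idx[order(records$BP[idx])]
        bp <- records$BP[idx]
        alive <- rep(TRUE, length(idx))
        for (a in seq_along(idx)) {
            if (!alive[a]) next
            b <- a + 1L
            while (b <= length(idx) && bp[b] - bp[a] <= windowBp) {
                if (alive[b]) {
                    r2 <- ldR2(ld, records$SNP[idx[a]], records$SNP[idx[b]],
                               warnMissing = FALSE)
                    if (r2 >= r2Max) alive[b] <- FALSE  # later position loses
                }
                b <- b + 1L
            }
        }
        keepAll[idx[alive]] <- TRUE
    }
    out <- records[keepAll, , drop = FALSE]
    rownames(out) <- NULL
    out
}
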