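#' GWAS summary-statistics tables
#'
#' Summary statistics travel through the package as plain data.frames with the
#' documented column contract `SNP CHR BP EA OA EAF BETA SE P INFO`: variant
#' id, chromosome label, 1-based position, effect and other allele (A/C/G/T),
#' effect-allele frequency in (0,1), per-allele log-odds, its standard error
#' (> 0), two-sided P-value in (0,1], and imputation quality in \[0,1\].
#' [readSumstats()] ingests delimited text (gzip transparently), maps
#' alternative headers, and drops rows violating the invariants with a logged
#' count.
#'
#' @param path file to read (TSV/CSV, optionally gzipped, header required).
#' @param columnMap optional named character vector mapping canonical names to
#'   the file's header names, e.g. `c(SNP = "rsid", BETA = "OR")`. When the
#'   `BETA` source column is named `"OR"` (case-insensitive) its values are
#'   treated as odds ratios and converted via `log()`.
#' @return data.frame of validated records, with attribute `"n_dropped"`
#'   giving the number of rows removed by validation.
#' @seealso [writeSumstats()], [harmonizeSumstats()], [filterSumstats()]
#' @export
readSumstats <- function(path, columnMap = NULL) {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    canonical <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "P", "INFO")
    if (!is.null(columnMap)) {
        for (canon in names(columnMap)) {
            src <- columnMap[[canon]]
            if (!src %in% names(dt))
                stop("column map names absent column: ", src)
            if (canon == "BETA" && toupper(src) == "OR") {
                dt[[src]] <- log(dt[[src]])
            }
            names(dt)[names(dt) == src] <- canon
        }
    }
    mandatory <- setdiff(canonical, "INFO")
    missing <- setdiff(mandatory, names(dt))
    if (length(missing))
        stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    if (!"INFO" %in% names(dt)) dt$INFO <- 1
    dt <- dt[, canonical]
    dt$SNP <- as.character(dt$SNP)
    dt$CHR <- as.character(dt$CHR)
    validateSumstats(dt)
}

#' Validate summary-statistic records
#'
#' Enforces the record invariants (SE > 0, distinct A/C/G/T alleles, EAF in
#' (0,1), P in (0,1], INFO in \[0,1\]) by dropping violating rows with a
#' message, and warns when a P-value disagrees grossly with the two-sided
#' normal P implied by BETA/SE (rounding slack of one order of magnitude is
#' tolerated).
#'
#' @param records summary-statistics data.frame.
#' @return the retained records, attribute `"n_dropped"` set.
#' @export
validateSumstats <- function(records) {
    bases <- c("A", "C", "G", "T")
    ok <- is.finite(records$BETA) & is.finite(records$SE) & records$SE > 0 &
        records$EA %in% bases & records$OA %in% bases &
        records$EA != records$OA &
        records$EAF > 0 & records$EAF < 1 &
        records$P > 0 & records$P <= 1 &
        records$INFO >= 0 & records$INFO <= 1
    ok[is.na(ok)] <- FALSE
    nDropped <- sum(!ok)
    if (nDropped > 0)
        message(nDropped, " record(s) dropped by summary-statistic validation")
    out <- records[ok, , drop = FALSE]
    rownames(out) <- NULL
    implied <- waldP(out$BETA, out$SE)
    loose <- abs(log10(pmax(out$P, 1e-300)) - log10(pmax(implied, 1e-300))) > 1
    if (any(loose, na.rm = TRUE))
        warning(sum(loose, na.rm = TRUE),
                " record(s) have P inconsistent with BETA/SE beyond rounding")
    attr(out, "n_dropped") <- nDropped
    out
}

#' Write summary statistics in the package's TSV dialect
#'
#' @param records summary-statistics data.frame.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(records, path) {
    data.table::fwrite(records, path, sep = "\t", compress = "auto")
    invisible(path)
}

complementBase <- c(A = "T", C = "G", G = "C", T = "A")

isPalindromic <- function(ea, oa) complementBase[ea] == oa

#' Harmonize two summary-statistics tables onto shared effect alleles
#'
#' Intersects two tables on variant id and aligns table `b`'s effects to table
#' `a`'s effect allele: swapped effect/other alleles negate `b`'s beta and
#' complement its frequency; strand flips are resolved by base-complementing
#' `b`'s alleles before matching. Palindromic (A/T, C/G) variants whose
#' effect-allele frequency falls in \[0.4, 0.6\] in either table are dropped as
#' strand-ambiguous, and variants whose allele sets cannot be reconciled are
#' dropped with a reason code.
#'
#' @param a,b summary-statistics data.frames (`a` = incidence, `b` =
#'   prognosis in the index-event workflow).
#' @return a `PairedEffects` data.frame: columns `SNP CHR BP EA OA EAF`
#'   (from `a`) plus `BETA_INC SE_INC P_INC INFO_INC BETA_PROG SE_PROG P_PROG
#'   INFO_PROG`; attribute `"drops"` tabulates drop reasons.
#' @export
harmonizeSumstats <- function(a, b) {
    shared <- intersect(a$SNP, b$SNP)
    a <- a[match(shared, a$SNP), , drop = FALSE]
    b <- b[match(shared, b$SNP), , drop = FALSE]
    n <- length(shared)
    keep <- rep(TRUE, n)
    reason <- rep(NA_character_, n)
    betaB <- b$BETA
    eafB <- b$EAF

    for (i in seq_len(n)) {
        eaA <- a$EA[i]; oaA <- a$OA[i]
        eaB <- b$EA[i]; oaB <- b$OA[i]
        pal <- isPalindromic(eaA, oaA)
        if (pal && (between04_06(a$EAF[i]) || between04_06(b$EAF[i]))) {
            keep[i] <- FALSE; reason[i] <- "palindromic_ambiguous"
            next
        }
        if (eaB == eaA && oaB == oaA) {
            # already aligned
        } else if (eaB == oaA && oaB == eaA) {
            betaB[i] <- -betaB[i]; eafB[i] <- 1 - eafB[i]
        } else {
            # try strand flip of b
            eaBf <- complementBase[[eaB]]; oaBf <- complementBase[[oaB]]
            if (eaBf == eaA && oaBf == oaA) {
                # same orientation on the other strand
            } else if (eaBf == oaA && oaBf == eaA) {
                betaB[i] <- -betaB[i]; eafB[i] <- 1 - eafB[i]
            } else {
                keep[i] <- FALSE; reason[i] <- "allele_mismatch"
            }
        }
    }
    out <- data.frame(
        SNP = a$SNP, CHR = a$CHR, BP = a$BP, EA = a$EA, OA = a$OA,
        EAF = a$EAF,
        BETA_INC = a$BETA, SE_INC = a$SE, P_INC = a$P, INFO_INC = a$INFO,
        BETA_PROG = betaB, SE_PROG = b$SE, P_PROG = b$P, INFO_PROG = b$INFO,
        stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "drops") <- table(reason[!keep])
    out
}

between04_06 <- function(x) x >= 0.4 & x <= 0.6

#' Filter summary statistics on P-value and imputation quality
#'
#' Thresholds are strict, matching the conventional phrasing "P < p" and
#' "INFO > info": a record with `P == pMax` or `INFO == infoMin` is removed.
#' Omitted thresholds are not applied; with both omitted the input is
#' returned unchanged.
#'
#' @param records summary-statistics data.frame.
#' @param pMax retain records with `P < pMax`.
#' @param infoMin retain records with `INFO > infoMin`.
#' @return the filtered records.
#' @export
filterSumstats <- function(records, pMax = NULL, infoMin = NULL) {
    if (!is.null(pMax)) {
        if (!"P" %in% names(records)) stop("records lack a P column")
        records <- records[records$P < pMax, , drop = FALSE]
    }
    if (!is.null(infoMin)) {
        if (!"INFO" %in% names(records)) stop("records lack an INFO column")
        records <- records[records$INFO > infoMin, , drop = FALSE]
    }
    rownames(records) <- NULL
    records
}
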