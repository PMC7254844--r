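# Shared fixtures and independent oracle implementations.

.fxCache <- new.env()

fixtures <- function() {
    if (is.null(.fxCache$fx))
        .fxCache$fx <- suppressWarnings(generateFixtures(seed = 42))
    .fxCache$fx
}

# Random summary-statistics table with internally consistent P-values.
makeSumstats <- function(n, seed = 1, chr = NULL, bp = NULL) {
    withr_seed <- function(expr) { set.seed(seed); expr }
    withr_seed({
        beta <- rnorm(n, 0, 0.1)
        se <- runif(n, 0.01, 0.05)
        pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
        al <- pairs[sample.int(4, n, replace = TRUE)]
        data.frame(
            SNP = sprintf("rs%04d", seq_len(n)),
            CHR = if (is.null(chr)) as.character(sample.int(2, n, TRUE)) else chr,
            BP = if (is.null(bp)) sort(sample.int(2e6, n)) else bp,
            EA = vapply(al, `[`, "", 1), OA = vapply(al, `[`, "", 2),
            EAF = runif(n, 0.05, 0.95),
            BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)),
            INFO = 1, stringsAsFactors = FALSE)
    })
}

# Random symmetric r2 table over a SNP set.
makeLDTable <- function(snps, seed = 1, density = 0.4) {
    set.seed(seed)
    cmb <- utils::combn(snps, 2)
    keep <- runif(ncol(cmb)) < density
    data.frame(SNP_A = cmb[1, keep], SNP_B = cmb[2, keep],
               R2 = runif(sum(keep)), stringsAsFactors = FALSE)
}

# --- Independent brute-force oracles ---------------------------------------

# r2 lookup against a pair table, written from scratch.
oracleR2 <- function(tab, a, b) {
    if (a == b) return(1)
    hit <- (tab$SNP_A == a & tab$SNP_B == b) | (tab$SNP_A == b & tab$SNP_B == a)
    if (any(hit)) tab$R2[which(hit)[1]] else 0
}

# Greedy clumping by ascending P (ties: smaller BP), acceptance requires
# r2 < r2max against every accepted SNP on the same chromosome within the
# inclusive window.
oracleClump <- function(rec, ldtab, r2max, window) {
    ord <- order(rec$P, rec$BP)
    acc <- integer(0)
    for (i in ord) {
        ok <- TRUE
        for (j in acc) {
            if (rec$CHR[j] == rec$CHR[i] &&
                abs(rec$BP[j] - rec$BP[i]) <= window &&
                oracleR2(ldtab, rec$SNP[i], rec$SNP[j]) >= r2max) {
                ok <- FALSE; break
            }
        }
        if (ok) acc <- c(acc, i)
    }
    rec[sort(acc), , drop = FALSE]
}

# Pruning by the inductive definition: walking SNPs in position order per
# chromosome, a SNP survives iff every earlier survivor within the window has
# r2 < r2max with it.
oraclePrune <- function(rec, ldtab, r2max, window) {
    keep <- logical(nrow(rec))
    for (chr in unique(rec$CHR)) {
        idx <- which(rec$CHR == chr)
        idx <- idx[order(rec$BP[idx])]
        surv <- integer(0)
        for (i in idx) {
            ok <- TRUE
            for (j in surv) {
                if (rec$BP[i] - rec$BP[j] <= window &&
                    oracleR2(ldtab, rec$SNP[i], rec$SNP[j]) >= r2max) {
                    ok <- FALSE; break
                }
            }
            if (ok) surv <- c(surv, i)
        }
        keep[surv] <- TRUE
    }
    rec[keep, , drop = FALSE]
}

# PairedEffects builder for slope/IVW tests.
makePairs <- function(b1, b2, se1, se2, p1 = NULL) {
    n <- length(b1)
    data.frame(SNP = sprintf("rs%04d", seq_len(n)),
               CHR = "1", BP = seq_len(n) * 1000L,
               EA = "A", OA = "G", EAF = 0.5,
               BETA_INC = b1, SE_INC = rep_len(se1, n),
               P_INC = p1 %||% 2 * pnorm(-abs(b1 / rep_len(se1, n))),
               INFO_INC = 1,
               BETA_PROG = b2, SE_PROG = rep_len(se2, n),
               P_PROG = 2 * pnorm(-abs(b2 / rep_len(se2, n))),
               INFO_PROG = 1, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_local_tempfile <- function() tempfile(fileext = ".tsv")
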