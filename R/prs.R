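#' Build a P-value-thresholded, LD-clumped polygenic score model
#'
#' Retains records with `P < pThreshold`, removes correlated survivors by
#' greedy LD clumping ([ldClump()]), and takes each surviving SNP's GWAS
#' log-odds estimate as its score weight — the classical clumping +
#' thresholding construction.
#'
#' @param records validated incidence summary statistics.
#' @param ld an [LDReference-class].
#' @param pThreshold P-value inclusion criterion (default 5e-6).
#' @param r2Max,windowBp clumping parameters (defaults 0.2 and 250000).
#' @return a [PRSModel-class]; provenance records the thresholds and the
#'   record counts at each stage.
#' @export
buildPRSModel <- function(records, ld, pThreshold = 5e-6,
                          r2Max = 0.2, windowBp = 250000) {
    surv <- filterSumstats(records, pMax = pThreshold)
    clumped <- ldClump(surv, ld, r2Max = r2Max, windowBp = windowBp)
    if (nrow(clumped) == 0L) stop("empty model: no records survive thresholds")
    new("PRSModel",
        entries = data.frame(snp = clumped$SNP, ea = clumped$EA,
                             weight = clumped$BETA, stringsAsFactors = FALSE),
        provenance = list(p_threshold = pThreshold, r2_max = r2Max,
                          window_bp = windowBp,
                          n_input = nrow(records), n_after_p = nrow(surv),
                          n_final = nrow(clumped)))
}

#' Score individuals with a PRS model
#'
#' Computes `score_i = sum_j w_j * dosage_ij` over the model's variants.
#' Dosages are assumed to count the allele named in `dosageAlleles` (defaults
#' to the model's effect alleles); where the counted allele is the model's
#' other allele the dosage is reflected to `2 - dosage`, so flipping a model
#' entry's allele and negating its weight shifts raw scores only by the
#' constant `2w` (standardized scores are unchanged). Missing
#' dosages are mean-imputed with `2 * eaf` when an allele frequency is known,
#' otherwise with the column mean.
#'
#' @param genotypes individuals x SNPs dosage matrix with SNP-named columns,
#'   or a cohort `SummarizedExperiment`.
#' @param model a [PRSModel-class].
#' @param dosageAlleles optional named character vector giving the allele each
#'   genotype column counts (names = SNP ids).
#' @param eaf optional named numeric vector of effect-allele frequencies used
#'   for missing-dosage imputation.
#' @return numeric vector of raw scores, one per individual.
#' @export
scoreIndividuals <- function(genotypes, model, dosageAlleles = NULL, eaf = NULL) {
    if (methods::is(genotypes, "SummarizedExperiment"))
        genotypes <- dosages(genotypes)
    entries <- modelEntries(model)
    absent <- setdiff(entries$snp, colnames(genotypes))
    if (length(absent))
        stop("model variants absent from genotypes: ",
             paste(absent, collapse = ", "))
    g <- genotypes[, entries$snp, drop = FALSE]
    if (!is.null(dosageAlleles)) {
        counted <- dosageAlleles[entries$snp]
        flip <- !is.na(counted) & counted != entries$ea
        if (any(flip)) g[, flip] <- 2 - g[, flip]
    }
    if (anyNA(g)) {
        for (j in seq_len(ncol(g))) {
            nas <- is.na(g[, j])
            if (!any(nas)) next
            fill <- if (!is.null(eaf) && !is.na(eaf[entries$snp[j]]))
                2 * eaf[[entries$snp[j]]]
            else mean(g[, j], na.rm = TRUE)
            g[nas, j] <- fill
        }
    }
    as.vector(g %*% entries$weight)
}

#' Standardize a score to zero mean and unit SD
#'
#' Uses the sample SD (n-1 denominator) over the full vector supplied — the
#' pooled, unstratified sample — so per-SD effects share a unit across strata.
#'
#' @param scores numeric vector with at least two distinct values.
#' @return z-scores.
#' @export
standardizeScore <- function(scores) {
    if (length(unique(scores)) < 2L) stop("constant scores cannot be standardized")
    (scores - mean(scores)) / sd(scores)
}

#' Persist / load a PRS model
#'
#' Written as a 3-column TSV `SNP EA WEIGHT` with a JSON provenance sidecar.
#'
#' @param model a [PRSModel-class].
#' @param path output TSV path.
#' @return `path` invisibly (write); a [PRSModel-class] (read).
#' @export
writePRSModel <- function(model, path) {
    e <- modelEntries(model)
    data.table::fwrite(data.frame(SNP = e$snp, EA = e$ea, WEIGHT = e$weight),
                       path, sep = "\t")
    jsonlite::write_json(modelProvenance(model), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePRSModel
#' @export
readPRSModel <- function(path) {
    tab <- data.table::fread(path, data.table = FALSE)
    prov <- if (file.exists(paste0(path, ".json")))
        jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    else list()
    new("PRSModel",
        entries = data.frame(snp = tab$SNP, ea = tab$EA, weight = tab$WEIGHT,
                             stringsAsFactors = FALSE),
        provenance = prov)
}
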