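# Per-SNP logistic GWAS on simulated cohorts.

# One logistic fit per SNP with shared covariates; returns beta/se/p for the
# SNP term plus a flag for non-converged or separated fits. Uses glm.fit with
# the same IRLS machinery as stats::glm, with (X'WX)^-1 standard errors.
snpLogistic <- function(g, y, covars) {
    m <- ncol(g)
    Xbase <- cbind(`(Intercept)` = 1, snp = 0, as.matrix(covars))
    beta <- se <- rep(NA_real_, m)
    flag <- rep(FALSE, m)
    for (j in seq_len(m)) {
        x <- g[, j]
        if (var(x) == 0) { flag[j] <- TRUE; next }
        Xbase[, "snp"] <- x
        fit <- tryCatch(
            suppressWarnings(glm.fit(Xbase, y, family = binomial())),
            error = function(e) NULL)
        if (is.null(fit) || !fit$converged || fit$boundary) {
            flag[j] <- TRUE; next
        }
        p <- fit$rank
        covUnscaled <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
        sej <- sqrt(diag(covUnscaled))[2L]
        if (!is.finite(sej) || sej > 50 || abs(fit$coefficients[2L]) > 20) {
            flag[j] <- TRUE; next  # effective separation
        }
        beta[j] <- fit$coefficients[2L]
        se[j] <- sej
    }
    data.frame(beta = beta, se = se, p = waldP(beta, se), flag = flag)
}

#' Simulate an external incidence GWAS
#'
#' Draws a fresh case-control sample under the same generative configuration
#' (the two-sample design: incidence effects come from a study independent of
#' the prognosis cohort) and fits one logistic regression of case status on
#' each SNP's dosage, adjusted for age and sex. Monomorphic or non-converged
#' SNPs are dropped with a warning.
#'
#' @param config a [SimConfig-class].
#' @param nSample size of the external sample (default `config@nIndividuals`).
#' @param seed RNG seed for the external sample (default derived from the
#'   config seed, distinct from the cohort's).
#' @return a summary-statistics data.frame (`SNP CHR BP EA OA EAF BETA SE P
#'   INFO`), with `INFO = 1` for simulated genotypes and `EAF` the observed
#'   effect-allele frequency.
#' @export
gwasIncidence <- function(config, nSample = config@nIndividuals,
                          seed = childSeed(config@seed, "external")) {
    ext <- simConfig(
        nIndividuals = nSample, nSnps = config@nSnps, seed = seed,
        alleleFreqs = config@alleleFreqs, betaIncidence = config@betaIncidence,
        betaPrognosisDirect = config@betaPrognosisDirect,
        gammaU = config@gammaU, deltaU = config@deltaU,
        varSharedFactor = config@varSharedFactor,
        incidenceThreshold = config@incidenceThreshold,
        survivalCoefficient = config@survivalCoefficient,
        recruitIntercept = config@recruitIntercept,
        covariateEffects = config@covariateEffects,
        prognosisIntercept = config@prognosisIntercept,
        incidenceModel = config@incidenceModel,
        ldRho = config@ldRho, ldBlockSize = config@ldBlockSize,
        positionSpacing = config@positionSpacing)
    coh <- simulateIncidence(newCohort(ext))
    ph <- phenotypes(coh)
    g <- dosages(coh)
    fits <- snpLogistic(g, as.integer(ph$prevalentCase),
                        data.frame(age = ageZ(ph$age), sex = ph$sex))
    ann <- snpAnnotation(config)
    out <- data.frame(ann,
                      EAF = colMeans(g) / 2,
                      BETA = fits$beta, SE = fits$se, P = fits$p, INFO = 1,
                      stringsAsFactors = FALSE)
    if (any(fits$flag)) {
        warning(sum(fits$flag),
                " SNP(s) dropped from incidence GWAS (monomorphic or unstable fit)")
        out <- out[!fits$flag, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' GWAS of prognosis among recruited cases
#'
#' Fits one logistic regression of a post-baseline outcome on each SNP's
#' dosage within the recruited prevalent-case stratum, adjusted for age and
#' sex (the simulator's stand-ins for the covariates a real analysis would
#' include). SNPs with unstable fits (separation, non-convergence,
#' monomorphism in the stratum) are flagged and excluded with a warning.
#'
#' @param cohort a fully simulated cohort.
#' @param outcome name of the binary outcome column (default `"death"`).
#' @param covariates phenotype columns to adjust for (age is standardized
#'   internally).
#' @return a summary-statistics data.frame as in [gwasIncidence()].
#' @export
gwasPrognosis <- function(cohort, outcome = "death",
                          covariates = c("age", "sex")) {
    ph <- phenotypes(cohort)
    keep <- which(ph$recruited & ph$prevalentCase)
    if (length(keep) == 0L) stop("empty case stratum")
    y <- ph[[outcome]][keep]
    if (is.null(y)) stop("unknown outcome column: ", outcome)
    if (length(unique(y)) < 2L) stop("degenerate outcome: single class")
    covs <- ph[keep, covariates, drop = FALSE]
    if ("age" %in% names(covs)) covs$age <- ageZ(covs$age)
    g <- dosages(cohort)[keep, , drop = FALSE]
    fits <- snpLogistic(g, as.integer(y), covs)
    config <- cohortConfig(cohort)
    ann <- snpAnnotation(config)
    out <- data.frame(ann,
                      EAF = colMeans(g) / 2,
                      BETA = fits$beta, SE = fits$se, P = fits$p, INFO = 1,
                      stringsAsFactors = FALSE)
    if (any(fits$flag)) {
        warning(sum(fits$flag),
                " SNP(s) excluded from prognosis GWAS (separation or monomorphic)")
        out <- out[!fits$flag, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}
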