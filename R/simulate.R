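#' Construct a simulation configuration
#'
#' Builds a [SimConfig-class] describing a liability-threshold cohort with an
#' unmeasured shared risk factor and survival-dependent recruitment. The
#' defaults encode the *bias scenario*: positive per-SNP liability effects,
#' zero direct genetic effects on prognosis, a shared factor U raising both
#' disease liability (`gammaU`) and post-disease event risk (`deltaU`), and
#' selective pre-recruitment survival of less severe cases
#' (`survivalCoefficient`). Under these conditions case status is a collider
#' between the genetic score and U, so case-only associations between the
#' score and prognosis are biased towards protection even though the score
#' has no direct prognostic effect.
#'
#' Unspecified per-SNP quantities are drawn deterministically from `seed`:
#' allele frequencies from Uniform(0.05, 0.95) and incidence effects from
#' N(0, 0.08²). Age is drawn Uniform(40, 69) — the recruitment window of a
#' typical mid-life biobank — and enters the models standardized; sex is
#' Bernoulli(0.5) and enters centred. When `incidenceThreshold` is omitted it
#' is solved analytically (probit model) so the expected prevalence equals
#' `targetPrevalence`.
#'
#' @param nIndividuals cohort size.
#' @param nSnps number of SNPs.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param alleleFreqs optional per-SNP effect-allele frequencies in (0,1).
#' @param betaIncidence optional per-SNP liability effects.
#' @param betaPrognosisDirect per-SNP direct prognosis effects (scalar
#'   recycled; default 0 — the bias scenario).
#' @param gammaU,deltaU effects of the shared factor U on liability and on the
#'   prognosis logit.
#' @param varSharedFactor variance of U.
#' @param incidenceThreshold liability cutoff; if `NULL`, derived from
#'   `targetPrevalence`.
#' @param targetPrevalence expected disease prevalence used to place the
#'   threshold (default 0.05).
#' @param survivalCoefficient recruitment-logit decrease per within-case SD of
#'   liability.
#' @param recruitIntercept recruitment logit at mean case liability
#'   (default 1.5, i.e. ~82% of average-severity cases are recruited).
#' @param covariateEffects list with named vectors `incidence` and
#'   `prognosis`, elements `age` (per SD) and `sex`.
#' @param prognosisIntercept prognosis logit intercept (default -2.5, giving a
#'   roughly 20-25% event rate among cases once the shared factor is added).
#' @param incidenceModel `"probit"` (Gaussian liability, default) or
#'   `"logit"`.
#' @param ldRho adjacent-SNP latent correlation for optional block LD.
#' @param ldBlockSize SNPs per LD block.
#' @param positionSpacing base pairs between adjacent simulated SNPs.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nIndividuals = 10000, nSnps = 100, seed = 1,
                      alleleFreqs = NULL, betaIncidence = NULL,
                      betaPrognosisDirect = 0,
                      gammaU = 1, deltaU = 1, varSharedFactor = 1,
                      incidenceThreshold = NULL, targetPrevalence = 0.05,
                      survivalCoefficient = 1, recruitIntercept = 1.5,
                      covariateEffects = list(
                          incidence = c(age = 0.3, sex = 0.2),
                          prognosis = c(age = 0.3, sex = 0.2)),
                      prognosisIntercept = -2.5,
                      incidenceModel = c("probit", "logit"),
                      ldRho = 0, ldBlockSize = 10, positionSpacing = 50000) {
    incidenceModel <- match.arg(incidenceModel)
    seed <- as.integer(seed)
    if (is.null(alleleFreqs))
        alleleFreqs <- withSeed(childSeed(seed, "genotypes") + 1L,
                                runif(nSnps, 0.05, 0.95))
    if (is.null(betaIncidence))
        betaIncidence <- withSeed(childSeed(seed, "genotypes") + 2L,
                                  rnorm(nSnps, 0, 0.08))
    betaPrognosisDirect <- rep_len(betaPrognosisDirect, nSnps)
    if (is.null(incidenceThreshold)) {
        varG <- sum(2 * alleleFreqs * (1 - alleleFreqs) * betaIncidence^2)
        ce <- covariateEffects$incidence
        varCov <- ce[["age"]]^2 + ce[["sex"]]^2 * 0.25
        varL <- varG + gammaU^2 * varSharedFactor + varCov +
            if (incidenceModel == "probit") 1 else (pi^2 / 3)
        incidenceThreshold <- qnorm(1 - targetPrevalence, sd = sqrt(varL))
    }
    new("SimConfig",
        nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
        alleleFreqs = alleleFreqs, betaIncidence = betaIncidence,
        betaPrognosisDirect = betaPrognosisDirect,
        gammaU = gammaU, deltaU = deltaU, varSharedFactor = varSharedFactor,
        incidenceThreshold = incidenceThreshold,
        survivalCoefficient = survivalCoefficient,
        recruitIntercept = recruitIntercept,
        covariateEffects = covariateEffects,
        prognosisIntercept = prognosisIntercept,
        incidenceModel = incidenceModel,
        ldRho = ldRho, ldBlockSize = as.integer(ldBlockSize),
        positionSpacing = as.integer(positionSpacing), seed = seed)
}

snpAnnotation <- function(config) {
    m <- config@nSnps
    pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    al <- pairs[((seq_len(m) - 1L) %% 4L) + 1L]
    data.frame(
        SNP = sprintf("snp%05d", seq_len(m)),
        CHR = as.character(1L + (seq_len(m) - 1L) %/% 50L),
        BP = (((seq_len(m) - 1L) %% 50L) + 1L) * config@positionSpacing,
        EA = vapply(al, `[`, "", 1L),
        OA = vapply(al, `[`, "", 2L),
        stringsAsFactors = FALSE
    )
}

#' Simulate genotype dosages
#'
#' Per-SNP dosages are Binomial(2, f) counts of the effect allele; with
#' `ldRho > 0`, haplotypes within blocks of `ldBlockSize` SNPs are derived by
#' thresholding an AR(1) latent Gaussian (lag-one correlation `ldRho`), which
#' induces decaying linkage disequilibrium between neighbouring SNPs while
#' preserving the marginal frequencies.
#'
#' @param config a [SimConfig-class].
#' @param n number of individuals (default `config@nIndividuals`).
#' @param seed RNG seed (default derived from the config seed).
#' @return integer matrix, individuals x SNPs, dosages in `{0, 1, 2}` counting
#'   the effect allele; columns named by SNP id.
#' @export
simulateGenotypes <- function(config, n = config@nIndividuals,
                              seed = childSeed(config@seed, "genotypes")) {
    f <- config@alleleFreqs
    m <- config@nSnps
    ann <- snpAnnotation(config)
    g <- withSeed(seed, {
        if (config@ldRho == 0) {
            matrix(rbinom(n * m, 2L, rep(f, each = n)), nrow = n)
        } else {
            hap <- function() {
                z <- matrix(rnorm(n * m), n, m)
                for (j in seq_len(m)[-1]) {
                    if ((j - 1L) %% config@ldBlockSize != 0L)
                        z[, j] <- config@ldRho * z[, j - 1L] +
                            sqrt(1 - config@ldRho^2) * z[, j]
                }
                sweep(z, 2, qnorm(f), "<") * 1L
            }
            hap() + hap()
        }
    })
    colnames(g) <- ann$SNP
    storage.mode(g) <- "integer"
    g
}

ageZ <- function(age) (age - 54.5) / (29 / sqrt(12))

#' Initialise a cohort with genotypes, covariates and the shared factor
#'
#' Creates the `SummarizedExperiment` cohort container: the dosage assay
#' (SNPs x individuals), per-SNP annotation and generative truth in
#' `rowData`, and per-individual age, sex and the unmeasured factor U in
#' `colData`. Disease status is added by [simulateIncidence()].
#'
#' @param config a [SimConfig-class].
#' @return a `SummarizedExperiment` with assay `"dosage"` and the config in
#'   `metadata(.)$config`.
#' @export
newCohort <- function(config) {
    validObject(config)
    g <- simulateGenotypes(config)
    n <- config@nIndividuals
    cov <- withSeed(childSeed(config@seed, "covariates"), {
        data.frame(age = runif(n, 40, 69),
                   sex = rbinom(n, 1L, 0.5),
                   u = rnorm(n, 0, sqrt(config@varSharedFactor)))
    })
    ann <- snpAnnotation(config)
    rd <- S4Vectors::DataFrame(ann,
                               freq = config@alleleFreqs,
                               betaIncidence = config@betaIncidence,
                               betaPrognosisDirect = config@betaPrognosisDirect)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = t(g)),
        rowData = rd,
        colData = S4Vectors::DataFrame(cov),
        metadata = list(config = config))
}

cohortConfig <- function(cohort) {
    cfg <- S4Vectors::metadata(cohort)$config
    if (is.null(cfg)) stop("cohort carries no SimConfig in metadata")
    cfg
}

#' Individual-by-SNP dosage matrix of a cohort
#'
#' @param cohort a cohort `SummarizedExperiment`.
#' @return numeric matrix, individuals x SNPs.
#' @export
dosages <- function(cohort) t(SummarizedExperiment::assay(cohort, "dosage"))

#' Per-individual phenotype table of a cohort
#'
#' @param cohort a cohort `SummarizedExperiment`.
#' @return data.frame of `colData`.
#' @export
phenotypes <- function(cohort) as.data.frame(SummarizedExperiment::colData(cohort))

# Genetic liability component with dosages centred at their expectation 2f,
# so the configured threshold maps onto prevalence analytically.
geneticLiability <- function(g, beta, freqs) {
    as.vector(g %*% beta) - sum(2 * freqs * beta)
}

incidenceLinearPredictor <- function(cohort, config) {
    ph <- phenotypes(cohort)
    g <- dosages(cohort)
    ce <- config@covariateEffects$incidence
    geneticLiability(g, config@betaIncidence, config@alleleFreqs) +
        config@gammaU * ph$u +
        ce[["age"]] * ageZ(ph$age) + ce[["sex"]] * (ph$sex - 0.5)
}

#' Simulate disease incidence on the liability scale
#'
#' Adds standard Gaussian noise to the linear predictor (genetics + shared
#' factor + covariates) and declares disease where the resulting liability
#' exceeds `incidenceThreshold` (probit model); under the `"logit"` switch the
#' case indicator is instead Bernoulli with logit `predictor - threshold`.
#' Stores `trueScore` (the purely genetic liability component), `liability`
#' and `prevalentCase` in `colData`.
#'
#' @param cohort a cohort from [newCohort()].
#' @return the cohort with incidence columns added.
#' @export
simulateIncidence <- function(cohort) {
    config <- cohortConfig(cohort)
    eta <- incidenceLinearPredictor(cohort, config)
    n <- ncol(cohort)
    res <- withSeed(childSeed(config@seed, "incidence"), {
        if (config@incidenceModel == "probit") {
            liab <- eta + rnorm(n)
            list(liability = liab, case = liab > config@incidenceThreshold)
        } else {
            p <- plogis(eta - config@incidenceThreshold)
            list(liability = eta, case = rbinom(n, 1L, p) == 1L)
        }
    })
    cd <- SummarizedExperiment::colData(cohort)
    cd$trueScore <- geneticLiability(dosages(cohort), config@betaIncidence,
                                     config@alleleFreqs)
    cd$liability <- res$liability
    cd$prevalentCase <- res$case
    SummarizedExperiment::colData(cohort) <- cd
    cohort
}

#' Apply survival-dependent recruitment
#'
#' Among prevalent cases, the probability of surviving to (and consenting
#' into) the study decreases with disease liability: the recruitment logit is
#' `recruitIntercept - survivalCoefficient * z`, where `z` is the liability
#' standardized within cases. Individuals without disease are always
#' recruited. With `survivalCoefficient = 0`, recruitment is independent of
#' liability (and hence of the genetic score).
#'
#' @param cohort a cohort with incidence simulated.
#' @return the cohort with a logical `recruited` column.
#' @export
applyRecruitment <- function(cohort) {
    config <- cohortConfig(cohort)
    ph <- phenotypes(cohort)
    if (is.null(ph$prevalentCase)) stop("incidence must be simulated first")
    recruited <- rep(TRUE, ncol(cohort))
    ci <- which(ph$prevalentCase)
    if (length(ci) > 0L) {
        z <- ph$liability[ci]
        z <- if (length(ci) > 1L && sd(z) > 0) (z - mean(z)) / sd(z) else 0 * z
        p <- plogis(config@recruitIntercept - config@survivalCoefficient * z)
        recruited[ci] <- withSeed(childSeed(config@seed, "recruitment"),
                                  rbinom(length(ci), 1L, p) == 1L)
    }
    cd <- SummarizedExperiment::colData(cohort)
    cd$recruited <- recruited
    SummarizedExperiment::colData(cohort) <- cd
    cohort
}

#' Simulate post-baseline outcomes
#'
#' For every recruited individual the binary event `death` is drawn from a
#' logistic model: intercept + direct genetic effects + `deltaU * U` +
#' covariates. Because U also raised disease liability, conditioning on case
#' status makes the genetic score and U negatively correlated among cases —
#' the collider structure that biases case-only score-prognosis associations
#' even when the direct genetic effects are zero. For recruited individuals
#' free of disease at baseline, `incidentDisease` is additionally drawn by
#' redrawing the liability noise against the same threshold (new disease
#' onset during follow-up).
#'
#' @param cohort a cohort with recruitment applied.
#' @return the cohort with `death` (NA if not recruited) and
#'   `incidentDisease` (NA for prevalent cases / not recruited) columns.
#' @export
simulatePrognosis <- function(cohort) {
    config <- cohortConfig(cohort)
    ph <- phenotypes(cohort)
    if (is.null(ph$recruited)) stop("recruitment must be applied first")
    if (!any(ph$recruited & ph$prevalentCase)) stop("empty case stratum")
    g <- dosages(cohort)
    ce <- config@covariateEffects$prognosis
    etaP <- config@prognosisIntercept +
        geneticLiability(g, config@betaPrognosisDirect, config@alleleFreqs) +
        config@deltaU * ph$u +
        ce[["age"]] * ageZ(ph$age) + ce[["sex"]] * (ph$sex - 0.5)
    etaI <- incidenceLinearPredictor(cohort, config)
    n <- ncol(cohort)
    res <- withSeed(childSeed(config@seed, "prognosis"), {
        death <- rbinom(n, 1L, plogis(etaP))
        liab2 <- etaI + rnorm(n)
        list(death = death, incident = liab2 > config@incidenceThreshold)
    })
    death <- ifelse(ph$recruited, res$death, NA_integer_)
    incident <- ifelse(ph$recruited & !ph$prevalentCase,
                       as.integer(res$incident), NA_integer_)
    cd <- SummarizedExperiment::colData(cohort)
    cd$death <- death
    cd$incidentDisease <- incident
    SummarizedExperiment::colData(cohort) <- cd
    cohort
}

#' Simulate a complete cohort
#'
#' Runs [newCohort()], [simulateIncidence()], [applyRecruitment()] and
#' [simulatePrognosis()] in sequence.
#'
#' @param config a [SimConfig-class].
#' @return the fully populated cohort `SummarizedExperiment`.
#' @export
simulateCohort <- function(config) {
    simulatePrognosis(applyRecruitment(simulateIncidence(newCohort(config))))
}

#' Write / read a cohort as delimited text
#'
#' The phenotype columns and dosage matrix are written as one TSV (gzip if the
#' path ends in `.gz`); the generative configuration travels in a JSON sidecar
#' `<path>.json` so a round-tripped cohort retains its ground truth.
#'
#' @param cohort a cohort `SummarizedExperiment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
    tab <- cbind(phenotypes(cohort), as.data.frame(dosages(cohort)))
    data.table::fwrite(tab, path, sep = "\t", compress = "auto")
    cfg <- cohortConfig(cohort)
    sidecar <- lapply(slotNames(cfg), function(s) slot(cfg, s))
    names(sidecar) <- slotNames(cfg)
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    tab <- data.table::fread(path, data.table = FALSE)
    sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    cfg <- do.call(simConfig, c(
        list(nIndividuals = sidecar$nIndividuals, nSnps = sidecar$nSnps,
             seed = sidecar$seed, alleleFreqs = sidecar$alleleFreqs,
             betaIncidence = sidecar$betaIncidence,
             betaPrognosisDirect = sidecar$betaPrognosisDirect,
             gammaU = sidecar$gammaU, deltaU = sidecar$deltaU,
             varSharedFactor = sidecar$varSharedFactor,
             incidenceThreshold = sidecar$incidenceThreshold,
             survivalCoefficient = sidecar$survivalCoefficient,
             recruitIntercept = sidecar$recruitIntercept,
             covariateEffects = lapply(sidecar$covariateEffects, unlist),
             prognosisIntercept = sidecar$prognosisIntercept,
             incidenceModel = sidecar$incidenceModel,
             ldRho = sidecar$ldRho, ldBlockSize = sidecar$ldBlockSize,
             positionSpacing = sidecar$positionSpacing)))
    ann <- snpAnnotation(cfg)
    g <- as.matrix(tab[, ann$SNP, drop = FALSE])
    ph <- tab[, setdiff(names(tab), ann$SNP), drop = FALSE]
    for (col in c("prevalentCase", "recruited"))
        if (col %in% names(ph)) ph[[col]] <- as.logical(ph[[col]])
    rd <- S4Vectors::DataFrame(ann, freq = cfg@alleleFreqs,
                               betaIncidence = cfg@betaIncidence,
                               betaPrognosisDirect = cfg@betaPrognosisDirect)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = t(g)), rowData = rd,
        colData = S4Vectors::DataFrame(ph),
        metadata = list(config = cfg))
}
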