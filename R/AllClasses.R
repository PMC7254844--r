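#' @import methods
#' @importFrom stats coef cor cov glm.fit lm pnorm qnorm quantile rbinom rnorm
#'   runif sd var binomial plogis predict setNames complete.cases ks.test
#'   vcov
#' @importFrom utils head modifyList
NULL

#' Simulation configuration for liability-threshold cohorts
#'
#' `SimConfig` holds every generative quantity of the synthetic-cohort model:
#' per-SNP allele frequencies and liability effects, the unmeasured shared risk
#' factor linking incidence and prognosis, the liability threshold defining
#' disease, survival-dependent recruitment, covariate effects and the seed.
#' Defaults (see [simConfig()]) describe the *bias scenario*: positive genetic
#' and shared-factor effects on incidence, zero direct genetic effects on
#' prognosis, and selective survival into the study — the structure under which
#' conditioning on case status induces spurious protective associations.
#'
#' @slot nIndividuals number of individuals to simulate.
#' @slot nSnps number of SNPs.
#' @slot alleleFreqs effect-allele frequencies, length `nSnps`, each in (0,1).
#' @slot betaIncidence per-SNP additive effect on the liability scale.
#' @slot betaPrognosisDirect per-SNP *direct* effect on the prognosis logit.
#' @slot gammaU effect of the unmeasured factor U on liability.
#' @slot deltaU effect of U on the prognosis logit.
#' @slot varSharedFactor variance of U (U ~ N(0, varSharedFactor)).
#' @slot incidenceThreshold liability cutoff; disease iff liability exceeds it.
#' @slot survivalCoefficient logit decrease in recruitment probability per
#'   within-case SD of liability (pre-recruitment death of severe cases).
#' @slot recruitIntercept recruitment logit at mean case liability.
#' @slot covariateEffects named list with elements `incidence` and `prognosis`,
#'   each a named numeric vector of effects for `age` (per SD of age) and `sex`.
#' @slot prognosisIntercept intercept of the prognosis logit (base event rate).
#' @slot incidenceModel `"probit"` (liability threshold, default) or
#'   `"logit"`.
#' @slot ldRho adjacent-SNP latent haplotype correlation (0 = independent).
#' @slot ldBlockSize SNPs per LD block when `ldRho > 0`.
#' @slot positionSpacing base pairs between adjacent simulated SNPs.
#' @slot seed integer seed; identical seeds give bit-identical cohorts.
#'
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
    nIndividuals = "integer",
    nSnps = "integer",
    alleleFreqs = "numeric",
    betaIncidence = "numeric",
    betaPrognosisDirect = "numeric",
    gammaU = "numeric",
    deltaU = "numeric",
    varSharedFactor = "numeric",
    incidenceThreshold = "numeric",
    survivalCoefficient = "numeric",
    recruitIntercept = "numeric",
    covariateEffects = "list",
    prognosisIntercept = "numeric",
    incidenceModel = "character",
    ldRho = "numeric",
    ldBlockSize = "integer",
    positionSpacing = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
    if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
    if (length(object@alleleFreqs) != object@nSnps)
        msg <- c(msg, "alleleFreqs must have length nSnps")
    if (any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
        msg <- c(msg, "allele frequencies must lie strictly in (0, 1)")
    if (length(object@betaIncidence) != object@nSnps)
        msg <- c(msg, "betaIncidence must have length nSnps")
    if (length(object@betaPrognosisDirect) != object@nSnps)
        msg <- c(msg, "betaPrognosisDirect must have length nSnps")
    if (object@varSharedFactor < 0) msg <- c(msg, "varSharedFactor must be >= 0")
    if (!object@incidenceModel %in% c("probit", "logit"))
        msg <- c(msg, "incidenceModel must be 'probit' or 'logit'")
    if (object@ldRho < 0 || object@ldRho >= 1)
        msg <- c(msg, "ldRho must lie in [0, 1)")
    if (!all(c("incidence", "prognosis") %in% names(object@covariateEffects)))
        msg <- c(msg, "covariateEffects needs 'incidence' and 'prognosis' entries")
    if (length(msg)) msg else TRUE
})

#' Polygenic risk score model
#'
#' A set of variant weights defining a score: one row per variant with its
#' effect allele and the per-allele log-odds weight taken from the incidence
#' GWAS. `provenance` records the thresholds that produced the model
#' (P-value cutoff, clumping r² and window, input record counts).
#'
#' @slot entries data.frame with columns `snp`, `ea`, `weight`.
#' @slot provenance named list of construction metadata.
#' @seealso [buildPRSModel()], [scoreIndividuals()]
#' @export
setClass("PRSModel", representation(entries = "data.frame", provenance = "list"))

setValidity("PRSModel", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("snp", "ea", "weight") %in% names(e)))
        msg <- c(msg, "entries must have columns snp, ea, weight")
    else {
        if (anyDuplicated(e$snp)) msg <- c(msg, "duplicate variant ids in model")
        if (any(!is.finite(e$weight))) msg <- c(msg, "weights must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Linkage-disequilibrium reference
#'
#' Pairwise r² lookups used by [ldClump()] and [ldPrune()]. Built either from
#' a genotype dosage panel (r² computed as the squared Pearson correlation of
#' dosages) or from an explicit three-column pair table. Variant pairs absent
#' from the reference are treated as independent (r² = 0) with a warning, so
#' sparse synthetic panels do not empty a run.
#'
#' @slot panel numeric dosage matrix (individuals x SNPs, named columns), or a
#'   0x0 matrix when the reference is table-based.
#' @slot pairs named numeric vector of r² values keyed `"snpA|snpB"` with
#'   both orderings present; empty when panel-based.
#' @seealso [ldFromPanel()], [ldFromTable()], [ldR2()]
#' @export
setClass("LDReference", representation(panel = "matrix", pairs = "numeric"))

#' Per-stratum association estimate
#'
#' One fitted PRS-outcome (logistic) or PRS-covariate (linear) association:
#' the per-SD effect, its standard error, P-value, and for logistic models the
#' odds ratio with 95% CI.
#'
#' @slot stratum stratum label (e.g. `"disease-free"`, `"case"`, `"pooled"`).
#' @slot outcome outcome label.
#' @slot beta per-SD effect on the link scale.
#' @slot se standard error of `beta`.
#' @slot p two-sided Wald P-value.
#' @slot or odds ratio `exp(beta)` (NA for linear models).
#' @slot ci95 `exp(beta -/+ 1.959964 se)` (log-scale CI for linear models).
#' @slot n number of observations in the fit.
#' @slot model `"logistic"` or `"linear"`.
#' @slot covariates names of adjustment covariates.
#' @export
setClass("AssocEstimate", representation(
    stratum = "character", outcome = "character",
    beta = "numeric", se = "numeric", p = "numeric",
    or = "numeric", ci95 = "numeric", n = "integer",
    model = "character", covariates = "character"
))

setValidity("AssocEstimate", function(object) {
    msg <- character()
    if (object@se <= 0) msg <- c(msg, "se must be > 0")
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
    if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must have length 2")
    if (length(msg)) msg else TRUE
})

#' Cross-SNP bias-slope estimate
#'
#' The slope of prognosis effects regressed on incidence effects across SNPs —
#' the summary-level measure of index event bias. Produced by [slopeNaive()]
#' (ordinary least squares), [slopeHedgesOlkin()] (de-attenuated for
#' estimation error in the incidence effects) or [slopeSimex()]
#' (simulation-extrapolation).
#'
#' @slot method `"naive"`, `"hedges_olkin"` or `"simex"`.
#' @slot value the slope estimate (dimensionless).
#' @slot se standard error.
#' @slot ci95 95% confidence interval.
#' @slot nSnps number of SNP pairs used.
#' @slot diagnostics method-specific list (SIMEX extrapolation curve, jackknife
#'   spread, I2GX when attached).
#' @export
setClass("SlopeEstimate", representation(
    method = "character", value = "numeric", se = "numeric",
    ci95 = "numeric", nSnps = "integer", diagnostics = "list"
))

setValidity("SlopeEstimate", function(object) {
    if (!is.finite(object@value)) "slope value must be finite" else TRUE
})

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW combination of per-variant ratio estimates: the log-odds of
#' the prognosis outcome per unit log-odds genetic liability to the index
#' disease.
#'
#' @slot beta IVW estimate on the log-odds scale.
#' @slot se fixed-effect standard error.
#' @slot p two-sided Wald P-value.
#' @slot or `exp(beta)`.
#' @slot ci95 95% CI for the odds ratio.
#' @slot nInstruments number of instrument SNPs.
#' @slot corrected whether the prognosis effects were bias-adjusted first.
#' @export
setClass("IVWResult", representation(
    beta = "numeric", se = "numeric", p = "numeric", or = "numeric",
    ci95 = "numeric", nInstruments = "integer", corrected = "logical"
))

setValidity("IVWResult", function(object) {
    msg <- character()
    if (abs(object@or - exp(object@beta)) > 1e-8 * max(1, object@or))
        msg <- c(msg, "or must equal exp(beta)")
    if (object@ci95[1] > object@or || object@ci95[2] < object@or)
        msg <- c(msg, "ci95 must bracket or")
    if (length(msg)) msg else TRUE
})
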