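#' Pair incidence and prognosis effects and apply the correction filters
#'
#' Harmonizes the two summary-statistics tables onto shared effect alleles
#' ([harmonizeSumstats()]), keeps well-imputed SNPs (`INFO > infoMin` in both
#' studies), removes correlated SNPs by window-based LD pruning ([ldPrune()]),
#' and optionally restricts to SNPs nominally associated with the index
#' disease (`P_INC < pIncMax`) — the subset used for slope estimation when
#' noise from null SNPs prevents SIMEX convergence.
#'
#' @param incRecords incidence summary statistics.
#' @param progRecords prognosis summary statistics.
#' @param ld an [LDReference-class].
#' @param infoMin imputation-quality threshold (strict >; default 0.99).
#' @param pruneParams list with `window_bp`, `step_snps`, `r2_max` (defaults
#'   250000, 5, 0.1).
#' @param pIncMax optional incidence P-value ceiling (strict <).
#' @return a `PairedEffects` data.frame (see [harmonizeSumstats()]); attribute
#'   `"stage_counts"` logs record counts in/out of every filter.
#' @export
pairAndFilter <- function(incRecords, progRecords, ld, infoMin = 0.99,
                          pruneParams = list(window_bp = 250000,
                                             step_snps = 5, r2_max = 0.1),
                          pIncMax = NULL) {
    counts <- c(incidence = nrow(incRecords), prognosis = nrow(progRecords))
    pairs <- harmonizeSumstats(incRecords, progRecords)
    counts["harmonized"] <- nrow(pairs)
    if (nrow(pairs) == 0L) stop("no shared variants after harmonization")
    pairs <- pairs[pairs$INFO_INC > infoMin & pairs$INFO_PROG > infoMin, ,
                   drop = FALSE]
    counts["info"] <- nrow(pairs)
    pairs <- ldPrune(pairs, ld, windowBp = pruneParams$window_bp,
                     stepSnps = pruneParams$step_snps,
                     r2Max = pruneParams$r2_max)
    counts["pruned"] <- nrow(pairs)
    if (!is.null(pIncMax)) {
        pairs <- pairs[pairs$P_INC < pIncMax, , drop = FALSE]
        counts["p_inc"] <- nrow(pairs)
    }
    if (nrow(pairs) == 0L) stop("no variants survive pairing filters")
    rownames(pairs) <- NULL
    attr(pairs, "stage_counts") <- counts
    pairs
}

slopeOLS <- function(b1, b2, intercept = TRUE) {
    n <- length(b1)
    if (intercept) {
        sxx <- sum((b1 - mean(b1))^2)
        if (sxx == 0) stop("zero variance in incidence effects")
        slope <- sum((b1 - mean(b1)) * (b2 - mean(b2))) / sxx
        resid <- b2 - mean(b2) - slope * (b1 - mean(b1))
        se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    } else {
        sxx <- sum(b1^2)
        if (sxx == 0) stop("zero variance in incidence effects")
        slope <- sum(b1 * b2) / sxx
        resid <- b2 - slope * b1
        se <- sqrt(sum(resid^2) / (n - 1) / sxx)
    }
    c(slope = slope, se = se)
}

#' Naive cross-SNP bias slope
#'
#' Unweighted least-squares regression of prognosis effects on incidence
#' effects across SNPs, intercept included by default (the intercept absorbs
#' any directional shift so the slope captures the proportional bias).
#' Because the incidence effects are estimates, not true values, this slope
#' is attenuated towards zero; [slopeHedgesOlkin()] and [slopeSimex()]
#' de-attenuate it.
#'
#' @param pairs a `PairedEffects` data.frame (>= 3 rows).
#' @param intercept include an intercept (default TRUE).
#' @return a [SlopeEstimate-class] with `method = "naive"`.
#' @export
slopeNaive <- function(pairs, intercept = TRUE) {
    if (nrow(pairs) < 3L) stop("need at least 3 SNP pairs")
    est <- slopeOLS(pairs$BETA_INC, pairs$BETA_PROG, intercept)
    new("SlopeEstimate", method = "naive",
        value = unname(est["slope"]), se = unname(est["se"]),
        ci95 = unname(est["slope"] + c(-1, 1) * Z975 * est["se"]),
        nSnps = nrow(pairs), diagnostics = list(intercept = intercept))
}

#' Hedges-Olkin (regression-dilution-corrected) bias slope
#'
#' De-attenuates the naive slope by removing the estimation-error variance of
#' the incidence effects from the regressor variance:
#' `b_HO = cov(beta1, beta2) / (var(beta1) - mean(se1^2))`.
#' The standard error is obtained by leave-one-out jackknife, which makes no
#' distributional assumption about the SNP effects. With all incidence SEs
#' zero the estimator reduces exactly to the naive OLS slope.
#'
#' @param pairs a `PairedEffects` data.frame (>= 3 rows).
#' @return a [SlopeEstimate-class] with `method = "hedges_olkin"`.
#' @export
slopeHedgesOlkin <- function(pairs) {
    if (nrow(pairs) < 3L) stop("need at least 3 SNP pairs")
    hoValue <- function(b1, b2, s1) {
        denom <- var(b1) - mean(s1^2)
        if (denom <= 0)
            stop("incidence effects dominated by noise: var(beta1) <= mean(se1^2)")
        cov(b1, b2) / denom
    }
    b1 <- pairs$BETA_INC; b2 <- pairs$BETA_PROG; s1 <- pairs$SE_INC
    value <- hoValue(b1, b2, s1)
    n <- length(b1)
    loo <- vapply(seq_len(n), function(i)
        tryCatch(hoValue(b1[-i], b2[-i], s1[-i]), error = function(e) NA_real_),
        numeric(1))
    loo <- loo[is.finite(loo)]
    k <- length(loo)
    se <- if (k >= 2L) sqrt((k - 1) / k * sum((loo - mean(loo))^2)) else NA_real_
    new("SlopeEstimate", method = "hedges_olkin",
        value = value, se = se,
        ci95 = value + c(-1, 1) * Z975 * se,
        nSnps = n, diagnostics = list(jackknife_n = k))
}

#' SIMEX (simulation-extrapolation) bias slope
#'
#' Re-estimates the naive slope after inflating the measurement error of the
#' incidence effects: for each `lambda` in `lambdaGrid`, `nSim` replicates add
#' independent noise with per-SNP variance `lambda * se1^2` to the incidence
#' betas and the replicate naive slopes are averaged. A quadratic in `lambda`
#' is then fitted to the mean slopes (weighted by their Monte-Carlo
#' precision) and extrapolated to `lambda = -1`, the no-measurement-error
#' limit. The CI propagates the replicate spread through the extrapolation.
#' With all incidence SEs zero every replicate equals the naive slope and the
#' extrapolation returns it exactly.
#'
#' @param pairs a `PairedEffects` data.frame (>= 3 rows).
#' @param lambdaGrid added-noise multipliers in \[0, 2\]
#'   (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param nSim replicates per lambda (default 1000).
#' @param seed RNG seed for the noise replicates.
#' @param intercept include an intercept in each replicate regression.
#' @return a [SlopeEstimate-class] with `method = "simex"`; diagnostics carry
#'   the per-lambda mean slopes and Monte-Carlo variances (the extrapolation
#'   curve) for convergence assessment.
#' @export
slopeSimex <- function(pairs, lambdaGrid = c(0, 0.5, 1, 1.5, 2), nSim = 1000,
                       seed = 1, intercept = TRUE) {
    if (nrow(pairs) < 3L) stop("need at least 3 SNP pairs")
    if (any(lambdaGrid < 0 | lambdaGrid > 2))
        stop("lambdaGrid must lie in [0, 2]")
    b1 <- pairs$BETA_INC; b2 <- pairs$BETA_PROG; s1 <- pairs$SE_INC
    nSnp <- length(b1)
    naive <- unname(slopeOLS(b1, b2, intercept)["slope"])

    # Vectorized replicate slopes: columns of B1 are noisy copies of b1.
    replicateSlopes <- function(lambda) {
        if (lambda == 0 || all(s1 == 0)) return(rep(naive, nSim))
        B1 <- b1 + matrix(rnorm(nSnp * nSim, 0, sqrt(lambda) * s1),
                          nSnp, nSim)
        if (intercept) {
            cm <- colMeans(B1)
            Bc <- sweep(B1, 2, cm)
            num <- as.vector(crossprod(Bc, b2 - mean(b2)))
            den <- colSums(Bc^2)
        } else {
            num <- as.vector(crossprod(B1, b2))
            den <- colSums(B1^2)
        }
        num / den
    }
    curve <- withSeed(seed, {
        lapply(lambdaGrid, function(l) {
            sl <- replicateSlopes(l)
            if (any(!is.finite(sl)))
                stop("non-finite replicate slopes at lambda = ", l)
            c(mean = mean(sl), var = var(sl) / length(sl))
        })
    })
    means <- vapply(curve, `[[`, 0, "mean")
    vars <- vapply(curve, `[[`, 0, "var")
    if (all(abs(means - means[1]) < 1e-15)) {
        value <- means[1]; se <- 0
    } else {
        w <- 1 / pmax(vars, max(vars[vars > 0], 1e-30) * 1e-6)
        X <- cbind(1, lambdaGrid, lambdaGrid^2)
        XtWX <- crossprod(X, w * X)
        coefs <- solve(XtWX, crossprod(X, w * means))
        x0 <- c(1, -1, 1)
        value <- sum(x0 * coefs)
        # Monte-Carlo variance of the extrapolated value given the per-lambda
        # means' variances: var(x0' (X'WX)^-1 X'W m) with diag(vars).
        A <- solve(XtWX, t(w * X))       # maps means -> coefficients
        se <- sqrt(sum((as.vector(x0 %*% A))^2 * vars))
    }
    new("SlopeEstimate", method = "simex",
        value = unname(value), se = unname(se),
        ci95 = unname(value + c(-1, 1) * Z975 * se),
        nSnps = nSnp,
        diagnostics = list(lambda = lambdaGrid, mean_slope = unname(means),
                           mc_var = unname(vars), n_sim = nSim,
                           naive = naive, intercept = intercept))
}

#' I²GX weak-instrument / measurement-error diagnostic
#'
#' Heterogeneity-type statistic quantifying how much of the variation in the
#' estimated incidence effects is signal rather than estimation noise:
#' `Q = sum_j (beta1_j - betaBar_w)^2 / se1_j^2` with `betaBar_w` the
#' inverse-variance-weighted mean, and `I2 = max(0, (Q - (k - 1)) / Q)`.
#' Values well below 1 warn that slope estimates are attenuated by
#' measurement error.
#'
#' @param pairs a `PairedEffects` data.frame (>= 2 rows).
#' @return list with `i2` in \[0, 1), `q` and `k`.
#' @export
i2GX <- function(pairs) {
    k <- nrow(pairs)
    if (k < 2L) stop("I2GX requires at least 2 SNPs")
    w <- 1 / pairs$SE_INC^2
    bw <- sum(w * pairs$BETA_INC) / sum(w)
    q <- sum((pairs$BETA_INC - bw)^2 / pairs$SE_INC^2)
    list(i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0, q = q, k = k)
}

#' Adjust prognosis effects for index event bias
#'
#' Subtracts the slope-scaled incidence effect from each SNP's prognosis
#' effect: `beta2adj = beta2 - b * beta1`, with standard errors recombined as
#' `se_adj = sqrt(se2^2 + b^2 * se1^2)`. The uncertainty of the slope
#' estimate itself is not propagated by default (the adjustment rule treats
#' the slope as fixed); `propagateSlopeVar = TRUE` adds `var(b) * beta1^2`.
#' P-values are recomputed from the adjusted Wald ratios.
#'
#' @param pairs a `PairedEffects` data.frame.
#' @param slope a [SlopeEstimate-class] or a bare numeric slope.
#' @param propagateSlopeVar include the slope-uncertainty variance term.
#' @return a summary-statistics data.frame of adjusted prognosis effects.
#' @export
adjustPrognosis <- function(pairs, slope, propagateSlopeVar = FALSE) {
    b <- if (methods::is(slope, "SlopeEstimate")) slope@value else slope
    bVar <- if (propagateSlopeVar) {
        if (!methods::is(slope, "SlopeEstimate") || !is.finite(slope@se))
            stop("slope variance unavailable for propagation")
        slope@se^2
    } else 0
    if (!is.finite(b)) stop("slope must be finite")
    betaAdj <- pairs$BETA_PROG - b * pairs$BETA_INC
    seAdj <- sqrt(pairs$SE_PROG^2 + b^2 * pairs$SE_INC^2 +
                  bVar * pairs$BETA_INC^2)
    data.frame(SNP = pairs$SNP, CHR = pairs$CHR, BP = pairs$BP,
               EA = pairs$EA, OA = pairs$OA, EAF = pairs$EAF,
               BETA = betaAdj, SE = seAdj, P = waldP(betaAdj, seAdj),
               INFO = pairs$INFO_PROG, stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Combines per-variant ratio estimates into one causal effect of genetic
#' liability to the index disease on the prognosis outcome:
#' `beta_IVW = sum_j w_j beta1_j beta2_j / sum_j w_j beta1_j^2` with
#' `w_j = 1/se2_j^2` and `SE = 1/sqrt(sum_j w_j beta1_j^2)` — identical to
#' weighted regression of `beta2` on `beta1` through the origin with the
#' residual dispersion fixed at 1.
#'
#' @param pairs a `PairedEffects` data.frame; `beta2` / `se2` are taken from
#'   `BETA_PROG` / `SE_PROG` unless `beta2` and `se2` vectors are supplied
#'   (e.g. adjusted effects).
#' @param instruments optional character vector of SNP ids to use; default
#'   all rows of `pairs`.
#' @param beta2,se2 optional replacement prognosis effects (same order as
#'   `pairs`).
#' @param corrected flag recorded in the result.
#' @return an [IVWResult-class].
#' @export
ivw <- function(pairs, instruments = NULL, beta2 = NULL, se2 = NULL,
                corrected = FALSE) {
    b2 <- beta2 %||% pairs$BETA_PROG
    s2 <- se2 %||% pairs$SE_PROG
    b1 <- pairs$BETA_INC
    if (!is.null(instruments)) {
        idx <- match(instruments, pairs$SNP)
        if (anyNA(idx))
            stop("instrument(s) absent from pairs: ",
                 paste(instruments[is.na(idx)], collapse = ", "))
        b1 <- b1[idx]; b2 <- b2[idx]; s2 <- s2[idx]
    }
    if (length(b1) < 1L) stop("at least one instrument required")
    if (all(b1 == 0)) stop("no instrument strength: all incidence effects zero")
    w <- 1 / s2^2
    beta <- sum(w * b1 * b2) / sum(w * b1^2)
    se <- 1 / sqrt(sum(w * b1^2))
    new("IVWResult", beta = beta, se = se, p = waldP(beta, se),
        or = exp(beta), ci95 = orCI(beta, se),
        nInstruments = length(b1), corrected = corrected)
}

#' Full index-event-bias correction workflow
#'
#' Orchestrates the summary-level correction: pair and filter the incidence
#' and prognosis statistics, estimate the bias slope on the (optionally
#' P-subset) slope set, compute I²GX, adjust the prognosis effects, and
#' report fixed-effect IVW estimates over the instrument SNPs before and
#' after correction. The instrument list is deliberately a separate, stricter
#' set than the slope-estimation set (mirroring a genome-wide-significant
#' instrument panel vs the broad pruned SNP set) and is never inferred.
#'
#' @param incRecords,progRecords incidence / prognosis summary statistics.
#' @param ld an [LDReference-class].
#' @param instruments character vector of instrument SNP ids for IVW.
#' @param slopeMethod `"simex"`, `"hedges_olkin"` or `"naive"`.
#' @param infoMin,pruneParams,pIncMax filters passed to [pairAndFilter()]
#'   (slope-set construction).
#' @param simex list of SIMEX settings: `lambda`, `n_sim`, `seed`.
#' @param ivwWeights `"adjusted"` (default: corrected IVW weights use the
#'   adjusted prognosis SEs) or `"unadjusted"` (weights keep the raw
#'   prognosis SEs, in which case corrected IVW equals raw IVW minus the
#'   slope exactly).
#' @param intercept include an intercept in the slope regressions.
#' @return list with elements `raw` ([IVWResult-class]), `slope`
#'   ([SlopeEstimate-class] with I²GX in its diagnostics), `corrected`
#'   ([IVWResult-class]), `adjusted` (adjusted prognosis table), `i2_gx`,
#'   and `stage_counts`.
#' @export
correctAndEstimate <- function(incRecords, progRecords, ld, instruments,
                               slopeMethod = c("simex", "hedges_olkin", "naive"),
                               infoMin = 0.99,
                               pruneParams = list(window_bp = 250000,
                                                  step_snps = 5, r2_max = 0.1),
                               pIncMax = 0.05,
                               simex = list(lambda = c(0, 0.5, 1, 1.5, 2),
                                            n_sim = 1000, seed = 1),
                               ivwWeights = c("adjusted", "unadjusted"),
                               intercept = TRUE) {
    slopeMethod <- match.arg(slopeMethod)
    ivwWeights <- match.arg(ivwWeights)
    allPairs <- pairAndFilter(incRecords, progRecords, ld, infoMin = infoMin,
                              pruneParams = pruneParams, pIncMax = NULL)
    slopePairs <- if (!is.null(pIncMax)) {
        sp <- allPairs[allPairs$P_INC < pIncMax, , drop = FALSE]
        if (nrow(sp) < 3L) stop("fewer than 3 SNPs in the slope-estimation set")
        sp
    } else allPairs
    slope <- switch(slopeMethod,
        simex = slopeSimex(slopePairs, lambdaGrid = simex$lambda,
                           nSim = simex$n_sim, seed = simex$seed,
                           intercept = intercept),
        hedges_olkin = slopeHedgesOlkin(slopePairs),
        naive = slopeNaive(slopePairs, intercept = intercept))
    diag <- i2GX(slopePairs)
    slope@diagnostics$i2_gx <- diag$i2

    # IVW over the instrument set; instruments are matched within the
    # harmonized pairs (pre P-subset), not the slope set.
    instPairs <- allPairs[allPairs$SNP %in% instruments, , drop = FALSE]
    if (nrow(instPairs) == 0L) stop("no instruments present after pairing")
    raw <- ivw(instPairs, corrected = FALSE)
    adjusted <- adjustPrognosis(allPairs, slope)
    adjInst <- adjusted[match(instPairs$SNP, adjusted$SNP), , drop = FALSE]
    correctedIvw <- ivw(instPairs,
                        beta2 = adjInst$BETA,
                        se2 = if (ivwWeights == "adjusted") adjInst$SE
                              else instPairs$SE_PROG,
                        corrected = TRUE)
    list(raw = raw, slope = slope, corrected = correctedIvw,
         adjusted = adjusted, i2_gx = diag,
         stage_counts = c(attr(allPairs, "stage_counts"),
                          slope_set = nrow(slopePairs),
                          instruments = nrow(instPairs)))
}
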