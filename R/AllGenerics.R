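#' Point estimate of a fitted result
#'
#' @param object an [AssocEstimate-class], [SlopeEstimate-class] or
#'   [IVWResult-class].
#' @return numeric scalar: the effect / slope on its natural scale.
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' Standard error of a fitted result
#' @inheritParams estimate
#' @return numeric scalar.
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' 95% confidence interval of a fitted result
#' @inheritParams estimate
#' @return numeric length-2 vector (lower, upper).
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' P-value of a fitted result
#' @inheritParams estimate
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @export
setMethod("estimate", "AssocEstimate", function(object) object@beta)
#' @export
setMethod("estimate", "SlopeEstimate", function(object) object@value)
#' @export
setMethod("estimate", "IVWResult", function(object) object@beta)

#' @export
setMethod("stdError", "AssocEstimate", function(object) object@se)
#' @export
setMethod("stdError", "SlopeEstimate", function(object) object@se)
#' @export
setMethod("stdError", "IVWResult", function(object) object@se)

#' @export
setMethod("confint95", "AssocEstimate", function(object) object@ci95)
#' @export
setMethod("confint95", "SlopeEstimate", function(object) object@ci95)
#' @export
setMethod("confint95", "IVWResult", function(object) object@ci95)

#' @export
setMethod("pValue", "AssocEstimate", function(object) object@p)
#' @export
setMethod("pValue", "IVWResult", function(object) object@p)

#' Odds ratio of a logistic estimate
#' @inheritParams estimate
#' @return numeric scalar `exp(beta)`.
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))
#' @export
setMethod("oddsRatio", "AssocEstimate", function(object) object@or)
#' @export
setMethod("oddsRatio", "IVWResult", function(object) object@or)

#' Model entries of a PRS model
#' @param object a [PRSModel-class].
#' @return data.frame with columns `snp`, `ea`, `weight`.
#' @export
setGeneric("modelEntries", function(object) standardGeneric("modelEntries"))
#' @export
setMethod("modelEntries", "PRSModel", function(object) object@entries)

#' Provenance of a PRS model
#' @param object a [PRSModel-class].
#' @return named list of construction thresholds and counts.
#' @export
setGeneric("modelProvenance", function(object) standardGeneric("modelProvenance"))
#' @export
setMethod("modelProvenance", "PRSModel", function(object) object@provenance)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nIndividuals, "individuals,",
        object@nSnps, "SNPs\n")
    cat("  incidence model:", object@incidenceModel,
        " threshold:", signif(object@incidenceThreshold, 4), "\n")
    cat("  shared factor: var", object@varSharedFactor,
        " gammaU", object@gammaU, " deltaU", object@deltaU, "\n")
    cat("  survival coefficient:", object@survivalCoefficient,
        " seed:", object@seed, "\n")
})

setMethod("show", "PRSModel", function(object) {
    cat("PRSModel with", nrow(object@entries), "variants\n")
    pv <- object@provenance
    if (!is.null(pv$p_threshold))
        cat("  P threshold:", pv$p_threshold, "\n")
    if (!is.null(pv$r2_max))
        cat("  clumping: r2 <", pv$r2_max, "within", pv$window_bp, "bp\n")
})

setMethod("show", "AssocEstimate", function(object) {
    cat(sprintf("AssocEstimate [%s | %s] (%s, n = %d)\n",
                object@stratum, object@outcome, object@model, object@n))
    if (object@model == "logistic") {
        cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f), P = %.3g\n",
                    object@or, object@ci95[1], object@ci95[2], object@p))
    } else {
        cat(sprintf("  beta %.4f (SE %.4f), P = %.3g\n",
                    object@beta, object@se, object@p))
    }
})

setMethod("show", "SlopeEstimate", function(object) {
    cat(sprintf("SlopeEstimate [%s]: %.4f (95%% CI %.4f, %.4f), %d SNPs\n",
                object@method, object@value, object@ci95[1], object@ci95[2],
                object@nSnps))
    if (!is.null(object@diagnostics$i2_gx))
        cat(sprintf("  I2GX = %.3f\n", object@diagnostics$i2_gx))
})

setMethod("show", "IVWResult", function(object) {
    cat(sprintf("IVWResult (%s, %d instruments)\n",
                if (object@corrected) "bias-corrected" else "uncorrected",
                object@nInstruments))
    cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f), P = %.3g\n",
                object@or, object@ci95[1], object@ci95[2], object@p))
})
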