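#' Fit a per-SD score-outcome association within a stratum
#'
#' Maximum-likelihood logistic (binary outcome) or ordinary least-squares
#' linear (continuous outcome) regression of the outcome on the score plus
#' adjustment covariates. Pass a standardized score ([standardizeScore()],
#' pooled scaling) to obtain per-SD effects. Perfect separation or a
#' single-class binary outcome raises an error naming the stratum and
#' outcome.
#'
#' @param score numeric score vector for the stratum members.
#' @param outcome numeric outcome vector (binary 0/1 for logistic).
#' @param covariates optional data.frame of adjustment covariates.
#' @param stratum stratum label carried into the result.
#' @param outcomeName outcome label carried into the result.
#' @param model `"logistic"` or `"linear"`; default guesses logistic for 0/1
#'   outcomes.
#' @return an [AssocEstimate-class].
#' @export
fitOutcomeAssoc <- function(score, outcome, covariates = NULL,
                            stratum = "all", outcomeName = "outcome",
                            model = NULL) {
    keep <- !is.na(outcome) & !is.na(score)
    if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
    score <- score[keep]; outcome <- outcome[keep]
    covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
    if (is.null(model))
        model <- if (all(outcome %in% c(0, 1))) "logistic" else "linear"
    dat <- data.frame(.y = outcome, .score = score)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    form <- stats::reformulate(setdiff(names(dat), ".y"), response = ".y")
    if (model == "logistic") {
        if (length(unique(outcome)) < 2L)
            stop(sprintf("single-class outcome in stratum '%s' / '%s'",
                         stratum, outcomeName))
        fit <- suppressWarnings(stats::glm(form, data = dat, family = binomial()))
        sm <- summary(fit)$coefficients
        if (!fit$converged || fit$boundary || sm[".score", "Std. Error"] > 50)
            stop(sprintf("separation in stratum '%s' / '%s'",
                         stratum, outcomeName))
    } else {
        fit <- stats::lm(form, data = dat)
        sm <- summary(fit)$coefficients
    }
    beta <- sm[".score", "Estimate"]
    se <- sm[".score", "Std. Error"]
    p <- waldP(beta, se)
    new("AssocEstimate",
        stratum = stratum, outcome = outcomeName,
        beta = beta, se = se, p = p,
        or = if (model == "logistic") exp(beta) else NA_real_,
        ci95 = if (model == "logistic") orCI(beta, se)
               else beta + c(-1, 1) * Z975 * se,
        n = length(outcome), model = model,
        covariates = if (is.null(covariates)) character() else names(covariates))
}

#' Heterogeneity test between two independent estimates
#'
#' Two-sample z test on the effect (log-odds) scale:
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal P — the
#' standard test for comparing a stratified effect between independent
#' subgroups.
#'
#' @param a,b [AssocEstimate-class] objects for the same outcome and scale.
#' @return list with elements `z` and `p`.
#' @export
heterogeneityTest <- function(a, b) {
    if (a@outcome != b@outcome)
        stop("estimates are for different outcomes: ", a@outcome, " vs ", b@outcome)
    z <- (a@beta - b@beta) / sqrt(a@se^2 + b@se^2)
    list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Recover a log-scale standard error from a printed OR and its 95% CI
#'
#' `se = (log(upper) - log(lower)) / (2 * 1.959964)` — the plumbing needed to
#' consume published odds-ratio tables.
#'
#' @param or_point the odds ratio (unused in the computation; retained so the
#'   call documents which estimate the CI belongs to).
#' @param ci95 numeric length-2 vector (lower, upper), both positive and
#'   strictly ordered.
#' @return the log-odds standard error.
#' @export
ciToSE <- function(or_point, ci95) {
    if (any(ci95 <= 0)) stop("confidence bounds must be positive")
    if (ci95[1] >= ci95[2]) stop("degenerate confidence interval")
    (log(ci95[2]) - log(ci95[1])) / (2 * Z975)
}

#' Covariate values at score quantiles
#'
#' Regresses a covariate on the score (plus optional adjustment covariates)
#' and reports the model-predicted covariate value at the 20/40/60/80%
#' empirical score quantiles, with adjustment covariates held at their sample
#' means. Binary covariates are deliberately profiled with the *linear* fit,
#' so predictions are not confined to \[0,1\] — a strong association in a
#' small stratum can push the top-quintile prediction above 1. Quantile-bin
#' raw means are available via `method = "binmeans"`.
#'
#' @param score numeric score vector.
#' @param covariate the covariate to profile (continuous or binary).
#' @param covariates optional data.frame of adjustment covariates.
#' @param probs score quantiles to profile (default `c(.2, .4, .6, .8)`).
#' @param method `"model"` (linear-model predictions, default) or
#'   `"binmeans"` (raw means within quantile bins).
#' @return named numeric vector of predicted covariate values.
#' @export
quintileProfile <- function(score, covariate, covariates = NULL,
                            probs = c(0.2, 0.4, 0.6, 0.8),
                            method = c("model", "binmeans")) {
    method <- match.arg(method)
    qs <- quantile(score, probs, names = FALSE)
    if (length(unique(covariate)) < 2L) {
        warning("constant covariate; returning the constant at every quantile")
        return(setNames(rep(covariate[1], length(probs)),
                        paste0(probs * 100, "%")))
    }
    if (method == "binmeans") {
        bins <- cut(score, breaks = c(-Inf, qs, Inf), labels = FALSE)
        means <- tapply(covariate, bins, mean)
        out <- as.numeric(means)[seq_along(probs)]
        return(setNames(out, paste0(probs * 100, "%")))
    }
    dat <- data.frame(.y = covariate, .score = score)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    form <- stats::reformulate(setdiff(names(dat), ".y"), response = ".y")
    fit <- stats::lm(form, data = dat)
    newdat <- data.frame(.score = qs)
    if (!is.null(covariates))
        for (nm in names(covariates)) newdat[[nm]] <- mean(covariates[[nm]])
    setNames(as.numeric(predict(fit, newdata = newdat)),
             paste0(probs * 100, "%"))
}

#' Assign stratum labels to a cohort
#'
#' `"case_control"` labels recruited individuals `"case"` / `"disease-free"`
#' by prevalent disease status; `"subtype"` splits recruited cases into
#' `"CADMI"` / `"CADnoMI"` by a myocardial-infarction flag column (cases
#' without the column or with flag 0 are `"CADnoMI"`). Non-recruited
#' individuals get `NA`; the labels partition the recruited sample.
#'
#' @param cohort a simulated cohort.
#' @param scheme `"case_control"` or `"subtype"`.
#' @param miColumn name of the MI indicator column for the subtype scheme.
#' @return character vector of labels, one per individual.
#' @export
stratifyCohort <- function(cohort, scheme = c("case_control", "subtype"),
                           miColumn = "miFlag") {
    scheme <- match.arg(scheme)
    ph <- phenotypes(cohort)
    lab <- rep(NA_character_, nrow(ph))
    rec <- ph$recruited
    if (scheme == "case_control") {
        lab[rec & ph$prevalentCase] <- "case"
        lab[rec & !ph$prevalentCase] <- "disease-free"
    } else {
        cases <- rec & ph$prevalentCase
        mi <- if (miColumn %in% names(ph)) ph[[miColumn]] == 1 else FALSE
        mi <- rep_len(mi, nrow(ph))
        lab[cases & mi] <- "CADMI"
        lab[cases & !mi] <- "CADnoMI"
    }
    lab
}
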