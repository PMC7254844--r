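# Internal helpers shared across modules.

Z975 <- qnorm(0.975)  # 1.959964...

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic child seed: one global seed is expanded into per-stage seeds
# so stages can be re-run in isolation. Kept below 2^31 - 1.
childSeed <- function(seed, stage) {
    offsets <- c(genotypes = 11L, covariates = 23L, incidence = 37L,
                 recruitment = 53L, prognosis = 71L, external = 97L,
                 simex = 131L, fixtures = 151L, study = 173L)
    off <- offsets[[stage]]
    if (is.null(off)) stop("unknown seed stage: ", stage)
    as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483647)
}

# Wald two-sided P from estimate and SE, floored to avoid underflow to an
# exact zero (which would violate the P in (0, 1] record invariant).
waldP <- function(beta, se) pmax(2 * pnorm(-abs(beta / se)), 1e-300)

orCI <- function(beta, se) exp(c(beta - Z975 * se, beta + Z975 * se))

`%||%` <- function(a, b) if (is.null(a)) b else a
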