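test_that("genotype dosages match their generative frequencies", {
    cfg <- simConfig(nIndividuals = 10000, nSnps = 4, seed = 3,
                     alleleFreqs = rep(0.5, 4), betaIncidence = rep(0, 4))
    g <- simulateGenotypes(cfg)
    expect_true(all(colMeans(g) > 0.97 & colMeans(g) < 1.03))
    rare <- simConfig(nIndividuals = 100, nSnps = 2, seed = 3,
                      alleleFreqs = rep(0.001, 2), betaIncidence = rep(0, 2))
    gr <- simulateGenotypes(rare)
    expect_true(all(gr %in% 0:2))
    expect_gt(mean(gr == 0), 0.97)
})

test_that("identical seeds give bit-identical cohorts, distinct seeds differ", {
    cfg <- simConfig(nIndividuals = 300, nSnps = 10, seed = 5)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(dosages(c1), dosages(c2))
    expect_identical(phenotypes(c1), phenotypes(c2))
    c3 <- simulateCohort(simConfig(nIndividuals = 300, nSnps = 10, seed = 6))
    expect_false(identical(dosages(c1), dosages(c3)))
})

test_that("block LD induces correlation between neighbouring SNPs only", {
    cfg <- simConfig(nIndividuals = 4000, nSnps = 10, seed = 8,
                     ldRho = 0.7, ldBlockSize = 5)
    g <- simulateGenotypes(cfg)
    expect_gt(cor(g[, 1], g[, 2])^2, 0.1)       # adjacent within block
    expect_lt(cor(g[, 5], g[, 6])^2, 0.05)      # across block boundary
    expect_true(all(abs(colMeans(g) / 2 - cfg@alleleFreqs) < 0.05))
})

test_that("prevalence follows the liability threshold", {
    n <- 20000
    nullCfg <- simConfig(nIndividuals = n, nSnps = 2, seed = 9,
                         betaIncidence = rep(0, 2), gammaU = 0,
                         covariateEffects = list(incidence = c(age = 0, sex = 0),
                                                 prognosis = c(age = 0, sex = 0)),
                         incidenceThreshold = 0)
    ph <- phenotypes(simulateIncidence(newCohort(nullCfg)))
    expect_lt(abs(mean(ph$prevalentCase) - 0.5), 3 * sqrt(0.25 / n))
    allCfg <- simConfig(nIndividuals = 200, nSnps = 2, seed = 9,
                        incidenceThreshold = -Inf)
    expect_true(all(phenotypes(simulateIncidence(newCohort(allCfg)))$prevalentCase))
    # configured target prevalence is realized within Monte-Carlo error
    cfg <- simConfig(nIndividuals = 50000, nSnps = 50, seed = 10,
                     targetPrevalence = 0.05)
    ph2 <- phenotypes(simulateIncidence(newCohort(cfg)))
    expect_lt(abs(mean(ph2$prevalentCase) - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))
    # genetic liability effects force a positive case-score correlation
    expect_gt(cor(ph2$prevalentCase, ph2$trueScore), 0)
})

test_that("survival selection depletes high-score cases among the recruited", {
    cfg <- simConfig(nIndividuals = 50000, nSnps = 60, seed = 12,
                     survivalCoefficient = 2)
    ph <- phenotypes(applyRecruitment(simulateIncidence(newCohort(cfg))))
    cases <- ph$prevalentCase
    expect_lt(mean(ph$trueScore[cases & ph$recruited]),
              mean(ph$trueScore[cases]))
    # no selection: recruitment independent of the score
    cfg0 <- simConfig(nIndividuals = 50000, nSnps = 60, seed = 12,
                      survivalCoefficient = 0)
    ph0 <- phenotypes(applyRecruitment(simulateIncidence(newCohort(cfg0))))
    cases0 <- ph0$prevalentCase
    d <- mean(ph0$trueScore[cases0 & ph0$recruited]) -
        mean(ph0$trueScore[cases0])
    expect_lt(abs(d), 3 * sd(ph0$trueScore[cases0]) / sqrt(sum(cases0)))
})

test_that("prognosis requires recruited cases and honours the base rate", {
    cfg <- simConfig(nIndividuals = 200, nSnps = 2, seed = 13,
                     incidenceThreshold = 1e9)  # nobody becomes a case
    coh <- applyRecruitment(simulateIncidence(newCohort(cfg)))
    expect_error(simulatePrognosis(coh), "empty case stratum")
    nullCfg <- simConfig(nIndividuals = 20000, nSnps = 2, seed = 14,
                         betaIncidence = rep(0, 2), gammaU = 0, deltaU = 0,
                         survivalCoefficient = 0,
                         covariateEffects = list(incidence = c(age = 0, sex = 0),
                                                 prognosis = c(age = 0, sex = 0)),
                         incidenceThreshold = 0, prognosisIntercept = -1)
    ph <- phenotypes(simulateCohort(nullCfg))
    rate <- mean(ph$death[ph$recruited])
    expect_lt(abs(rate - plogis(-1)), 3 * sqrt(0.25 / sum(ph$recruited)))
})

test_that("per-SNP GWAS fits agree with a reference logistic regression", {
    fx <- fixtures()
    coh <- fx$cohort
    ph <- phenotypes(coh)
    keep <- ph$recruited & ph$prevalentCase
    prog <- suppressWarnings(gwasPrognosis(coh))
    g <- dosages(coh)
    for (snp in prog$SNP[1:3]) {
        dat <- data.frame(y = ph$death[keep], snp = g[keep, snp],
                          age = (ph$age[keep] - 54.5) / (29 / sqrt(12)),
                          sex = ph$sex[keep])
        ref <- glm(y ~ snp + age + sex, data = dat, family = binomial())
        i <- match(snp, prog$SNP)
        expect_equal(prog$BETA[i], unname(coef(ref)["snp"]), tolerance = 1e-6)
        expect_equal(prog$SE[i],
                     unname(sqrt(diag(vcov(ref)))["snp"]), tolerance = 1e-6)
    }
})

test_that("monomorphic SNPs are dropped from the incidence GWAS", {
    cfg <- simConfig(nIndividuals = 30, nSnps = 3, seed = 15,
                     alleleFreqs = c(0.5, 0.001, 0.5),
                     betaIncidence = rep(0, 3), incidenceThreshold = 0,
                     gammaU = 0)
    expect_warning(out <- gwasIncidence(cfg, nSample = 30), "dropped")
    expect_lt(nrow(out), 3)
})

test_that("null-SNP incidence effects are unbiased across replicates", {
    betas <- vapply(1:200, function(s) {
        cfg <- simConfig(nIndividuals = 500, nSnps = 1, seed = 20000 + s,
                         alleleFreqs = 0.4, betaIncidence = 0, gammaU = 0,
                         incidenceThreshold = 0)
        gwasIncidence(cfg, nSample = 500)$BETA
    }, numeric(1))
    expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("a degenerate prognosis outcome raises an error", {
    fx <- fixtures()
    coh <- fx$cohort
    cd <- SummarizedExperiment::colData(coh)
    cd$death <- 0L
    SummarizedExperiment::colData(coh) <- cd
    expect_error(gwasPrognosis(coh), "degenerate outcome")
})

test_that("cohorts round-trip through the delimited representation", {
    cfg <- simConfig(nIndividuals = 120, nSnps = 8, seed = 21)
    coh <- simulateCohort(cfg)
    path <- withr_local_tempfile()
    writeCohort(coh, path)
    back <- readCohort(path)
    expect_equal(dosages(back), dosages(coh))
    expect_equal(phenotypes(back)$liability, phenotypes(coh)$liability,
                 tolerance = 1e-12)
    expect_equal(cohortConfig(back)@betaIncidence, cfg@betaIncidence,
                 tolerance = 1e-12)
})
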