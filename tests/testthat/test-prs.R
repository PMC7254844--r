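test_that("model construction applies the P threshold and clumping", {
    rec <- makeSumstats(3, seed = 31, chr = "1", bp = c(1e5, 2e5, 3e5))
    rec$P <- c(1e-7, 1e-5, 1e-3)
    ldNone <- ldFromTable(data.frame(SNP_A = character(), SNP_B = character(),
                                     R2 = numeric()))
    m <- buildPRSModel(rec, ldNone, pThreshold = 5e-6)
    expect_equal(nrow(modelEntries(m)), 1)
    expect_equal(modelEntries(m)$snp, "rs0001")
    expect_equal(modelEntries(m)$weight, rec$BETA[1])  # weights are the betas
    # correlated survivors: only the best-P member remains
    rec2 <- rec
    rec2$P <- c(1e-8, 1e-7, 0.5)
    ld <- ldFromTable(data.frame(SNP_A = "rs0001", SNP_B = "rs0002", R2 = 0.9))
    m2 <- buildPRSModel(rec2, ld, pThreshold = 5e-6)
    expect_equal(modelEntries(m2)$snp, "rs0001")
    expect_error(buildPRSModel(rec, ldNone, pThreshold = 1e-12), "empty model")
})

test_that("scoring is the weighted dosage sum with the documented imputation", {
    g <- matrix(c(2, 1, 0, 1), nrow = 2,
                dimnames = list(NULL, c("rs1", "rs2")))
    m <- new("PRSModel",
             entries = data.frame(snp = c("rs1", "rs2"), ea = c("A", "C"),
                                  weight = c(0.1, -0.2)),
             provenance = list())
    expect_equal(scoreIndividuals(g, m), c(0.1 * 2 - 0.2 * 0, 0.1 * 1 - 0.2 * 1))
    expect_equal(scoreIndividuals(g, m)[1], 0.2)
    # zero weights give zero scores
    m0 <- new("PRSModel", entries = data.frame(snp = c("rs1", "rs2"),
                                               ea = c("A", "C"),
                                               weight = c(0, 0)),
              provenance = list())
    expect_equal(scoreIndividuals(g, m0), c(0, 0))
    # missing dosage imputed at 2*eaf
    gna <- g; gna[1, "rs2"] <- NA
    s <- scoreIndividuals(gna, m, eaf = c(rs2 = 0.25))
    expect_equal(s[1], 0.1 * 2 - 0.2 * 0.5)
    # absent model variant is an error naming the id
    mBad <- new("PRSModel", entries = data.frame(snp = "rs9", ea = "A",
                                                 weight = 1),
                provenance = list())
    expect_error(scoreIndividuals(g, mBad), "rs9")
})

test_that("dosage re-orientation makes scores allele-convention invariant", {
    set.seed(41)
    g <- matrix(rbinom(60, 2, 0.4), nrow = 20,
                dimnames = list(NULL, c("rs1", "rs2", "rs3")))
    m <- new("PRSModel",
             entries = data.frame(snp = c("rs1", "rs2", "rs3"),
                                  ea = c("A", "C", "G"),
                                  weight = c(0.1, -0.2, 0.3)),
             provenance = list())
    base <- scoreIndividuals(g, m, dosageAlleles = c(rs1 = "A", rs2 = "C",
                                                     rs3 = "G"))
    # flip rs2's model entry: effect allele becomes the other allele,
    # weight negates; dosages still count "C"
    mFlip <- new("PRSModel",
                 entries = data.frame(snp = c("rs1", "rs2", "rs3"),
                                      ea = c("A", "T", "G"),
                                      weight = c(0.1, 0.2, 0.3)),
                 provenance = list())
    flip <- scoreIndividuals(g, mFlip, dosageAlleles = c(rs1 = "A", rs2 = "C",
                                                         rs3 = "G"))
    expect_equal(flip, base + 2 * (-0.2) * -1)  # constant offset 2*w only
    expect_equal(diff(range((flip - base))), 0)
    expect_equal(standardizeScore(flip), standardizeScore(base))
})

test_that("scoring is linear in the weight vector", {
    set.seed(42)
    g <- matrix(rbinom(40, 2, 0.5), nrow = 10,
                dimnames = list(NULL, c("a", "b", "c", "d")))
    w1 <- c(0.1, 0.2, -0.3, 0); w2 <- c(-0.2, 0.1, 0.5, 1)
    mk <- function(w) new("PRSModel",
                          entries = data.frame(snp = colnames(g), ea = "A",
                                               weight = w),
                          provenance = list())
    expect_equal(scoreIndividuals(g, mk(w1 + w2)),
                 scoreIndividuals(g, mk(w1)) + scoreIndividuals(g, mk(w2)))
})

test_that("standardization is the n-1 sample z-score and is idempotent", {
    expect_equal(standardizeScore(c(1, 2, 3)), c(-1, 0, 1))
    z <- standardizeScore(rnorm(50))
    expect_equal(standardizeScore(z), z, tolerance = 1e-12)
    expect_error(standardizeScore(rep(2, 5)), "constant")
})

test_that("per-SD odds ratios obey the scaling identity exp(b * s)", {
    set.seed(43)
    n <- 2000
    raw <- rnorm(n, 0, 2.7)
    y <- rbinom(n, 1, plogis(-1 + 0.3 * raw))
    bRaw <- coef(glm(y ~ raw, family = binomial()))["raw"]
    z <- standardizeScore(raw)
    bZ <- coef(glm(y ~ z, family = binomial()))["z"]
    expect_equal(unname(exp(bZ)), unname(exp(bRaw * sd(raw))), tolerance = 1e-6)
})

test_that("PRS models persist as TSV plus provenance sidecar", {
    fx <- fixtures()
    ld <- ldFromPanel(fx$panel)
    rec <- fx$incStats[1:20, ]
    rec$P <- rec$P / 1e4  # ensure survivors at the default threshold
    m <- suppressWarnings(buildPRSModel(rec, ld, pThreshold = 0.05))
    path <- withr_local_tempfile()
    writePRSModel(m, path)
    back <- readPRSModel(path)
    expect_equal(modelEntries(back), modelEntries(m), tolerance = 1e-12)
    expect_equal(modelProvenance(back)$p_threshold, 0.05)
})
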