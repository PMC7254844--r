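test_that("pairing composes harmonization, INFO and LD filters", {
    inc <- makeSumstats(10, seed = 61, chr = "1",
                        bp = seq(1e5, 1e6, length.out = 10))
    prog <- inc
    prog$BETA <- rnorm(10, 0, 0.05)
    inc$INFO <- c(rep(1, 8), 0.9, 0.9)          # 2 fail INFO
    ld <- ldFromTable(data.frame(SNP_A = c("rs0001", "rs0003"),
                                 SNP_B = c("rs0002", "rs0004"),
                                 R2 = c(0.8, 0.9)))                # 2 pruned
    pairs <- pairAndFilter(inc, prog, ld, infoMin = 0.99)
    expect_equal(nrow(pairs), 6)
    counts <- attr(pairs, "stage_counts")
    expect_equal(unname(counts["harmonized"]), 10)
    expect_equal(unname(counts["info"]), 8)
    expect_equal(unname(counts["pruned"]), 6)
    # incidence-P subsetting removes exactly the nominally-null SNPs
    sub <- pairAndFilter(inc, prog, ld, infoMin = 0.99, pIncMax = 0.05)
    expect_true(all(sub$P_INC < 0.05))
    expect_equal(nrow(sub), sum(pairs$P_INC < 0.05))
    # disjoint SNP sets cannot be paired
    prog2 <- prog; prog2$SNP <- paste0("x", prog2$SNP)
    expect_error(pairAndFilter(inc, prog2, ld), "no shared variants")
})

test_that("the naive slope is ordinary least squares", {
    b1 <- c(0.1, 0.2, 0.3, -0.1, 0.05)
    pairs <- makePairs(b1, 0.5 * b1, se1 = 0.01, se2 = 0.01)
    expect_equal(estimate(slopeNaive(pairs)), 0.5, tolerance = 1e-12)
    set.seed(62)
    pairs2 <- makePairs(rnorm(30, 0, 0.1), rnorm(30, 0, 0.05),
                        se1 = 0.02, se2 = 0.02)
    ref <- lm(BETA_PROG ~ BETA_INC, data = pairs2)
    sl <- slopeNaive(pairs2)
    expect_equal(estimate(sl), unname(coef(ref)["BETA_INC"]), tolerance = 1e-10)
    expect_equal(stdError(sl), unname(sqrt(diag(vcov(ref)))["BETA_INC"]),
                 tolerance = 1e-10)
    refNoInt <- lm(BETA_PROG ~ BETA_INC - 1, data = pairs2)
    expect_equal(estimate(slopeNaive(pairs2, intercept = FALSE)),
                 unname(coef(refNoInt)), tolerance = 1e-10)
    expect_error(slopeNaive(makePairs(rep(0.1, 5), rnorm(5), 0.01, 0.01)),
                 "zero variance")
})

test_that("Hedges-Olkin de-attenuation follows the closed form", {
    set.seed(63)
    pairs <- makePairs(rnorm(50, 0, 0.1), rnorm(50, 0, 0.05),
                       se1 = runif(50, 0.01, 0.03), se2 = 0.02)
    ho <- slopeHedgesOlkin(pairs)
    direct <- cov(pairs$BETA_INC, pairs$BETA_PROG) /
        (var(pairs$BETA_INC) - mean(pairs$SE_INC^2))
    expect_equal(estimate(ho), direct, tolerance = 1e-10)
    # no measurement error: reduces exactly to the naive OLS slope
    pairs0 <- makePairs(pairs$BETA_INC, pairs$BETA_PROG, se1 = 0, se2 = 0.02)
    expect_equal(estimate(slopeHedgesOlkin(pairs0)),
                 estimate(slopeNaive(pairs0)), tolerance = 1e-12)
    # noise-dominated incidence effects are refused
    noisy <- makePairs(rnorm(10, 0, 0.01), rnorm(10), se1 = 1, se2 = 1)
    expect_error(slopeHedgesOlkin(noisy), "dominated by noise")
})

test_that("the naive slope attenuates and Hedges-Olkin restores it", {
    set.seed(64)
    b1true <- rnorm(300, 0, 0.1)
    b2 <- -0.4 * b1true + rnorm(300, 0, 0.02)
    b1obs <- b1true + rnorm(300, 0, 0.05)
    pairs <- makePairs(b1obs, b2, se1 = 0.05, se2 = 0.02)
    naive <- estimate(slopeNaive(pairs))
    expect_gt(naive, -0.4)                       # attenuated towards zero
    expect_lt(abs(estimate(slopeHedgesOlkin(pairs)) + 0.4),
              abs(naive + 0.4))                  # HO closer to the truth
})

test_that("SIMEX reduces to the naive slope without measurement error", {
    set.seed(65)
    pairs <- makePairs(rnorm(20, 0, 0.1), rnorm(20, 0, 0.05),
                       se1 = 0, se2 = 0.02)
    sx <- slopeSimex(pairs, nSim = 50, seed = 9)
    expect_equal(estimate(sx), estimate(slopeNaive(pairs)), tolerance = 1e-12)
    expect_true(all(sx@diagnostics$mean_slope == estimate(slopeNaive(pairs))))
})

test_that("SIMEX is seed-reproducible and attenuates monotonically", {
    set.seed(66)
    b1true <- rnorm(400, 0, 0.1)
    b1obs <- b1true + rnorm(400, 0, 0.04)
    b2 <- -0.3 * b1true + rnorm(400, 0, 0.02)
    pairs <- makePairs(b1obs, b2, se1 = 0.04, se2 = 0.02)
    s1 <- slopeSimex(pairs, nSim = 300, seed = 7)
    s2 <- slopeSimex(pairs, nSim = 300, seed = 7)
    expect_identical(estimate(s1), estimate(s2))
    expect_identical(s1@diagnostics$mean_slope, s2@diagnostics$mean_slope)
    # |slope(lambda)| decreases as noise is added
    expect_true(all(diff(abs(s1@diagnostics$mean_slope)) < 0))
    # extrapolation lands beyond the naive slope, towards the generative value
    expect_lt(estimate(s1), s1@diagnostics$naive)
    expect_error(slopeSimex(pairs, lambdaGrid = c(0, 3)), "\\[0, 2\\]")
})

test_that("I2GX matches its hand-computed definition and is scale invariant", {
    pairs <- makePairs(c(0.1, 0.2, 0.3), c(0, 0, 0), se1 = 0.01, se2 = 1)
    out <- i2GX(pairs)
    # equal weights: weighted mean 0.2, Q = (0.01 + 0 + 0.01)/1e-4 = 200
    expect_equal(out$q, 200, tolerance = 1e-10)
    expect_equal(out$i2, (200 - 2) / 200, tolerance = 1e-10)
    expect_equal(out$k, 3)
    same <- makePairs(rep(0.2, 4), rep(0, 4), se1 = 0.05, se2 = 1)
    expect_equal(i2GX(same)$i2, 0)
    scaled <- makePairs(c(0.1, 0.2, 0.3) * 7, c(0, 0, 0), se1 = 0.07, se2 = 1)
    expect_equal(i2GX(scaled)$i2, out$i2, tolerance = 1e-12)
    expect_error(i2GX(pairs[1, ]), "at least 2")
})

test_that("beta adjustment is the quoted subtraction rule with variance sum", {
    pairs <- makePairs(0.20, 0.10, se1 = 0.04, se2 = 0.03)
    adj <- adjustPrognosis(pairs, 0.05)
    expect_equal(adj$BETA, 0.10 - 0.05 * 0.20, tolerance = 1e-12)
    adj2 <- adjustPrognosis(pairs, 0.5)
    expect_equal(adj2$SE, sqrt(0.03^2 + 0.5^2 * 0.04^2), tolerance = 1e-12)
    expect_equal(adj2$SE, 0.0360555, tolerance = 1e-6)
    # zero slope is the identity on betas and SEs
    adj0 <- adjustPrognosis(pairs, 0)
    expect_equal(adj0$BETA, pairs$BETA_PROG)
    expect_equal(adj0$SE, pairs$SE_PROG)
    # adjusting by b1 then b2 equals one pass with b1 + b2 (betas exactly)
    set.seed(67)
    many <- makePairs(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1),
                      se1 = 0.02, se2 = 0.02)
    once <- adjustPrognosis(many, 0.3)
    twicePairs <- many
    twicePairs$BETA_PROG <- adjustPrognosis(many, 0.1)$BETA
    expect_equal(adjustPrognosis(twicePairs, 0.2)$BETA,
                 adjustPrognosis(many, 0.3)$BETA, tolerance = 1e-14)
    expect_equal(once$BETA, many$BETA_PROG - 0.3 * many$BETA_INC)
})

test_that("IVW is weighted regression through the origin with unit dispersion", {
    # single instrument: the Wald ratio
    one <- makePairs(0.25, 0.1, se1 = 0.01, se2 = 0.04)
    res <- ivw(one)
    expect_equal(estimate(res), 0.1 / 0.25, tolerance = 1e-12)
    expect_equal(stdError(res), 0.04 / 0.25, tolerance = 1e-12)
    set.seed(68)
    pairs <- makePairs(rnorm(40, 0, 0.15), rnorm(40, 0, 0.1),
                       se1 = 0.01, se2 = runif(40, 0.02, 0.08))
    res2 <- ivw(pairs)
    ref <- lm(BETA_PROG ~ BETA_INC - 1, data = pairs,
              weights = 1 / pairs$SE_PROG^2)
    expect_equal(estimate(res2), unname(coef(ref)), tolerance = 1e-10)
    refSE <- unname(sqrt(diag(vcov(ref)))) / summary(ref)$sigma
    expect_equal(stdError(res2), refSE, tolerance = 1e-10)
    expect_error(ivw(makePairs(c(0, 0), c(1, 1), 0.1, 0.1)),
                 "no instrument strength")
    expect_error(ivw(pairs, instruments = "zzz"), "absent")
})

test_that("the corrected IVW equals raw minus slope in unadjusted-weight mode", {
    set.seed(69)
    inc <- makeSumstats(30, seed = 70, chr = "1",
                        bp = seq(5e4, 3e6, length.out = 30))
    prog <- inc
    prog$BETA <- -0.2 * inc$BETA + rnorm(30, 0, 0.02)
    ldNone <- ldFromTable(data.frame(SNP_A = character(), SNP_B = character(),
                                     R2 = numeric()))
    res <- correctAndEstimate(inc, prog, ldNone,
                              instruments = inc$SNP[1:10],
                              slopeMethod = "hedges_olkin", pIncMax = NULL,
                              ivwWeights = "unadjusted")
    expect_equal(estimate(res$corrected),
                 estimate(res$raw) - estimate(res$slope), tolerance = 1e-12)
    # a zero slope leaves the IVW untouched end to end
    pairs <- pairAndFilter(inc, prog, ldNone)
    adj <- adjustPrognosis(pairs, 0)
    expect_equal(ivw(pairs, beta2 = adj$BETA, se2 = adj$SE)@beta,
                 ivw(pairs)@beta, tolerance = 1e-14)
})
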