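#' Assemble a full run configuration
#'
#' Nested configuration for [runSimulationStudy()], with every analysis
#' threshold defaulting to the published workflow settings: PRS inclusion at
#' P < 5e-6 with clumping at r² < 0.2 within 250 kb; correction filters
#' INFO > 0.99, pruning (250 kb window, 5-SNP step, r² = 0.1) and a P < 0.05
#' incidence subset for slope estimation. The simulation block holds the
#' [simConfig()] arguments; `externalN` sizes the independent case-control
#' sample behind the incidence GWAS, and `panelN` the LD reference panel.
#'
#' @param seed global seed; expanded deterministically into per-stage seeds.
#' @param simulation named list of [simConfig()] overrides.
#' @param externalN external incidence-GWAS sample size.
#' @param panelN individuals in the simulated LD reference panel.
#' @param prs list: `p_threshold`, `r2_max`, `window_bp`.
#' @param correction list: `info_min`, `prune` (window_bp/step_snps/r2_max),
#'   `p_inc_max`, `slope_method`, `simex` (lambda/n_sim), `ivw_weights`,
#'   `instruments` (explicit SNP id list, or NULL to use the PRS model's
#'   clumped genome-wide-strict SNPs).
#' @return a nested list; serializes losslessly to YAML.
#' @seealso [readRunConfig()], [writeRunConfig()]
#' @export
runConfig <- function(seed = 1, simulation = list(), externalN = 50000,
                      panelN = 500,
                      prs = list(p_threshold = 5e-6, r2_max = 0.2,
                                 window_bp = 250000),
                      correction = list(info_min = 0.99,
                                        prune = list(window_bp = 250000,
                                                     step_snps = 5,
                                                     r2_max = 0.1),
                                        p_inc_max = 0.05,
                                        slope_method = "simex",
                                        simex = list(lambda = c(0, 0.5, 1, 1.5, 2),
                                                     n_sim = 1000),
                                        ivw_weights = "adjusted",
                                        instruments = NULL)) {
    defaults <- runConfig
    cfg <- list(seed = as.integer(seed), simulation = simulation,
                externalN = externalN, panelN = panelN,
                prs = modifyList(eval(formals(defaults)$prs), prs),
                correction = modifyList(eval(formals(defaults)$correction),
                                        correction))
    # empty vector = "use the PRS model's clumped SNPs"; keeps YAML lossless
    cfg$correction$instruments <- as.character(cfg$correction$instruments)
    cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a configuration list from [runConfig()].
#' @return the configuration list (read); `path` invisibly (write).
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(runConfig, raw)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Run the complete simulation study
#'
#' The synthetic analogue of the full analysis: simulate a cohort with
#' survival-selected prevalent cases, run an independent case-control
#' incidence GWAS, build the thresholded/clumped PRS, score and standardize
#' over the recruited sample, estimate stratified per-SD associations with
#' heterogeneity tests, profile covariates at score quintiles, and run the
#' index-event-bias correction (slope, I²GX, adjusted effects, IVW before and
#' after). Everything is seeded from `config$seed`; identical configs give
#' identical reports.
#'
#' @param config a list from [runConfig()].
#' @return list with elements `config`, `prsModel`, `associations` (tidy
#'   data.frame, one row per stratum x outcome), `heterogeneity`, `profiles`,
#'   `correction` (as returned by [correctAndEstimate()]) and
#'   `stage_counts`.
#' @export
runSimulationStudy <- function(config = runConfig()) {
    simArgs <- modifyList(list(seed = config$seed), config$simulation)
    simCfg <- do.call(simConfig, simArgs)
    cohort <- simulateCohort(simCfg)
    ph <- phenotypes(cohort)

    incStats <- gwasIncidence(simCfg, nSample = config$externalN)
    panel <- simulateGenotypes(simCfg, n = config$panelN,
                               seed = childSeed(config$seed, "fixtures"))
    ld <- ldFromPanel(panel)

    model <- buildPRSModel(incStats, ld,
                           pThreshold = config$prs$p_threshold,
                           r2Max = config$prs$r2_max,
                           windowBp = config$prs$window_bp)
    raw <- scoreIndividuals(cohort, model)
    rec <- ph$recruited
    z <- rep(NA_real_, length(raw))
    z[rec] <- standardizeScore(raw[rec])

    strata <- stratifyCohort(cohort, "case_control")
    covs <- data.frame(age = ageZ(ph$age), sex = ph$sex)
    fitIn <- function(stratum, outcome) {
        i <- which(strata == stratum & !is.na(ph[[outcome]]))
        fitOutcomeAssoc(z[i], ph[[outcome]][i], covs[i, ], stratum = stratum,
                        outcomeName = outcome)
    }
    fits <- list(
        fitIn("disease-free", "incidentDisease"),
        fitIn("disease-free", "death"),
        fitIn("case", "death"))
    associations <- do.call(rbind, lapply(fits, function(f)
        data.frame(stratum = f@stratum, outcome = f@outcome, n = f@n,
                   beta = f@beta, se = f@se, p = f@p, or = f@or,
                   ci_lower = f@ci95[1], ci_upper = f@ci95[2])))
    het <- heterogeneityTest(fits[[2]], fits[[3]])
    heterogeneity <- data.frame(outcome = "death", z = het$z, p = het$p)

    profiles <- lapply(c(case = "case", `disease-free` = "disease-free"),
                       function(s) {
        i <- which(strata == s)
        list(age = quintileProfile(z[i], ph$age[i]),
             sex = quintileProfile(z[i], ph$sex[i]))
    })

    progStats <- gwasPrognosis(cohort)
    corrCfg <- config$correction
    instruments <- if (length(corrCfg$instruments)) corrCfg$instruments
                   else modelEntries(model)$snp
    correction <- correctAndEstimate(
        incStats, progStats, ld, instruments = instruments,
        slopeMethod = corrCfg$slope_method,
        infoMin = corrCfg$info_min, pruneParams = corrCfg$prune,
        pIncMax = corrCfg$p_inc_max,
        simex = list(lambda = corrCfg$simex$lambda,
                     n_sim = corrCfg$simex$n_sim,
                     seed = childSeed(config$seed, "simex")),
        ivwWeights = corrCfg$ivw_weights)

    list(config = config, prsModel = model, associations = associations,
         heterogeneity = heterogeneity, profiles = profiles,
         correction = correction,
         stage_counts = correction$stage_counts)
}

#' Write the study report to disk
#'
#' Tidy TSVs for the association and heterogeneity tables, the adjusted
#' summary statistics, the PRS model, and a JSON report of the correction
#' (raw and corrected IVW, slope, I²GX, stage counts) plus the config echo.
#'
#' @param report output of [runSimulationStudy()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(report$associations,
                       file.path(dir, "associations.tsv"), sep = "\t")
    data.table::fwrite(report$heterogeneity,
                       file.path(dir, "heterogeneity.tsv"), sep = "\t")
    writeSumstats(report$correction$adjusted,
                  file.path(dir, "adjusted_sumstats.tsv"))
    writePRSModel(report$prsModel, file.path(dir, "prs_model.tsv"))
    corr <- report$correction
    jsonlite::write_json(list(
        config = report$config,
        raw = list(beta = corr$raw@beta, se = corr$raw@se, p = corr$raw@p,
                   or = corr$raw@or, ci95 = corr$raw@ci95,
                   n_instruments = corr$raw@nInstruments),
        slope = list(method = corr$slope@method, value = corr$slope@value,
                     se = corr$slope@se, ci95 = corr$slope@ci95,
                     n_snps = corr$slope@nSnps),
        i2_gx = corr$i2_gx,
        corrected = list(beta = corr$corrected@beta, se = corr$corrected@se,
                         p = corr$corrected@p, or = corr$corrected@or,
                         ci95 = corr$corrected@ci95),
        stage_counts = as.list(report$stage_counts)),
        file.path(dir, "correction_report.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Generate the small deterministic fixtures used by the test-suite
#'
#' A 50-SNP incidence/prognosis summary-statistics pair, a 20-SNP LD dosage
#' panel (with block LD so clumping and pruning have something to remove) and
#' a 2000-person cohort, all reproducible from `seed`.
#'
#' @param seed integer seed (default 42).
#' @return list with elements `incStats`, `progStats`, `panel`, `cohort`,
#'   `config`.
#' @export
generateFixtures <- function(seed = 42) {
    cfg <- simConfig(nIndividuals = 2000, nSnps = 50, seed = seed,
                     ldRho = 0.4, ldBlockSize = 5)
    cohort <- simulateCohort(cfg)
    incStats <- gwasIncidence(cfg, nSample = 4000)
    progCfg <- simConfig(nIndividuals = 20000, nSnps = 50,
                         seed = childSeed(seed, "fixtures"),
                         alleleFreqs = cfg@alleleFreqs,
                         betaIncidence = cfg@betaIncidence,
                         incidenceThreshold = cfg@incidenceThreshold,
                         ldRho = 0.4, ldBlockSize = 5)
    progStats <- gwasPrognosis(simulateCohort(progCfg))
    panelCfg <- simConfig(nIndividuals = 200, nSnps = 20,
                          seed = childSeed(seed, "external"),
                          alleleFreqs = cfg@alleleFreqs[1:20],
                          betaIncidence = cfg@betaIncidence[1:20],
                          ldRho = 0.4, ldBlockSize = 5)
    panel <- simulateGenotypes(panelCfg)
    list(incStats = incStats, progStats = progStats, panel = panel,
         cohort = cohort, config = cfg)
}
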