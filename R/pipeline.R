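pipelineDefaults <- function() {
  list(seed = 1L,
       discoveryCohorts = 4L,
       replicationCohorts = 2L,
       rescale = FALSE,
       simulation = list(),
       estimators = list(phi = 1, nBoot = 1000L, nSim = 1000L,
                         significance = 0.05),
       riskFactors = c("bmi", "waist_circumference", "waist_hip_ratio",
                       "ldl", "triglycerides", "homa_ir", "type2_diabetes"),
       outputDir = NULL)
}

mergeConfig <- function(user, defaults) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(user[[nm]], defaults[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

mrRow <- function(fit) {
  data.frame(method = mrMethod(fit), nVariants = fit@nVariants,
             estimate = estimate(fit), se = stdError(fit),
             ciLower = confInt(fit)[1L], ciUpper = confInt(fit)[2L],
             or = exp(estimate(fit)), orLower = exp(confInt(fit)[1L]),
             orUpper = exp(confInt(fit)[2L]), p = pvalue(fit))
}

#' Run the full Mendelian-randomization pipeline on synthetic data
#'
#' Executes simulate -> build-score -> two-stage Cox per cohort ->
#' discovery/replication/combined meta-analysis -> two-sample estimators
#' (IVW, MR-Egger, weighted median, weighted MBE, MR-PRESSO) ->
#' risk-factor screen, end to end, from one configuration. Every random
#' stage derives its stream from the single configured seed, so a rerun
#' with the same configuration is bit-identical.
#'
#' @param config a named list, or path to a YAML file, overriding any of:
#'   `seed`; `discoveryCohorts`; `replicationCohorts`; `rescale` (rescale
#'   the allele score within cohort); `simulation` (arguments to
#'   [simConfig()]); `estimators` (`phi`, `nBoot`, `nSim`,
#'   `significance`); `riskFactors` (names of the null risk-factor
#'   outcomes simulated for the screen); `outputDir` (when set, all
#'   tables plus a manifest recording the config hash and seeds are
#'   written there as TSV/YAML).
#' @return list with elements `perCohort` (estimate rows), `meta`
#'   (discovery/replication/combined [MetaResult-class]s), `mr`
#'   (two-sample fits and their table), `screen` (risk-factor screen
#'   table), `scoreCheck` (allele-score risk-factor associations),
#'   `panel`, and `manifest`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(config, pipelineDefaults())
  seed <- as.integer(cfg$seed)
  nCoh <- cfg$discoveryCohorts + cfg$replicationCohorts
  simCfg <- runStage("simulate", do.call(simConfig, c(
    cfg$simulation[setdiff(names(cfg$simulation), c("seed", "nCohorts"))],
    list(seed = seed, nCohorts = nCoh))))
  cohorts <- runStage("simulate",
    lapply(seq_len(nCoh), function(i) simulateCohort(simCfg, i)))
  arms <- rep(c("discovery", "replication"),
              c(cfg$discoveryCohorts, cfg$replicationCohorts))

  # instrument panel from the generative truth, run through all four filters
  m <- simCfg@nVariants
  panel <- runStage("build-score", {
    pan <- newVariantPanel(data.frame(
      variantId = variantNames(m), effectAllele = rep("A", m),
      otherAllele = rep("G", m), beta = simCfg@betaExposure,
      se = 1 / sqrt(2 * simCfg@eaf * (1 - simCfg@eaf) * simCfg@nExposureGwas),
      sourceRank = 1L, stringsAsFactors = FALSE))
    pan <- filterImputationQuality(pan, data.frame(
      variantId = character(0), method = character(0), quality = numeric(0)))
    pan <- filterRiskFactorCorrelation(pan, cohorts)
    pan <- filterChdLd(pan, data.frame(variantId = character(0),
                                       locus = character(0), r2 = numeric(0)))
    pan <- pruneLdPairs(pan, data.frame(id1 = character(0),
                                        id2 = character(0), r2 = numeric(0)))
    filterMissingness(pan, cohorts[arms == "discovery"])
  })
  cohortScores <- runStage("build-score", lapply(cohorts, function(coh) {
    al <- alignEffectAlleles(panel, dosages(coh))
    s <- computeAlleleScore(al$dosages, al$panel)
    if (isTRUE(cfg$rescale)) rescaleScore(s) else s
  }))
  scoreCheck <- runStage("build-score", scoreRiskFactorCheck(cohorts, cohortScores))

  perCohort <- runStage("fit-2sc", do.call(rbind, lapply(seq_len(nCoh),
    function(i) {
      fit <- twoStageCox(cohorts[[i]], cohortScores[[i]])
      data.frame(cohort = cohortLabel(cohorts[[i]]), arm = arms[i],
                 method = "2sc", estimate = estimate(fit), se = stdError(fit),
                 ciLower = confInt(fit)[1L], ciUpper = confInt(fit)[2L],
                 p = pvalue(fit), n = fit@n, nEvents = fit@nEvents,
                 stage1F = fit@stage1F)
    })))

  metas <- runStage("meta", combineDiscoveryReplication(
    perCohort[perCohort$arm == "discovery", ],
    perCohort[perCohort$arm == "replication", ]))

  est <- cfg$estimators
  ss <- runStage("mr2", simulateSummaryStats(simCfg))
  fits <- runStage("mr2", list(
    ivw = mrIvw(ss),
    egger = mrEgger(ss),
    weighted_median = mrWeightedMedian(ss, nBoot = est$nBoot,
                                       seed = deriveSeed(seed, 21L)),
    mbe = mrWeightedMode(ss, phi = est$phi, nBoot = est$nBoot,
                         seed = deriveSeed(seed, 22L)),
    presso = mrPresso(ss, nSim = est$nSim, seed = deriveSeed(seed, 23L),
                      significance = est$significance)))
  mrTable <- do.call(rbind, lapply(fits, mrRow))

  exposureTab <- {
    d <- as.data.frame(ss)
    data.frame(variantId = d$variantId, effectAllele = d$effectAllele,
               otherAllele = d$otherAllele, eaf = d$eaf,
               beta = d$betaExposure, se = d$seExposure)
  }
  screen <- runStage("screen", {
    outcomeTables <- lapply(seq_along(cfg$riskFactors), function(i) {
      nullCfg <- simConfig(
        nIndividuals = simCfg@nIndividuals, nCohorts = 1L, nVariants = m,
        eaf = simCfg@eaf, betaExposure = simCfg@betaExposure,
        causalEffect = 0, pleiotropyMode = "none",
        nExposureGwas = simCfg@nExposureGwas,
        nOutcomeGwas = simCfg@nOutcomeGwas,
        seed = deriveSeed(seed, 100L + i))
      d <- as.data.frame(simulateSummaryStats(nullCfg))
      data.frame(variantId = d$variantId, effectAllele = d$effectAllele,
                 otherAllele = d$otherAllele, eaf = d$eaf,
                 beta = d$betaOutcome, se = d$seOutcome)
    })
    names(outcomeTables) <- cfg$riskFactors
    riskFactorScreen(exposureTab, outcomeTables, nBoot = est$nBoot,
                     seed = deriveSeed(seed, 31L))
  })

  manifest <- list(seed = seed,
                   discoveryCohorts = cfg$discoveryCohorts,
                   replicationCohorts = cfg$replicationCohorts,
                   nVariants = m, retainedVariants = length(retainedVariants(panel)),
                   estimators = est,
                   bonferroniScore = bonferroniThreshold(6L)$threshold,
                   bonferroniScreen = attr(screen, "threshold"))

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    cfgPath <- file.path(cfg$outputDir, "config.yaml")
    yaml::write_yaml(cfg[setdiff(names(cfg), "outputDir")], cfgPath)
    manifest$configHash <- unname(tools::md5sum(cfgPath))
    writeEstimates(cbind(perCohort[, c("cohort", "method", "estimate", "se",
                                       "ciLower", "ciUpper", "p", "n",
                                       "nEvents")]),
                   file.path(cfg$outputDir, "per_cohort_estimates.tsv"))
    writeSummaryPairs(ss, file.path(cfg$outputDir, "summary_pairs.tsv"))
    writeTsv(mrTable, file.path(cfg$outputDir, "mr_estimates.tsv"))
    writeTsv(screen, file.path(cfg$outputDir, "risk_factor_screen.tsv"))
    yaml::write_yaml(manifest, file.path(cfg$outputDir, "manifest.yaml"))
  }

  list(perCohort = perCohort, meta = metas, mr = list(fits = fits, table = mrTable),
       screen = screen, scoreCheck = scoreCheck, panel = panel,
       manifest = manifest)
}
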