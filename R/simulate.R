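#' Build a simulation configuration
#'
#' Defines the generative truth for a synthetic multi-cohort Mendelian
#' randomization study: Hardy-Weinberg genotypes, a genetic plus confounded
#' fibrinogen exposure, an exponential proportional-hazards incident
#' outcome, and two-sample GWAS summary statistics with configurable
#' horizontal pleiotropy.
#'
#' When `alpha` is not supplied it is generated from `pleiotropyMode` (using
#' the master seed, so the configuration is fully reproducible): `"none"`
#' sets all direct effects to zero; `"balanced"` draws them with mean zero
#' and SD `pleiotropySd`; `"directional"` draws them with mean
#' `pleiotropyMean` and SD `pleiotropySd` independently of the instrument
#' strengths (the InSIDE condition); `"outliers"` leaves all but the first
#' `nOutliers` variants at zero and gives those a direct effect of
#' `outlierAlpha`.
#'
#' @param nIndividuals individuals per cohort.
#' @param nCohorts number of cohorts.
#' @param nVariants number of instrument variants M.
#' @param eaf effect-allele frequencies (length M, strictly inside (0,1)).
#' @param betaExposure per-allele fibrinogen effects, g/L.
#' @param causalEffect causal effect of fibrinogen on the outcome per 1 g/L
#'   (log hazard one-sample; log odds two-sample).
#' @param pleiotropyMode "none", "balanced", "directional" or "outliers".
#' @param alpha optional explicit direct variant-outcome effects (length M).
#' @param pleiotropyMean,pleiotropySd,nOutliers,outlierAlpha generation
#'   parameters for `alpha`, see Details.
#' @param confExposure,confOutcome latent-confounder effects on fibrinogen
#'   (g/L per SD) and on the log hazard.
#' @param baselineHazard baseline event rate, events per person-year.
#' @param censoringMax administrative censoring time, years.
#' @param noiseSd residual fibrinogen SD, g/L.
#' @param ageEffect,sexEffect fibrinogen shifts per year of age (centred at
#'   55) and for male sex.
#' @param fibrinogenMean target population mean fibrinogen, g/L.
#' @param nExposureGwas,nOutcomeGwas effective sample sizes behind the
#'   exposure and outcome summary statistics.
#' @param seed master seed; every cohort and the summary statistics use a
#'   counter-derived stream from it.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nIndividuals = 500, nCohorts = 2, nVariants = 10, seed = 7)
#' cfg
#' @export
simConfig <- function(nIndividuals = 5000L, nCohorts = 6L, nVariants = 38L,
                      eaf = NULL, betaExposure = NULL,
                      causalEffect = 0.25,
                      pleiotropyMode = c("none", "balanced", "directional", "outliers"),
                      alpha = NULL, pleiotropyMean = 0.05, pleiotropySd = 0.02,
                      nOutliers = 2L, outlierAlpha = NULL,
                      confExposure = 0.3, confOutcome = 0.3,
                      baselineHazard = 0.005, censoringMax = 12,
                      noiseSd = 0.6, ageEffect = 0.01, sexEffect = -0.1,
                      fibrinogenMean = 3.0,
                      nExposureGwas = 50000, nOutcomeGwas = 184305,
                      seed = 1L) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  m <- as.integer(nVariants)
  if (is.null(eaf)) eaf <- seq(0.1, 0.5, length.out = m)
  if (is.null(betaExposure)) betaExposure <- seq(0.02, 0.08, length.out = m)
  if (is.null(alpha)) {
    alpha <- switch(pleiotropyMode,
      none = rep(0, m),
      balanced = withSeed(deriveSeed(seed, 9001L), rnorm(m, 0, pleiotropySd)),
      directional = withSeed(deriveSeed(seed, 9002L),
                             rnorm(m, pleiotropyMean, pleiotropySd)),
      outliers = {
        if (nOutliers >= m) stop("nOutliers must be smaller than nVariants")
        if (is.null(outlierAlpha))
          outlierAlpha <- 10 * mean(abs(betaExposure)) * max(abs(causalEffect), 0.25)
        a <- rep(0, m)
        a[seq_len(nOutliers)] <- outlierAlpha
        a
      })
  }
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals), nCohorts = as.integer(nCohorts),
      nVariants = m, eaf = as.numeric(eaf),
      betaExposure = as.numeric(betaExposure),
      causalEffect = as.numeric(causalEffect), pleiotropyMode = pleiotropyMode,
      alpha = as.numeric(alpha), confExposure = as.numeric(confExposure),
      confOutcome = as.numeric(confOutcome),
      baselineHazard = as.numeric(baselineHazard),
      censoringMax = as.numeric(censoringMax), noiseSd = as.numeric(noiseSd),
      ageEffect = as.numeric(ageEffect), sexEffect = as.numeric(sexEffect),
      fibrinogenMean = as.numeric(fibrinogenMean),
      nExposureGwas = as.numeric(nExposureGwas),
      nOutcomeGwas = as.numeric(nOutcomeGwas), seed = as.integer(seed))
}

variantNames <- function(m) sprintf("var%03d", seq_len(m))

#' Simulate one cohort of individual-level data
#'
#' Dosages are drawn per variant as Binomial(2, freq) under Hardy-Weinberg
#' equilibrium. Fibrinogen is the sum of an intercept, the per-allele
#' genetic effects, a latent standard-normal confounder, small age and sex
#' terms, and Gaussian noise. Event times follow an exponential
#' proportional-hazards model whose log hazard is the causal effect times
#' fibrinogen plus the confounder and any direct (pleiotropic) variant
#' effects, administratively censored at `censoringMax`. Output is
#' deterministic given (config, cohortIndex).
#'
#' @param config a [SimConfig-class].
#' @param cohortIndex 1-based cohort counter; selects the per-cohort
#'   random stream.
#' @param censorType "right" (default) or "interval"; interval censoring
#'   places each event between successive biennial examinations, as in a
#'   cohort followed by repeated exams rather than continuous surveillance.
#' @return a [CohortData-class].
#' @examples
#' coh <- simulateCohort(simConfig(nIndividuals = 200, nVariants = 5, seed = 1), 1)
#' coh
#' @export
simulateCohort <- function(config, cohortIndex, censorType = c("right", "interval")) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  censorType <- match.arg(censorType)
  stopifnotScalar(cohortIndex, "cohortIndex")
  n <- config@nIndividuals
  m <- config@nVariants
  withSeed(deriveSeed(config@seed, as.integer(cohortIndex)), {
    G <- vapply(config@eaf, function(p) rbinom(n, 2L, p), numeric(n))
    if (n == 1L) G <- matrix(G, nrow = 1L)
    colnames(G) <- variantNames(m)
    U <- rnorm(n)
    age <- rnorm(n, 55, 10)
    sex <- rbinom(n, 1L, 0.5)
    intercept <- config@fibrinogenMean - sum(config@betaExposure * 2 * config@eaf)
    fib <- intercept + drop(G %*% config@betaExposure) +
      config@confExposure * U + config@ageEffect * (age - 55) +
      config@sexEffect * sex + rnorm(n, 0, config@noiseSd)
    # risk factors: BMI shares the latent confounder, the rest are noise
    bmi <- 27 + 2 * U + rnorm(n, 0, 4)
    ldl <- rnorm(n, 130, 38)
    hdl <- rnorm(n, 52, 16)
    hypertension <- rbinom(n, 1L, 0.3)
    diabetes <- rbinom(n, 1L, 0.12)
    smoking <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.30, 0.25))
    rate <- config@baselineHazard *
      exp(config@causalEffect * fib + config@confOutcome * U +
            drop(G %*% config@alpha))
    tEvent <- rexp(n, rate)
    cmax <- config@censoringMax
    event <- as.integer(tEvent <= cmax)
    time <- pmin(tEvent, cmax)
    outc <- if (censorType == "right") {
      data.frame(time = time, event = event)
    } else {
      # biennial examination schedule; event located in (last exam, next exam]
      right <- ifelse(event == 1L, pmin(2 * ceiling(tEvent / 2), cmax), Inf)
      left <- ifelse(event == 1L, pmax(right - 2, 0), cmax)
      left <- pmin(left, right - 1e-8)
      data.frame(left = left, right = right)
    }
    new("CohortData",
        label = sprintf("cohort%02d", as.integer(cohortIndex)),
        dosages = G,
        phenotypes = data.frame(age = age, sex = sex, fibrinogen = fib,
                                bmi = bmi, ldl = ldl, hdl = hdl,
                                hypertension = hypertension,
                                diabetes = diabetes, smoking = smoking),
        outcomes = outc, censorType = censorType)
  })
}

#' Construct harmonized summary statistics directly
#'
#' @param variantId,effectAllele,otherAllele,eaf,betaExposure,seExposure,betaOutcome,seOutcome
#'   per-variant vectors; see [MRSummaryData-class].
#' @return an [MRSummaryData-class].
#' @export
mrSummaryData <- function(variantId, effectAllele, otherAllele, eaf,
                          betaExposure, seExposure, betaOutcome, seOutcome) {
  new("MRSummaryData", variantId = as.character(variantId),
      effectAllele = as.character(effectAllele),
      otherAllele = as.character(otherAllele), eaf = as.numeric(eaf),
      betaExposure = as.numeric(betaExposure),
      seExposure = as.numeric(seExposure),
      betaOutcome = as.numeric(betaOutcome),
      seOutcome = as.numeric(seOutcome))
}

#' Simulate two-sample GWAS summary statistics
#'
#' Exposure estimates are drawn around the true per-allele fibrinogen
#' effects and outcome estimates around (causal effect x variant effect +
#' direct pleiotropic effect), with standard errors from the standard GWAS
#' approximation for a standardized trait, se = 1/sqrt(2 p (1-p) n).
#' Deterministic given the config seed.
#'
#' @param config a [SimConfig-class].
#' @return an [MRSummaryData-class] with one row per variant.
#' @examples
#' ss <- simulateSummaryStats(simConfig(nVariants = 10, seed = 3))
#' ss
#' @export
simulateSummaryStats <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  m <- config@nVariants
  p <- config@eaf
  seExp <- 1 / sqrt(2 * p * (1 - p) * config@nExposureGwas)
  seOut <- 1 / sqrt(2 * p * (1 - p) * config@nOutcomeGwas)
  withSeed(deriveSeed(config@seed, 7777L), {
    betaHat <- rnorm(m, config@betaExposure, seExp)
    gammaHat <- rnorm(m, config@causalEffect * config@betaExposure + config@alpha,
                      seOut)
    mrSummaryData(variantNames(m), rep("A", m), rep("G", m), p,
                  betaHat, seExp, gammaHat, seOut)
  })
}

# Population Spearman attenuation of a Hardy-Weinberg trinomial dosage
# against a continuous trait under a Gaussian copula, estimated once by
# Monte Carlo; the rank correlation is close to linear in the latent
# Pearson correlation, so a single slope calibrates the copula.
spearmanSlope <- function(p, seed) {
  withSeed(seed, {
    z1 <- rnorm(60000)
    z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(60000)
    d <- cut(pnorm(z1), c(-Inf, (1 - p)^2, (1 - p)^2 + 2 * p * (1 - p), Inf),
             labels = FALSE) - 1
    cor(d, z2, method = "spearman") / 0.5
  })
}

#' Simulate a cohort with one risk-factor-correlated variant
#'
#' Returns a cohort in which the first variant's dosage has population
#' Spearman correlation approximately `targetRho` with BMI, generated
#' through a Gaussian copula (latent bivariate normal, dosage obtained by
#' Hardy-Weinberg thresholding, BMI as a monotone transform). Used to
#' exercise the risk-factor correlation filter.
#'
#' @param config a [SimConfig-class].
#' @param targetRho desired Spearman correlation, |targetRho| < 1.
#' @param cohortIndex cohort counter as in [simulateCohort()].
#' @return a [CohortData-class].
#' @export
simulateCorrelatedVariant <- function(config, targetRho, cohortIndex = 1L) {
  stopifnot(is(config, "SimConfig"))
  stopifnotScalar(targetRho, "targetRho")
  if (abs(targetRho) >= 1) stop("|targetRho| must be < 1")
  coh <- simulateCohort(config, cohortIndex)
  p <- config@eaf[1L]
  slope <- spearmanSlope(p, deriveSeed(config@seed, 8888L))
  rLatent <- max(-0.999, min(0.999, targetRho / slope))
  n <- config@nIndividuals
  withSeed(deriveSeed(config@seed, 8000L + as.integer(cohortIndex)), {
    z1 <- rnorm(n)
    z2 <- rLatent * z1 + sqrt(1 - rLatent^2) * rnorm(n)
    d <- cut(pnorm(z1), c(-Inf, (1 - p)^2, (1 - p)^2 + 2 * p * (1 - p), Inf),
             labels = FALSE) - 1
    dos <- coh@dosages
    dos[, 1L] <- d
    phe <- coh@phenotypes
    phe$bmi <- 27 + 4 * z2   # monotone in the latent scale: rank-preserving
    new("CohortData", label = coh@label, dosages = dos, phenotypes = phe,
        outcomes = coh@outcomes, censorType = coh@censorType)
  })
}
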