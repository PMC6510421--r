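#' @import methods
#' @importFrom stats coef cor lm glm binomial pnorm qnorm rnorm rbinom rexp
#'   sd mad median optimize pchisq quantile var fitted residuals setNames
#'   complete.cases na.exclude dnorm
#' @importFrom utils read.delim write.table head
NULL

#' Simulation configuration with known causal truth
#'
#' Holds every generative parameter for the synthetic multi-cohort study:
#' variant effects on fibrinogen, the causal effect of fibrinogen on the
#' outcome, horizontal-pleiotropy effects, confounding, and the survival
#' model. Construct with [simConfig()].
#'
#' @slot nIndividuals individuals per cohort.
#' @slot nCohorts number of cohorts.
#' @slot nVariants number of instrument variants M.
#' @slot eaf effect-allele frequencies, length M, each in (0,1).
#' @slot betaExposure per-allele effects on fibrinogen (g/L), length M.
#' @slot causalEffect causal effect of fibrinogen on the outcome: log-hazard
#'   (one-sample) or log-odds (two-sample) per 1 g/L.
#' @slot pleiotropyMode one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"outliers"}.
#' @slot alpha direct variant-to-outcome effects, length M.
#' @slot confExposure effect of the latent confounder on fibrinogen (g/L per SD).
#' @slot confOutcome effect of the latent confounder on the log hazard.
#' @slot baselineHazard baseline event rate (events per person-year).
#' @slot censoringMax administrative censoring time (years).
#' @slot noiseSd residual SD of fibrinogen (g/L).
#' @slot ageEffect,sexEffect fibrinogen shift per year of age (centred at 55)
#'   and for male sex.
#' @slot fibrinogenMean target population mean fibrinogen (g/L).
#' @slot nExposureGwas,nOutcomeGwas effective sample sizes behind the
#'   two-sample summary statistics.
#' @slot seed master seed; all randomness derives from it.
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer", nCohorts = "integer", nVariants = "integer",
  eaf = "numeric", betaExposure = "numeric", causalEffect = "numeric",
  pleiotropyMode = "character", alpha = "numeric",
  confExposure = "numeric", confOutcome = "numeric",
  baselineHazard = "numeric", censoringMax = "numeric", noiseSd = "numeric",
  ageEffect = "numeric", sexEffect = "numeric", fibrinogenMean = "numeric",
  nExposureGwas = "numeric", nOutcomeGwas = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  m <- object@nVariants
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nCohorts < 1L) msg <- c(msg, "nCohorts must be >= 1")
  if (m < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (length(object@eaf) != m || any(!is.finite(object@eaf)) ||
      any(object@eaf <= 0) || any(object@eaf >= 1))
    msg <- c(msg, "eaf must be length M with every value strictly inside (0,1)")
  if (length(object@betaExposure) != m || any(!is.finite(object@betaExposure)))
    msg <- c(msg, "betaExposure must be length M and finite")
  if (length(object@alpha) != m || any(!is.finite(object@alpha)))
    msg <- c(msg, "alpha must be length M and finite")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional", "outliers"))
    msg <- c(msg, "unknown pleiotropyMode")
  if (object@pleiotropyMode == "none" && any(object@alpha != 0))
    msg <- c(msg, "pleiotropyMode 'none' requires all alpha = 0")
  for (nm in c("causalEffect", "confExposure", "confOutcome", "ageEffect",
               "sexEffect", "fibrinogenMean"))
    if (!is.finite(slot(object, nm))) msg <- c(msg, paste(nm, "must be finite"))
  if (!is.finite(object@baselineHazard) || object@baselineHazard <= 0)
    msg <- c(msg, "baselineHazard must be > 0")
  if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (!is.finite(object@censoringMax) || object@censoringMax <= 0)
    msg <- c(msg, "censoringMax must be > 0")
  if (object@nExposureGwas <= 1 || object@nOutcomeGwas <= 1)
    msg <- c(msg, "GWAS sample sizes must exceed 1")
  if (length(msg)) msg else TRUE
})

#' One cohort's individual-level data
#'
#' Genotype dosages, phenotypes (fibrinogen plus cardiovascular risk
#' factors), and survival outcomes for one simulated or imported cohort.
#'
#' @slot label cohort label, unique within a study.
#' @slot dosages numeric matrix, individuals x variants, values in [0,2]
#'   (NA allowed); column names are variant ids.
#' @slot phenotypes data.frame with columns age (years), sex (1 = male),
#'   fibrinogen (g/L), bmi, ldl, hdl, hypertension (0/1), diabetes (0/1),
#'   smoking (0 never < 1 former < 2 current).
#' @slot outcomes data.frame; for right censoring columns time (years) and
#'   event (0/1); for interval censoring columns left and right with the
#'   event known to lie in (left, right], right = Inf when censored.
#' @slot censorType \code{"right"} or \code{"interval"}.
#' @export
setClass("CohortData", representation(
  label = "character", dosages = "matrix", phenotypes = "data.frame",
  outcomes = "data.frame", censorType = "character"))

setValidity("CohortData", function(object) {
  msg <- character(0)
  n <- nrow(object@dosages)
  if (n < 1L) msg <- c(msg, "cohort must contain at least one individual")
  d <- object@dosages
  if (any(d < 0 | d > 2, na.rm = TRUE)) msg <- c(msg, "dosages must lie in [0,2]")
  if (is.null(colnames(d))) msg <- c(msg, "dosage columns must be named by variant id")
  if (nrow(object@phenotypes) != n || nrow(object@outcomes) != n)
    msg <- c(msg, "phenotypes/outcomes must have one row per individual")
  if (!object@censorType %in% c("right", "interval"))
    msg <- c(msg, "censorType must be 'right' or 'interval'")
  if (object@censorType == "right") {
    if (!all(c("time", "event") %in% names(object@outcomes)))
      msg <- c(msg, "right-censored outcomes need columns time, event")
    else if (any(object@outcomes$time < 0, na.rm = TRUE))
      msg <- c(msg, "follow-up time must be >= 0")
  } else {
    if (!all(c("left", "right") %in% names(object@outcomes)))
      msg <- c(msg, "interval-censored outcomes need columns left, right")
    else if (any(object@outcomes$left >= object@outcomes$right, na.rm = TRUE))
      msg <- c(msg, "interval bounds must satisfy left < right")
  }
  if (length(msg)) msg else TRUE
})

#' Harmonized two-sample summary statistics
#'
#' Per-variant exposure (fibrinogen, g/L per allele) and outcome (log-odds
#' per allele) associations on a common effect allele, the input to every
#' two-sample estimator. Construct with [mrSummaryData()] or
#' [harmonizeSummaryStats()].
#'
#' @slot variantId,effectAllele,otherAllele character vectors.
#' @slot eaf effect-allele frequency.
#' @slot betaExposure,seExposure exposure association and its SE.
#' @slot betaOutcome,seOutcome outcome association and its SE.
#' @export
setClass("MRSummaryData", representation(
  variantId = "character", effectAllele = "character", otherAllele = "character",
  eaf = "numeric", betaExposure = "numeric", seExposure = "numeric",
  betaOutcome = "numeric", seOutcome = "numeric"))

setValidity("MRSummaryData", function(object) {
  msg <- character(0)
  k <- length(object@variantId)
  lens <- c(length(object@effectAllele), length(object@otherAllele),
            length(object@eaf), length(object@betaExposure),
            length(object@seExposure), length(object@betaOutcome),
            length(object@seOutcome))
  if (any(lens != k)) msg <- c(msg, "all slots must have equal length")
  if (anyDuplicated(object@variantId)) msg <- c(msg, "duplicate variant ids")
  if (any(object@seExposure <= 0) || any(object@seOutcome <= 0))
    msg <- c(msg, "standard errors must be > 0")
  if (any(object@effectAllele == object@otherAllele))
    msg <- c(msg, "effect and other allele must differ")
  if (length(msg)) msg else TRUE
})

#' One causal-effect estimate from a two-sample method
#'
#' @slot mrMethod one of wald, ivw, egger, weighted_median, mbe, presso.
#' @slot estimate log odds ratio per 1 g/L fibrinogen.
#' @slot se standard error of the estimate.
#' @slot ciLower,ciUpper 95% confidence limits (log scale).
#' @slot pvalue two-sided normal-approximation P.
#' @slot nVariants number of variants used.
#' @slot extras method-specific diagnostics (Egger intercept, MBE bandwidth,
#'   PRESSO global P and outlier list, heterogeneity Q, ...).
#' @export
setClass("MREstimate", representation(
  mrMethod = "character", estimate = "numeric", se = "numeric",
  ciLower = "numeric", ciUpper = "numeric", pvalue = "numeric",
  nVariants = "integer", extras = "list"))

setValidity("MREstimate", function(object) {
  msg <- character(0)
  if (length(object@estimate) != 1L) msg <- c(msg, "estimate must be scalar")
  if (is.finite(object@ciLower) && is.finite(object@ciUpper) &&
      object@ciLower > object@ciUpper)
    msg <- c(msg, "CI endpoints out of order")
  if (length(msg)) msg else TRUE
})

#' Two-stage Cox (or interval-censored exponential) result
#'
#' @slot stage1Coef,stage1Se first-stage regression of fibrinogen residuals
#'   on the instrument (g/L per instrument unit).
#' @slot stage1F weak-instrument F statistic, (coef/se)^2.
#' @slot logHr stage-2 log hazard ratio per 1 g/L fibrinogen.
#' @slot se stage-2 standard error (naive model-based, or bootstrap).
#' @slot hazardRatio exp(logHr).
#' @slot ciLower,ciUpper 95% CI on the HR scale.
#' @slot pvalue two-sided normal-approximation P.
#' @slot n,nEvents analysed individuals and events.
#' @slot model fitting engine: "coxph" or "exponential-aft".
#' @export
setClass("TwoStageResult", representation(
  stage1Coef = "numeric", stage1Se = "numeric", stage1F = "numeric",
  logHr = "numeric", se = "numeric", hazardRatio = "numeric",
  ciLower = "numeric", ciUpper = "numeric", pvalue = "numeric",
  n = "integer", nEvents = "integer", model = "character"))

setValidity("TwoStageResult", function(object) {
  msg <- character(0)
  if (object@nEvents > object@n) msg <- c(msg, "nEvents cannot exceed n")
  if (is.finite(object@logHr) &&
      abs(object@hazardRatio - exp(object@logHr)) > 1e-8 * max(1, object@hazardRatio))
    msg <- c(msg, "hazardRatio must equal exp(logHr)")
  if (length(msg)) msg else TRUE
})

#' Pooled meta-analysis result
#'
#' @slot estimate pooled log-HR or log-OR.
#' @slot se pooled standard error; for fixed effects 1/sqrt(sum 1/se_i^2).
#' @slot ciLower,ciUpper 95% CI (log scale).
#' @slot pvalue two-sided normal-approximation P.
#' @slot Q Cochran's heterogeneity statistic.
#' @slot pQ upper-tail chi-square P with k-1 df.
#' @slot tau2 between-study variance (0 for fixed effects).
#' @slot k number of studies.
#' @slot weights normalized per-study weights.
#' @slot model "FE" or "DL".
#' @export
setClass("MetaResult", representation(
  estimate = "numeric", se = "numeric", ciLower = "numeric", ciUpper = "numeric",
  pvalue = "numeric", Q = "numeric", pQ = "numeric", tau2 = "numeric",
  k = "integer", weights = "numeric", model = "character"))

setValidity("MetaResult", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (is.finite(object@Q) && object@Q < -1e-12) msg <- c(msg, "Q must be >= 0")
  if (is.finite(object@pQ) && (object@pQ <= 0 || object@pQ > 1))
    msg <- c(msg, "pQ must lie in (0,1]")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-individual allele score
#'
#' Unweighted (default) sum of aligned effect-allele dosages over retained
#' instrument variants; optionally rescaled within cohort so that one unit
#' is half the observed score range.
#'
#' @slot scores per-individual scores.
#' @slot variantIds ordered ids of the variants summed.
#' @slot weighted TRUE when per-variant effect weights were applied.
#' @slot rescaled TRUE after [rescaleScore()].
#' @slot divisor rescale divisor ((max - min)/2), 1 when not rescaled.
#' @export
setClass("AlleleScore", representation(
  scores = "numeric", variantIds = "character", weighted = "logical",
  rescaled = "logical", divisor = "numeric"))

setValidity("AlleleScore", function(object) {
  msg <- character(0)
  if (!length(object@variantIds)) msg <- c(msg, "empty variant set")
  if (!object@weighted && !object@rescaled) {
    ub <- 2 * length(object@variantIds)
    if (any(object@scores < -1e-9 | object@scores > ub + 1e-9, na.rm = TRUE))
      msg <- c(msg, "scores must lie in [0, 2 x number of variants]")
  }
  if (object@divisor <= 0) msg <- c(msg, "divisor must be > 0")
  if (length(msg)) msg else TRUE
})
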