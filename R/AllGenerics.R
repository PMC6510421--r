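# Accessor generics and show methods. Slots are never accessed directly by
# user code; these are the supported surface.

#' Point estimate of a fitted result
#' @param object a fitted result object.
#' @return numeric scalar (log scale for hazard/odds ratios).
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' Standard error of a fitted result
#' @param object a fitted result object.
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' 95% confidence interval
#' @param object a fitted result object.
#' @return numeric length-2 vector (lower, upper). For [TwoStageResult-class]
#'   the interval is on the hazard-ratio scale; otherwise on the log scale.
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' Two-sided P-value
#' @param object a fitted result object.
#' @export
setGeneric("pvalue", function(object) standardGeneric("pvalue"))

#' Method label of a two-sample estimate
#' @param object an [MREstimate-class].
#' @export
setGeneric("mrMethod", function(object) standardGeneric("mrMethod"))

#' Per-individual scores of an allele score
#' @param object an [AlleleScore-class].
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' Variant ids contributing to an object
#' @param object an [AlleleScore-class] or [MRSummaryData-class].
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))

#' Dosage matrix of a cohort
#' @param object a [CohortData-class].
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' Phenotype table of a cohort
#' @param object a [CohortData-class].
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' Outcome table of a cohort
#' @param object a [CohortData-class].
#' @export
setGeneric("outcomes", function(object) standardGeneric("outcomes"))

#' Cohort label
#' @param object a [CohortData-class].
#' @export
setGeneric("cohortLabel", function(object) standardGeneric("cohortLabel"))

#' @describeIn estimate stage-2 log hazard ratio
#' @export
setMethod("estimate", "TwoStageResult", function(object) object@logHr)
#' @describeIn estimate pooled log effect
#' @export
setMethod("estimate", "MetaResult", function(object) object@estimate)
#' @describeIn estimate causal log odds ratio
#' @export
setMethod("estimate", "MREstimate", function(object) object@estimate)

#' @describeIn stdError stage-2 SE
#' @export
setMethod("stdError", "TwoStageResult", function(object) object@se)
#' @describeIn stdError pooled SE
#' @export
setMethod("stdError", "MetaResult", function(object) object@se)
#' @describeIn stdError SE of the causal estimate
#' @export
setMethod("stdError", "MREstimate", function(object) object@se)

#' @describeIn confInt on the hazard-ratio scale
#' @export
setMethod("confInt", "TwoStageResult", function(object)
  c(object@ciLower, object@ciUpper))
#' @describeIn confInt on the log scale
#' @export
setMethod("confInt", "MetaResult", function(object)
  c(object@ciLower, object@ciUpper))
#' @describeIn confInt on the log scale
#' @export
setMethod("confInt", "MREstimate", function(object)
  c(object@ciLower, object@ciUpper))

#' @describeIn pvalue two-sided P
#' @export
setMethod("pvalue", "TwoStageResult", function(object) object@pvalue)
#' @describeIn pvalue two-sided P
#' @export
setMethod("pvalue", "MetaResult", function(object) object@pvalue)
#' @describeIn pvalue two-sided P
#' @export
setMethod("pvalue", "MREstimate", function(object) object@pvalue)

#' @describeIn mrMethod method label
#' @export
setMethod("mrMethod", "MREstimate", function(object) object@mrMethod)

#' @describeIn scores per-individual score vector
#' @export
setMethod("scores", "AlleleScore", function(object) object@scores)

#' @describeIn variantIds variants summed into the score
#' @export
setMethod("variantIds", "AlleleScore", function(object) object@variantIds)
#' @describeIn variantIds harmonized variants
#' @export
setMethod("variantIds", "MRSummaryData", function(object) object@variantId)

#' @describeIn dosages individuals x variants matrix
#' @export
setMethod("dosages", "CohortData", function(object) object@dosages)
#' @describeIn phenotypes phenotype data.frame
#' @export
setMethod("phenotypes", "CohortData", function(object) object@phenotypes)
#' @describeIn outcomes outcome data.frame
#' @export
setMethod("outcomes", "CohortData", function(object) object@outcomes)
#' @describeIn cohortLabel cohort label string
#' @export
setMethod("cohortLabel", "CohortData", function(object) object@label)

#' Coerce harmonized summary statistics to a data.frame
#'
#' @param x an [MRSummaryData-class].
#' @param ... ignored.
#' @return data.frame with one row per variant.
#' @export
setMethod("as.data.frame", "MRSummaryData", function(x, ...) {
  data.frame(variantId = x@variantId, effectAllele = x@effectAllele,
             otherAllele = x@otherAllele, eaf = x@eaf,
             betaExposure = x@betaExposure, seExposure = x@seExposure,
             betaOutcome = x@betaOutcome, seOutcome = x@seOutcome,
             stringsAsFactors = FALSE)
})

#' Number of variants in a summary-statistics set
#' @param x an [MRSummaryData-class].
#' @export
setMethod("length", "MRSummaryData", function(x) length(x@variantId))

#' Subset harmonized summary statistics by position or variant id
#' @param x an [MRSummaryData-class].
#' @param i integer, logical or character index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MRSummaryData", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@variantId)
  new("MRSummaryData", variantId = x@variantId[i],
      effectAllele = x@effectAllele[i], otherAllele = x@otherAllele[i],
      eaf = x@eaf[i], betaExposure = x@betaExposure[i],
      seExposure = x@seExposure[i], betaOutcome = x@betaOutcome[i],
      seOutcome = x@seOutcome[i])
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d cohorts x %d individuals, %d variants\n",
              object@nCohorts, object@nIndividuals, object@nVariants))
  cat(sprintf("  causal effect %.3g per g/L; pleiotropy: %s\n",
              object@causalEffect, object@pleiotropyMode))
  cat(sprintf("  confounding (exposure %.3g, outcome %.3g); baseline hazard %.3g/py\n",
              object@confExposure, object@confOutcome, object@baselineHazard))
  cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "CohortData", function(object) {
  cat(sprintf("CohortData '%s': %d individuals, %d variants, %s-censored\n",
              object@label, nrow(object@dosages), ncol(object@dosages),
              object@censorType))
  ev <- if (object@censorType == "right") sum(object@outcomes$event)
        else sum(is.finite(object@outcomes$right))
  cat(sprintf("  %d events; mean fibrinogen %.2f g/L\n",
              ev, mean(object@phenotypes$fibrinogen, na.rm = TRUE)))
})

setMethod("show", "MRSummaryData", function(object) {
  cat(sprintf("MRSummaryData: %d harmonized variants\n", length(object@variantId)))
  if (length(object@variantId))
    print(head(as.data.frame(object), 4L), row.names = FALSE)
  if (length(object@variantId) > 4L) cat("  ...\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MR estimate [%s], %d variants\n", object@mrMethod, object@nVariants))
  cat(sprintf("  log OR %.4f (SE %.4f); OR %.3f (95%% CI %.3f-%.3f); P = %.3g\n",
              object@estimate, object@se, exp(object@estimate),
              exp(object@ciLower), exp(object@ciUpper), object@pvalue))
  if (!is.null(object@extras$eggerIntercept))
    cat(sprintf("  Egger intercept %.4f (SE %.4f)\n",
                object@extras$eggerIntercept, object@extras$eggerInterceptSe))
  if (!is.null(object@extras$outlierIds))
    cat(sprintf("  PRESSO global P %.3g; outliers: %s\n",
                object@extras$globalP,
                if (length(object@extras$outlierIds))
                  paste(object@extras$outlierIds, collapse = ", ") else "none"))
})

setMethod("show", "TwoStageResult", function(object) {
  cat(sprintf("Two-stage %s fit: n = %d, events = %d\n",
              object@model, object@n, object@nEvents))
  cat(sprintf("  stage 1: %.4f (SE %.4f), F = %.1f\n",
              object@stage1Coef, object@stage1Se, object@stage1F))
  cat(sprintf("  HR per 1 g/L: %.3f (95%% CI %.3f-%.3f); P = %.3g\n",
              object@hazardRatio, object@ciLower, object@ciUpper, object@pvalue))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("%s meta-analysis of %d studies\n",
              if (object@model == "FE") "Fixed-effects" else "Random-effects (DL)",
              object@k))
  cat(sprintf("  pooled %.4f (SE %.4f, 95%% CI %.4f to %.4f); P = %.3g\n",
              object@estimate, object@se, object@ciLower, object@ciUpper,
              object@pvalue))
  cat(sprintf("  Q = %.3f, P(Q) = %.3g, tau2 = %.4g\n",
              object@Q, object@pQ, object@tau2))
})

setMethod("show", "AlleleScore", function(object) {
  cat(sprintf("AlleleScore over %d variants (%s%s)\n",
              length(object@variantIds),
              if (object@weighted) "weighted" else "unweighted",
              if (object@rescaled) sprintf(", rescaled by %.3g", object@divisor) else ""))
  cat(sprintf("  %d individuals; range %.2f-%.2f\n", length(object@scores),
              min(object@scores), max(object@scores)))
})
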