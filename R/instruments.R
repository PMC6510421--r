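#' Create a variant panel for allele-score construction
#'
#' The panel is a plain data.frame, one row per candidate instrument, with
#' QC flag columns that the four filters switch on. A variant contributes to
#' the allele score only while every flag is FALSE.
#'
#' @param df data.frame with at least columns `variantId`, `effectAllele`,
#'   `otherAllele`, `beta` (published fibrinogen effect, g/L per effect
#'   allele) and `se`; optionally `chr`, `pos`, `sourceStudy`, `sourceRank`
#'   (1 = largest genome-wide scan).
#' @return the panel with logical columns `flagLowImputation`,
#'   `flagRfCorrelated`, `flagChdLd`, `flagLdPruned`, `flagMissing` added
#'   (all FALSE).
#' @examples
#' pan <- newVariantPanel(data.frame(
#'   variantId = c("rs1", "rs2"), effectAllele = c("A", "C"),
#'   otherAllele = c("G", "T"), beta = c(0.04, -0.02), se = c(0.005, 0.006)))
#' retainedVariants(pan)
#' @export
newVariantPanel <- function(df) {
  need <- c("variantId", "effectAllele", "otherAllele", "beta", "se")
  if (!all(need %in% names(df)))
    stop("panel needs columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$variantId)) stop("duplicate variant ids in panel")
  if (any(df$se <= 0)) stop("published SEs must be > 0")
  if (any(df$effectAllele == df$otherAllele))
    stop("effect and other allele must differ")
  if (is.null(df$sourceRank)) df$sourceRank <- 1L
  for (fl in c("flagLowImputation", "flagRfCorrelated", "flagChdLd",
               "flagLdPruned", "flagMissing"))
    if (is.null(df[[fl]])) df[[fl]] <- FALSE
  df
}

#' Variants retained by all QC filters
#'
#' @param panel a variant panel from [newVariantPanel()].
#' @return character vector of retained variant ids.
#' @export
retainedVariants <- function(panel) {
  fl <- panel[, c("flagLowImputation", "flagRfCorrelated", "flagChdLd",
                  "flagLdPruned", "flagMissing")]
  panel$variantId[rowSums(as.matrix(fl)) == 0]
}

#' Flag variants with low imputation quality
#'
#' A variant is flagged when its imputation quality is below the
#' method-specific cutoff: quality < 0.3 for MACH, quality < 0.4 for
#' IMPUTE. Both comparisons are strict. A variant with several quality
#' records (e.g. one per cohort) is flagged if any record fails.
#'
#' @param panel a variant panel.
#' @param qualityTable data.frame with columns `variantId`, `method`
#'   ("MACH" or "IMPUTE") and `quality` in [0,1].
#' @return the panel with `flagLowImputation` updated.
#' @export
filterImputationQuality <- function(panel, qualityTable) {
  stopifnot(all(c("variantId", "method", "quality") %in% names(qualityTable)))
  bad <- !qualityTable$method %in% c("MACH", "IMPUTE")
  if (any(bad))
    stop("unknown imputation method tag: ",
         paste(unique(qualityTable$method[bad]), collapse = ", "))
  cutoff <- ifelse(qualityTable$method == "MACH", 0.3, 0.4)
  failed <- unique(qualityTable$variantId[qualityTable$quality < cutoff])
  panel$flagLowImputation <- panel$flagLowImputation |
    panel$variantId %in% failed
  panel
}

riskFactorColumns <- c("bmi", "ldl", "hdl", "diabetes", "hypertension", "smoking")

#' Flag variants correlated with cardiovascular risk factors
#'
#' For each variant, the Spearman correlation against each of six risk
#' factors (BMI, LDL, HDL, type-2 diabetes, hypertension, smoking) is
#' computed in every cohort; a variant is flagged when |rho| > 0.10 for any
#' (cohort, trait) pair (strict inequality). Binary traits use 0/1 coding
#' and smoking the ordinal coding never(0) < former(1) < current(2).
#' A trait that is constant within a cohort is skipped with a warning.
#'
#' @param panel a variant panel.
#' @param cohorts list of [CohortData-class].
#' @param threshold correlation cutoff (default 0.10).
#' @return the panel with `flagRfCorrelated` updated.
#' @export
filterRiskFactorCorrelation <- function(panel, cohorts, threshold = 0.10) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  failed <- character(0)
  for (coh in cohorts) {
    phe <- phenotypes(coh)
    dos <- dosages(coh)
    ids <- intersect(panel$variantId, colnames(dos))
    for (trait in riskFactorColumns) {
      y <- as.numeric(phe[[trait]])
      if (length(unique(y[!is.na(y)])) < 2L) {
        warning(sprintf("trait '%s' constant in cohort '%s'; pair skipped",
                        trait, cohortLabel(coh)))
        next
      }
      rho <- suppressWarnings(
        cor(dos[, ids, drop = FALSE], y, method = "spearman",
            use = "pairwise.complete.obs"))
      failed <- c(failed, ids[!is.na(rho) & abs(rho) > threshold])
    }
  }
  panel$flagRfCorrelated <- panel$flagRfCorrelated |
    panel$variantId %in% unique(failed)
  panel
}

#' Flag variants in linkage disequilibrium with known CHD loci
#'
#' A variant is flagged when its r-squared with any supplied CHD locus
#' exceeds 0.20 (strict inequality). The locus list is a user-supplied
#' input; the package ships a small synthetic fixture for tests.
#'
#' @param panel a variant panel.
#' @param ldToChdLoci data.frame with columns `variantId`, `locus`, `r2`.
#'   An empty table flags nothing.
#' @return the panel with `flagChdLd` updated.
#' @export
filterChdLd <- function(panel, ldToChdLoci) {
  if (nrow(ldToChdLoci) == 0L) return(panel)
  stopifnot(all(c("variantId", "r2") %in% names(ldToChdLoci)))
  if (any(ldToChdLoci$r2 < 0 | ldToChdLoci$r2 > 1))
    stop("r2 values must lie in [0,1]")
  failed <- unique(ldToChdLoci$variantId[ldToChdLoci$r2 > 0.20])
  panel$flagChdLd <- panel$flagChdLd | panel$variantId %in% failed
  panel
}

#' Prune pairs of variants in high mutual linkage disequilibrium
#'
#' Pairs with r-squared > 0.70 (strict) form the edges of a graph; within
#' each connected component exactly one variant is retained -- the one from
#' the highest-ranked source study (smallest `sourceRank`, i.e. the largest
#' genome-wide scan), with ties broken by larger |published beta| and then
#' lexicographic variant id. All other component members are flagged.
#'
#' @param panel a variant panel with a `sourceRank` column.
#' @param pairwiseR2 long-format data.frame with columns `id1`, `id2`, `r2`
#'   (symmetric; each unordered pair may appear once).
#' @return the panel with `flagLdPruned` updated.
#' @export
pruneLdPairs <- function(panel, pairwiseR2) {
  if (nrow(pairwiseR2) == 0L) return(panel)
  stopifnot(all(c("id1", "id2", "r2") %in% names(pairwiseR2)))
  if (any(pairwiseR2$r2 < 0 | pairwiseR2$r2 > 1))
    stop("r2 values must lie in [0,1]")
  ed <- pairwiseR2[pairwiseR2$r2 > 0.70 &
                     pairwiseR2$id1 %in% panel$variantId &
                     pairwiseR2$id2 %in% panel$variantId, , drop = FALSE]
  if (nrow(ed) == 0L) return(panel)
  g <- igraph::graph_from_data_frame(ed[, c("id1", "id2")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  drop <- character(0)
  for (ids in membership) {
    sub <- panel[match(ids, panel$variantId), , drop = FALSE]
    ord <- order(sub$sourceRank, -abs(sub$beta), sub$variantId)
    drop <- c(drop, sub$variantId[ord[-1L]])
  }
  panel$flagLdPruned <- panel$flagLdPruned | panel$variantId %in% drop
  panel
}

#' Flag variants missing from any cohort of a set
#'
#' A variant is flagged when its dosage column is absent from any cohort in
#' the given set. Applying the filter with the discovery set and then again
#' with the replication set yields the nested replication score.
#'
#' @param panel a variant panel.
#' @param cohorts list of [CohortData-class] (one arm of the study).
#' @return the panel with `flagMissing` updated.
#' @export
filterMissingness <- function(panel, cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  present <- lapply(cohorts, function(coh) colnames(dosages(coh)))
  missing <- vapply(panel$variantId,
                    function(id) any(!vapply(present, function(p) id %in% p,
                                             logical(1))),
                    logical(1))
  panel$flagMissing <- panel$flagMissing | missing
  panel
}

#' Align dosages so the effect allele raises fibrinogen
#'
#' For every variant whose published fibrinogen effect is negative, the
#' dosage is reflected (d becomes 2 - d), the allele labels are swapped and
#' the published beta is negated, so that after alignment every per-allele
#' effect is positive. Alignment is an involution: applying it twice
#' restores the original dosages.
#'
#' @param panel a variant panel.
#' @param dos dosage matrix with columns named by variant id (e.g.
#'   `dosages(cohort)`).
#' @return list with elements `panel` (aligned) and `dosages` (aligned
#'   matrix, same shape).
#' @export
alignEffectAlleles <- function(panel, dos) {
  if (any(panel$beta == 0))
    stop("published beta of 0: effect-allele direction undefined for ",
         paste(panel$variantId[panel$beta == 0], collapse = ", "))
  flip <- panel$variantId[panel$beta < 0]
  flipCols <- intersect(flip, colnames(dos))
  dos[, flipCols] <- 2 - dos[, flipCols]
  i <- panel$beta < 0
  tmp <- panel$effectAllele[i]
  panel$effectAllele[i] <- panel$otherAllele[i]
  panel$otherAllele[i] <- tmp
  panel$beta[i] <- -panel$beta[i]
  list(panel = panel, dosages = dos)
}

#' Compute the per-individual allele score
#'
#' The score is the unweighted sum of aligned effect-allele dosages over
#' all retained variants. Per-individual missing dosages within an
#' available variant are imputed with twice the within-cohort effect-allele
#' frequency (the column mean of the dosage), preserving the score scale.
#' A beta-weighted variant is available but is not the default.
#'
#' @param dos aligned dosage matrix (see [alignEffectAlleles()]).
#' @param panel aligned variant panel; only retained variants are summed.
#' @param weighted if TRUE, weight each dosage by the published beta.
#' @return an [AlleleScore-class].
#' @export
computeAlleleScore <- function(dos, panel, weighted = FALSE) {
  ids <- retainedVariants(panel)
  if (length(ids) == 0L) stop("no retained variants: empty allele score")
  if (!all(ids %in% colnames(dos)))
    stop("dosages missing for retained variants: ",
         paste(setdiff(ids, colnames(dos)), collapse = ", "))
  d <- dos[, ids, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in seq_along(ids)) d[is.na(d[, j]), j] <- mu[j]
  }
  w <- if (weighted) panel$beta[match(ids, panel$variantId)] else rep(1, length(ids))
  new("AlleleScore", scores = drop(d %*% w), variantIds = ids,
      weighted = weighted, rescaled = FALSE, divisor = 1)
}

#' Rescale an allele score within cohort
#'
#' Divides the scores by half the observed within-cohort range, so that one
#' rescaled unit represents 50% of the range and the rescaled scores span
#' at most 2 units. Degenerate (constant) scores are an error.
#'
#' @param score an [AlleleScore-class].
#' @return the rescaled [AlleleScore-class].
#' @export
rescaleScore <- function(score) {
  stopifnot(is(score, "AlleleScore"))
  rng <- range(scores(score))
  div <- (rng[2L] - rng[1L]) / 2
  if (div <= 0) stop("zero score range: cannot rescale a constant score")
  new("AlleleScore", scores = scores(score) / div,
      variantIds = variantIds(score), weighted = score@weighted,
      rescaled = TRUE, divisor = div)
}

#' Meta-analyzed association of the allele score with CHD risk factors
#'
#' Within each cohort the score is tested against each of the six risk
#' factors: linear regression for the continuous traits (BMI, LDL, HDL),
#' logistic regression for the binary traits (hypertension, type-2
#' diabetes) and ordinal-as-linear regression for smoking. The per-cohort
#' coefficients are pooled by fixed-effects meta-analysis and each pooled P
#' is compared with the Bonferroni cutoff 0.05/6.
#'
#' @param cohorts list of [CohortData-class].
#' @param cohortScores list of [AlleleScore-class], parallel to `cohorts`.
#' @return data.frame with one row per trait (estimate, se, z, p, Q, pQ,
#'   significant) and attributes `threshold` (0.05/6, full precision) and
#'   `thresholdPrinted` (rounded to 3 decimals).
#' @export
scoreRiskFactorCheck <- function(cohorts, cohortScores) {
  stopifnot(length(cohorts) >= 1L, length(cohorts) == length(cohortScores))
  rows <- lapply(riskFactorColumns, function(trait) {
    est <- se <- numeric(0)
    for (i in seq_along(cohorts)) {
      phe <- phenotypes(cohorts[[i]])
      s <- scores(cohortScores[[i]])
      y <- as.numeric(phe[[trait]])
      fit <- if (trait %in% c("hypertension", "diabetes"))
        glm(y ~ s, family = binomial()) else lm(y ~ s)
      sm <- summary(fit)$coefficients
      est <- c(est, sm["s", 1L]); se <- c(se, sm["s", 2L])
    }
    pooled <- fixedEffectsMeta(est, se)
    data.frame(trait = trait, estimate = estimate(pooled),
               se = stdError(pooled), z = estimate(pooled) / stdError(pooled),
               p = pvalue(pooled), Q = pooled@Q, pQ = pooled@pQ)
  })
  out <- do.call(rbind, rows)
  thr <- bonferroniThreshold(6L)
  out$significant <- out$p < thr$threshold
  attr(out, "threshold") <- thr$threshold
  attr(out, "thresholdPrinted") <- thr$printed
  out
}
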