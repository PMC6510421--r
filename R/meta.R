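metaFromRma <- function(fit, weights, model) {
  est <- as.numeric(fit$b)
  se <- fit$se
  new("MetaResult", estimate = est, se = se,
      ciLower = est - Z95 * se, ciUpper = est + Z95 * se,
      pvalue = 2 * pnorm(-abs(est / se)),
      Q = fit$QE, pQ = max(fit$QEp, .Machine$double.xmin),
      tau2 = if (is.null(fit$tau2)) 0 else fit$tau2,
      k = as.integer(fit$k), weights = weights, model = model)
}

checkEstimates <- function(est, se) {
  if (length(est) != length(se)) stop("estimate and se lengths differ")
  if (length(est) == 0L) stop("no estimates to pool")
  if (any(!is.finite(est)) || any(!is.finite(se)) || any(se <= 0))
    stop("estimates must be finite and all standard errors > 0")
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort estimates with weights 1/se^2: the pooled estimate is
#' sum(est/se^2)/sum(1/se^2) with standard error 1/sqrt(sum(1/se^2)), and
#' Cochran's Q = sum(((est - pooled)/se)^2) is referred to a chi-square
#' with k-1 degrees of freedom. Fitted through [metafor::rma.uni()]
#' (method "FE").
#'
#' @param est per-study estimates (log HR or log OR).
#' @param se per-study standard errors, all > 0.
#' @return a [MetaResult-class].
#' @examples
#' fixedEffectsMeta(c(0.5, 0.3), c(0.1, 0.2))
#' @export
fixedEffectsMeta <- function(est, se) {
  checkEstimates(est, se)
  w <- 1 / se^2
  if (length(est) == 1L)
    return(new("MetaResult", estimate = est, se = se,
               ciLower = est - Z95 * se, ciUpper = est + Z95 * se,
               pvalue = 2 * pnorm(-abs(est / se)), Q = 0, pQ = 1, tau2 = 0,
               k = 1L, weights = 1, model = "FE"))
  fit <- metafor::rma.uni(yi = est, sei = se, method = "FE")
  metaFromRma(fit, w / sum(w), "FE")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance tau^2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w))) with w = 1/se^2; studies are then pooled with weights
#' 1/(se^2 + tau^2). Fitted through [metafor::rma.uni()] (method "DL").
#'
#' @inheritParams fixedEffectsMeta
#' @return a [MetaResult-class] with the `tau2` slot filled.
#' @export
randomEffectsMeta <- function(est, se) {
  checkEstimates(est, se)
  if (length(est) < 2L) stop("random-effects pooling needs k >= 2 studies")
  fit <- metafor::rma.uni(yi = est, sei = se, method = "DL")
  w <- 1 / (se^2 + fit$tau2)
  metaFromRma(fit, w / sum(w), "DL")
}

#' Discovery, replication and combined meta-analyses
#'
#' Pools the discovery arm, the replication arm, and the combination of
#' all per-cohort estimates (pooled directly, not as a meta-analysis of
#' the two pooled results -- though for fixed effects the two coincide).
#' Cohort labels must be disjoint across arms. An empty replication arm
#' returns the discovery result as the combined result.
#'
#' @param discovery data.frame with columns `cohort`, `estimate`, `se`.
#' @param replication data.frame with the same columns; may have 0 rows.
#' @return list with elements `discovery`, `replication` (NULL when the
#'   arm is empty) and `combined`, each a [MetaResult-class].
#' @export
combineDiscoveryReplication <- function(discovery, replication = NULL) {
  need <- c("cohort", "estimate", "se")
  stopifnot(all(need %in% names(discovery)))
  if (is.null(replication))
    replication <- discovery[0L, need, drop = FALSE]
  stopifnot(all(need %in% names(replication)))
  if (length(intersect(discovery$cohort, replication$cohort)))
    stop("cohort labels overlap between discovery and replication arms")
  disc <- fixedEffectsMeta(discovery$estimate, discovery$se)
  if (nrow(replication) == 0L)
    return(list(discovery = disc, replication = NULL, combined = disc))
  repl <- fixedEffectsMeta(replication$estimate, replication$se)
  comb <- fixedEffectsMeta(c(discovery$estimate, replication$estimate),
                           c(discovery$se, replication$se))
  list(discovery = disc, replication = repl, combined = comb)
}
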