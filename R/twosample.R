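# Two-sample Mendelian randomization estimators, implemented from first
# principles on harmonized per-variant summary statistics. All estimates
# are log odds ratios per 1 g/L fibrinogen; CIs use the 1.96 normal
# multiplier and P-values the two-sided normal approximation.

newMrEstimate <- function(mrMethod, est, se, k, extras = list()) {
  new("MREstimate", mrMethod = mrMethod, estimate = est, se = se,
      ciLower = est - Z95 * se, ciUpper = est + Z95 * se,
      pvalue = 2 * pnorm(-abs(est / se)), nVariants = as.integer(k),
      extras = extras)
}

isPalindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches the two GWAS tables on variant id and puts both associations on
#' the exposure's effect allele: when the outcome table reports the other
#' allele (labels swapped), the outcome beta's sign is flipped; variants
#' whose allele sets do not match are dropped with a reported count.
#' Palindromic (A/T, C/G) variants are retained by default without
#' allele-frequency inference; set `dropPalindromic = TRUE` to exclude
#' them.
#'
#' @param exposure,outcome data.frames with columns `variantId`,
#'   `effectAllele`, `otherAllele`, `eaf`, `beta`, `se` (per-allele effect
#'   and its SE). Duplicate variant ids are an error.
#' @param dropPalindromic drop A/T and C/G variants.
#' @return an [MRSummaryData-class]; the number of allele-mismatch drops is
#'   attached as attribute `nDropped`.
#' @export
harmonizeSummaryStats <- function(exposure, outcome, dropPalindromic = FALSE) {
  need <- c("variantId", "effectAllele", "otherAllele", "eaf", "beta", "se")
  stopifnot(all(need %in% names(exposure)), all(need %in% names(outcome)))
  if (anyDuplicated(exposure$variantId) || anyDuplicated(outcome$variantId))
    stop("duplicate variant ids in summary-statistics table")
  common <- intersect(exposure$variantId, outcome$variantId)
  ex <- exposure[match(common, exposure$variantId), ]
  ou <- outcome[match(common, outcome$variantId), ]
  same <- ou$effectAllele == ex$effectAllele & ou$otherAllele == ex$otherAllele
  swap <- ou$effectAllele == ex$otherAllele & ou$otherAllele == ex$effectAllele
  keep <- same | swap
  nDropped <- sum(!keep) + length(setdiff(union(exposure$variantId,
                                                outcome$variantId), common))
  betaOut <- ifelse(swap, -ou$beta, ou$beta)
  if (dropPalindromic)
    keep <- keep & !isPalindromic(ex$effectAllele, ex$otherAllele)
  if (sum(!same & !swap) > 0L)
    message(sprintf("harmonizeSummaryStats: dropped %d variants with non-matching alleles",
                    sum(!same & !swap)))
  out <- mrSummaryData(ex$variantId[keep], ex$effectAllele[keep],
                       ex$otherAllele[keep], ex$eaf[keep], ex$beta[keep],
                       ex$se[keep], betaOut[keep], ou$se[keep])
  attr(out, "nDropped") <- nDropped
  out
}

#' Wald ratio estimate from a single variant
#'
#' estimate = betaOutcome / betaExposure; the standard error is the
#' first-order delta-method approximation seOutcome / |betaExposure|.
#'
#' @param x an [MRSummaryData-class] with exactly one variant, or one
#'   selected by `variantId`.
#' @param variantId optional id selecting one variant from `x`.
#' @return an [MREstimate-class] with method `"wald"`.
#' @export
mrWaldRatio <- function(x, variantId = NULL) {
  stopifnot(is(x, "MRSummaryData"))
  if (!is.null(variantId)) x <- x[variantId]
  if (length(x) != 1L) stop("mrWaldRatio needs exactly one variant")
  b <- x@betaExposure
  if (b == 0) stop("betaExposure is 0: Wald ratio undefined")
  newMrEstimate("wald", x@betaOutcome / b, x@seOutcome / abs(b), 1L,
                extras = list(variantId = x@variantId))
}

ivwCore <- function(bx, by, sey) {
  w <- 1 / sey^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  seFE <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - est * bx)^2)
  k <- length(bx)
  scale <- if (k > 1L) max(1, sqrt(q / (k - 1L))) else 1
  list(est = est, se = seFE * scale, seFE = seFE, Q = q,
       pQ = if (k > 1L) pchisq(q, k - 1L, lower.tail = FALSE) else 1)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least-squares regression of the outcome associations on the
#' exposure associations through the origin with weights 1/seOutcome^2.
#' The fixed-effect SE 1/sqrt(sum(betaExposure^2/seOutcome^2)) is inflated
#' by the multiplicative overdispersion factor max(1, sqrt(Q/(k-1)))
#' under heterogeneity. Assumes no unbalanced horizontal pleiotropy. With
#' a single variant this reduces to the Wald ratio (a warning is issued).
#'
#' @param x an [MRSummaryData-class].
#' @return an [MREstimate-class] with method `"ivw"`; `extras` carries the
#'   heterogeneity Q, its P, and the unscaled fixed-effect SE.
#' @export
mrIvw <- function(x) {
  stopifnot(is(x, "MRSummaryData"))
  k <- length(x)
  if (k == 0L) stop("no variants")
  if (k < 2L) {
    warning("fewer than 2 variants: falling back to the Wald ratio")
    w <- mrWaldRatio(x)
    return(newMrEstimate("ivw", estimate(w), stdError(w), 1L,
                         extras = list(Q = 0, pQ = 1, seFE = stdError(w))))
  }
  core <- ivwCore(x@betaExposure, x@betaOutcome, x@seOutcome)
  newMrEstimate("ivw", core$est, core$se, k,
                extras = list(Q = core$Q, pQ = core$pQ, seFE = core$seFE))
}

#' MR-Egger regression
#'
#' Every variant is first oriented so its exposure association is positive
#' (both betas flipped where needed), then the outcome associations are
#' regressed on the exposure associations by weighted least squares with a
#' free intercept (weights 1/seOutcome^2). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the
#' average directional pleiotropy, valid under the InSIDE condition.
#' Standard errors come from the weighted-LS covariance with
#' multiplicative overdispersion scaling max(1, RSS/(k-2)).
#'
#' @param x an [MRSummaryData-class] with at least 3 variants.
#' @return an [MREstimate-class] with method `"egger"`; `extras` carries
#'   the intercept, its SE, CI and P.
#' @export
mrEgger <- function(x) {
  stopifnot(is(x, "MRSummaryData"))
  k <- length(x)
  if (k < 3L) stop("MR-Egger needs at least 3 variants")
  s <- ifelse(x@betaExposure < 0, -1, 1)
  bx <- s * x@betaExposure
  by <- s * x@betaOutcome
  w <- 1 / x@seOutcome^2
  if (var(bx) == 0) {
    # degenerate design (no spread in instrument strength): slope and
    # intercept are not separable; return the no-pleiotropy limit
    warning("identical exposure associations: returning the common ratio with zero intercept")
    core <- ivwCore(bx, by, x@seOutcome)
    return(newMrEstimate("egger", core$est, core$se, k, extras = list(
      eggerIntercept = 0, eggerInterceptSe = NA_real_,
      eggerInterceptCi = c(NA_real_, NA_real_),
      eggerInterceptP = NA_real_, overdispersion = NA_real_)))
  }
  X <- cbind(intercept = 1, slope = bx)
  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * by))
  resid <- by - drop(X %*% b)
  sigma2 <- max(1, sum(w * resid^2) / (k - 2L))
  covb <- solve(A) * sigma2
  slope <- unname(b["slope", 1L]); inter <- unname(b["intercept", 1L])
  seSlope <- unname(sqrt(covb["slope", "slope"]))
  seInter <- unname(sqrt(covb["intercept", "intercept"]))
  newMrEstimate("egger", slope, seSlope, k, extras = list(
    eggerIntercept = inter, eggerInterceptSe = seInter,
    eggerInterceptCi = c(inter - Z95 * seInter, inter + Z95 * seInter),
    eggerInterceptP = 2 * pnorm(-abs(inter / seInter)),
    overdispersion = sigma2))
}

ratioPieces <- function(bx, by, seyt) {
  r <- by / bx
  v <- seyt^2 / bx^2          # first-order delta-method variance
  w <- (1 / v) / sum(1 / v)
  list(r = r, w = w)
}

weightedMedianCore <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

dropZeroExposure <- function(x, what) {
  z <- x@betaExposure == 0
  if (any(z)) {
    warning(sprintf("%s: dropped %d variants with betaExposure = 0",
                    what, sum(z)))
    x <- x[!z]
  }
  x
}

#' Weighted median estimate
#'
#' The weighted median of the per-variant ratio estimates, with weights
#' proportional to the inverse first-order delta-method variance of each
#' ratio. Ratios are sorted, cumulative percentiles p_j = (S_j - w_j/2)
#' computed from the normalized weights, and the estimate linearly
#' interpolated at percentile 0.5. Consistent when at least half the
#' weight comes from valid instruments. The SE is a seeded parametric
#' bootstrap: exposure and outcome associations are resampled from their
#' reported standard errors and the weighted median recomputed.
#'
#' @param x an [MRSummaryData-class] with at least 3 variants.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(x, nBoot = 1000L, seed = 1L) {
  stopifnot(is(x, "MRSummaryData"))
  x <- dropZeroExposure(x, "mrWeightedMedian")
  k <- length(x)
  if (k < 3L) stop("weighted median needs at least 3 variants")
  rp <- ratioPieces(x@betaExposure, x@betaOutcome, x@seOutcome)
  est <- weightedMedianCore(rp$r, rp$w)
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    bx <- rnorm(k, x@betaExposure, x@seExposure)
    by <- rnorm(k, x@betaOutcome, x@seOutcome)
    ok <- bx != 0
    rpb <- ratioPieces(bx[ok], by[ok], x@seOutcome[ok])
    weightedMedianCore(rpb$r, rpb$w)
  }, numeric(1)))
  newMrEstimate("weighted_median", est, sd(boots), k,
                extras = list(nBoot = as.integer(nBoot)))
}

# Weighted normal-kernel mode of the ratio estimates. Bandwidth
# h = phi * 0.9 * min(sd, MAD/0.6745) * k^(-1/5) (modified Silverman
# scale); the mode is located by a 512-point grid search refined by
# golden-section optimization around the best grid cell.
mbeMode <- function(r, w, phi, gridN = 512L, refine = TRUE) {
  k <- length(r)
  h0 <- 0.9 * min(sd(r), mad(r)) * k^(-1 / 5)
  if (!is.finite(h0) || h0 <= 0) return(r[which.max(w)])
  h <- phi * h0
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = gridN)
  dens <- drop(crossprod(w, dnorm(outer(r, grid, "-") / h)))
  i <- which.max(dens)
  if (!refine) return(grid[i])
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(g) sum(w * dnorm((g - r) / h)), c(lo, hi),
                  maximum = TRUE, tol = 1e-10)
  opt$maximum
}

#' Weighted mode-based estimate (MBE)
#'
#' The mode of a kernel-smoothed density of the per-variant ratio
#' estimates, weighted by inverse delta-method variance. Consistent when
#' the largest group of instruments shares the true causal effect, even if
#' that group carries less than half the weight. The bandwidth is
#' phi times the modified-Silverman scale 0.9 min(sd, MAD/0.6745) k^(-1/5);
#' phi = 1 is the default. SE by seeded parametric bootstrap.
#'
#' @param x an [MRSummaryData-class] with at least 3 variants.
#' @param phi bandwidth multiplier, > 0.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return an [MREstimate-class] with method `"mbe"`.
#' @export
mrWeightedMode <- function(x, phi = 1, nBoot = 1000L, seed = 1L) {
  stopifnot(is(x, "MRSummaryData"))
  stopifnotScalar(phi, "phi", positive = TRUE)
  x <- dropZeroExposure(x, "mrWeightedMode")
  k <- length(x)
  if (k < 3L) stop("mode-based estimation needs at least 3 variants")
  rp <- ratioPieces(x@betaExposure, x@betaOutcome, x@seOutcome)
  est <- mbeMode(rp$r, rp$w, phi)
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    bx <- rnorm(k, x@betaExposure, x@seExposure)
    by <- rnorm(k, x@betaOutcome, x@seOutcome)
    ok <- bx != 0
    rpb <- ratioPieces(bx[ok], by[ok], x@seOutcome[ok])
    mbeMode(rpb$r, rpb$w, phi, gridN = 256L, refine = FALSE)
  }, numeric(1)))
  # robust (MAD-based) spread of the bootstrap modes, as in the original
  # mode-based-estimation recipe: stray bootstrap modes on a minor density
  # peak would otherwise dominate a plain standard deviation
  newMrEstimate("mbe", est, mad(boots), k,
                extras = list(phi = phi, nBoot = as.integer(nBoot)))
}

#' Two-sample screen of fibrinogen against metabolic risk factors
#'
#' Harmonizes the fibrinogen exposure panel against each supplied
#' risk-factor outcome GWAS, runs the IVW, MR-Egger and weighted median
#' estimators, and flags any P below the Bonferroni cutoff
#' alpha / (number of risk factors). The per-outcome variant counts after
#' harmonization are reported alongside the estimates.
#'
#' @param exposure exposure summary-statistics data.frame (see
#'   [harmonizeSummaryStats()]).
#' @param outcomeTables named list of outcome summary-statistics
#'   data.frames, one per risk factor.
#' @param alpha familywise significance level (default 0.05).
#' @param nBoot bootstrap resamples for the weighted median.
#' @param seed bootstrap seed.
#' @return data.frame with one row per (risk factor, method); attributes
#'   `threshold` (alpha / number of risk factors) and `nTests`.
#' @export
riskFactorScreen <- function(exposure, outcomeTables, alpha = 0.05,
                             nBoot = 500L, seed = 1L) {
  stopifnot(is.list(outcomeTables), length(outcomeTables) >= 1L,
            !is.null(names(outcomeTables)))
  thr <- alpha / length(outcomeTables)
  rows <- list()
  for (rf in names(outcomeTables)) {
    h <- harmonizeSummaryStats(exposure, outcomeTables[[rf]])
    fits <- list(ivw = mrIvw(h), egger = mrEgger(h),
                 weighted_median = mrWeightedMedian(h, nBoot = nBoot,
                                                    seed = deriveSeed(seed, match(rf, names(outcomeTables)))))
    for (f in fits)
      rows[[length(rows) + 1L]] <- data.frame(
        riskFactor = rf, method = mrMethod(f), nVariants = f@nVariants,
        estimate = estimate(f), se = stdError(f), p = pvalue(f),
        significant = pvalue(f) < thr)
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  attr(out, "nTests") <- length(outcomeTables)
  out
}
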