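#' Residualize fibrinogen on age and sex
#'
#' Ordinary least-squares residuals of fibrinogen on an intercept, age and
#' sex, the exposure used by the two-stage fits (residualization removes
#' the dominant demographic variance and improves power). Rows with a
#' missing value in any of the three variables are dropped; the residual
#' vector keeps one entry per individual with NA at dropped rows, and the
#' number dropped is attached as attribute `nDropped` (and reported via
#' message).
#'
#' @param cohort a [CohortData-class].
#' @return numeric vector of residuals (g/L), length = individuals.
#' @export
residualizeExposure <- function(cohort) {
  stopifnot(is(cohort, "CohortData"))
  phe <- phenotypes(cohort)
  cc <- complete.cases(phe[, c("fibrinogen", "age", "sex")])
  if (sum(cc) < 3L) stop("fewer than 3 complete rows: cannot residualize")
  nDropped <- sum(!cc)
  if (nDropped > 0L)
    message(sprintf("residualizeExposure: dropped %d incomplete rows", nDropped))
  fit <- lm(fibrinogen ~ age + sex, data = phe, na.action = na.exclude)
  res <- residuals(fit)
  attr(res, "nDropped") <- nDropped
  res
}

instrumentVector <- function(instrument, n) {
  x <- if (is(instrument, "AlleleScore")) scores(instrument)
       else as.numeric(instrument)
  if (length(x) != n)
    stop("instrument length does not match cohort size")
  if (var(x, na.rm = TRUE) == 0) stop("constant instrument: stage 1 undefined")
  x
}

stage1Fit <- function(resid, inst) {
  fit <- lm(resid ~ inst, na.action = na.exclude)
  sm <- summary(fit)$coefficients
  list(fitted = fitted(fit), coef = sm["inst", 1L], se = sm["inst", 2L],
       used = !is.na(resid) & !is.na(inst))
}

twoStageResult <- function(s1, logHr, se, n, nEvents, model) {
  new("TwoStageResult",
      stage1Coef = s1$coef, stage1Se = s1$se, stage1F = (s1$coef / s1$se)^2,
      logHr = logHr, se = se, hazardRatio = exp(logHr),
      ciLower = exp(logHr - Z95 * se), ciUpper = exp(logHr + Z95 * se),
      pvalue = 2 * pnorm(-abs(logHr / se)),
      n = as.integer(n), nEvents = as.integer(nEvents), model = model)
}

#' Two-stage Cox causal-effect estimate within one cohort
#'
#' Stage 1 regresses the age/sex-residualized fibrinogen on the instrument
#' (allele score or single-variant dosage) by ordinary least squares.
#' Stage 2 fits a Cox proportional-hazards model (Efron ties) of the
#' right-censored incident outcome on the stage-1 fitted values. Because
#' the fitted values are in g/L, the stage-2 coefficient is the log hazard
#' ratio per 1 g/L higher (genetically predicted) fibrinogen. The default
#' standard error is the naive model-based Cox SE of classical two-stage
#' predictor substitution; `nBoot > 0` replaces it with a seeded
#' nonparametric bootstrap over individuals that propagates stage-1
#' uncertainty.
#'
#' @param cohort a right-censored [CohortData-class].
#' @param instrument an [AlleleScore-class] or a numeric per-individual
#'   dosage/score vector.
#' @param adjust also include age and sex in the stage-2 Cox model.
#' @param nBoot bootstrap resamples for the SE (0 = naive SE; 500 is a
#'   reasonable choice when used).
#' @param seed seed for the bootstrap stream.
#' @return a [TwoStageResult-class].
#' @examples
#' cfg <- simConfig(nIndividuals = 800, nVariants = 10, causalEffect = 0.3, seed = 2)
#' coh <- simulateCohort(cfg, 1)
#' pan <- newVariantPanel(data.frame(
#'   variantId = colnames(dosages(coh)), effectAllele = "A", otherAllele = "G",
#'   beta = 0.05, se = 0.005))
#' sc <- computeAlleleScore(dosages(coh), pan)
#' twoStageCox(coh, sc)
#' @export
twoStageCox <- function(cohort, instrument, adjust = FALSE, nBoot = 0L,
                        seed = 1L) {
  stopifnot(is(cohort, "CohortData"))
  if (cohort@censorType != "right")
    stop("twoStageCox needs right-censored outcomes; see twoStageIntervalCensored")
  out <- outcomes(cohort)
  if (sum(out$event) == 0L) stop("no events in cohort: Cox model undefined")
  n <- nrow(out)
  inst <- instrumentVector(instrument, n)
  res <- residualizeExposure(cohort)
  s1 <- stage1Fit(res, inst)
  df <- data.frame(time = out$time, event = out$event, xhat = s1$fitted,
                   age = phenotypes(cohort)$age, sex = phenotypes(cohort)$sex)
  fml <- if (adjust) survival::Surv(time, event) ~ xhat + age + sex
         else survival::Surv(time, event) ~ xhat
  fit <- survival::coxph(fml, data = df, ties = "efron")
  logHr <- unname(coef(fit)["xhat"])
  se <- sqrt(diag(fit$var))[[which(names(coef(fit)) == "xhat")]]
  if (nBoot > 0L) {
    ests <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      s1b <- stage1Fit(res[idx], inst[idx])
      dfb <- df[idx, ]
      dfb$xhat <- s1b$fitted
      fb <- try(survival::coxph(fml, data = dfb, ties = "efron"), silent = TRUE)
      if (inherits(fb, "try-error")) NA_real_ else unname(coef(fb)["xhat"])
    }, numeric(1)))
    se <- sd(ests, na.rm = TRUE)
  }
  used <- sum(s1$used)
  twoStageResult(s1, logHr, se, used, sum(out$event[s1$used]), "coxph")
}

#' Two-stage estimate for an interval-censored cohort
#'
#' Stage 1 is as in [twoStageCox()]. Stage 2 maximizes the exponential
#' accelerated-failure-time likelihood for interval-censored outcomes
#' (events known to lie in (left, right]; right = Inf means right-censored
#' at `left`) via [survival::survreg()]. For the exponential distribution
#' the AFT coefficient equals minus the proportional-hazards log hazard
#' ratio exactly, so the returned log HR is the negated AFT coefficient.
#'
#' @param cohort an interval-censored [CohortData-class].
#' @param instrument as in [twoStageCox()].
#' @return a [TwoStageResult-class].
#' @export
twoStageIntervalCensored <- function(cohort, instrument) {
  stopifnot(is(cohort, "CohortData"))
  if (cohort@censorType != "interval")
    stop("cohort is not interval-censored")
  out <- outcomes(cohort)
  if (any(out$left >= out$right, na.rm = TRUE))
    stop("degenerate intervals: need left < right")
  isEvent <- is.finite(out$right)
  if (!any(isEvent)) stop("no events in cohort")
  n <- nrow(out)
  inst <- instrumentVector(instrument, n)
  res <- residualizeExposure(cohort)
  s1 <- stage1Fit(res, inst)
  # interval2 coding: (left, right] for events, right-censored at left otherwise
  t1 <- out$left
  t2 <- ifelse(isEvent, out$right, NA_real_)
  t1 <- pmax(t1, 1e-10)  # survreg requires positive times
  df <- data.frame(t1 = t1, t2 = t2, xhat = s1$fitted)
  fit <- survival::survreg(
    survival::Surv(t1, t2, type = "interval2") ~ xhat,
    data = df, dist = "exponential")
  aft <- unname(coef(fit)["xhat"])
  se <- sqrt(diag(fit$var))[[which(names(coef(fit)) == "xhat")]]
  twoStageResult(s1, -aft, se, sum(s1$used), sum(isEvent[s1$used]),
                 "exponential-aft")
}

#' Weak-instrument F statistic
#'
#' For a single-regressor first stage the F statistic is the squared
#' t ratio, (coefficient / SE)^2.
#'
#' @param x a [TwoStageResult-class], a stage-1 `lm` fit, or a numeric
#'   coefficient (then `se` must be given).
#' @param se standard error when `x` is a plain coefficient.
#' @return the F statistic.
#' @examples
#' weakInstrumentF(0.2, 0.05)  # 16
#' @export
weakInstrumentF <- function(x, se = NULL) {
  if (is(x, "TwoStageResult")) return(x@stage1F)
  if (inherits(x, "lm")) {
    sm <- summary(x)$coefficients
    if (nrow(sm) < 2L) stop("stage-1 fit has no slope")
    return((sm[2L, 1L] / sm[2L, 2L])^2)
  }
  stopifnotScalar(x, "x")
  stopifnotScalar(se, "se", positive = TRUE)
  (x / se)^2
}
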