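# fibromr

Mendelian randomization (MR) of plasma fibrinogen on incident coronary
heart disease (CHD) and myocardial infarction (MI).

Fibrinogen — the fibrin precursor, a driver of platelet aggregation and an
inflammatory mediator — is strongly associated with CHD in observational
studies, but association is not causation: confounding and reverse
causation can inflate the observational risk ratio. MR sidesteps both by
using genetic variants as instrumental variables: alleles are assigned at
conception, independently of lifestyle confounders, so a variant that
raises fibrinogen and (only through fibrinogen) raises CHD risk identifies
the causal effect. `fibromr` implements a complete analysis pipeline for
this question, for epidemiologists and methodologists who want each stage
as a tested, reusable function:

- **Instrument construction** — an unweighted allele score over
  fibrinogen-associated variants, after four QC filters: imputation
  quality (MACH < 0.3 / IMPUTE < 0.4 removed), Spearman correlation with
  six cardiovascular risk factors (|rho| > 0.10 in any cohort removed),
  linkage disequilibrium with known CHD loci (r² > 0.20 removed), and
  mutual LD pruning (r² > 0.70, keeping the variant from the largest
  genome-wide scan). Dosages are aligned so each effect allele raises
  fibrinogen before summing.
- **One-sample estimation** — the two-stage Cox model (2SC): stage 1
  regresses age/sex-residualized fibrinogen `F` on the allele score `S`
  (OLS); stage 2 fits a Cox proportional-hazards model of the incident
  outcome on the stage-1 fitted values, giving a log hazard ratio per
  1 g/L genetically predicted fibrinogen. An interval-censored variant
  maximizes the exponential accelerated-failure-time likelihood (for
  cohorts followed by periodic examinations) and maps back to the hazard
  scale through the exact exponential AFT/PH identity `beta_PH =
  -beta_AFT`.
- **Meta-analysis** — fixed-effects inverse-variance pooling across
  cohorts (discovery, replication, combined) with Cochran's Q
  heterogeneity diagnostics, plus DerSimonian–Laird random effects.
- **Two-sample estimation** — from harmonized per-variant summary
  statistics (exposure effect `beta_j` ± se, outcome effect `Gamma_j` ±
  se): the Wald ratio `Gamma_j / beta_j`; inverse-variance weighted (IVW)
  regression of `Gamma` on `beta` through the origin; MR-Egger regression
  with a free intercept estimating average directional pleiotropy;
  the weighted median of ratio estimates; the weighted mode-based
  estimate (kernel bandwidth multiplier φ = 1); and MR-PRESSO, a
  simulation-based residual-sum-of-squares test that flags pleiotropic
  outlier variants and re-estimates by IVW without them.
- **Synthetic data with known truth** — multi-cohort individual-level
  data (Hardy–Weinberg genotypes, confounded fibrinogen, exponential
  proportional-hazards outcomes) and two-sample summary statistics with
  configurable horizontal pleiotropy (none / balanced / directional /
  planted outliers), so every estimator can be validated against the
  generative causal effect.

## Worked example

Six cohorts of 5,000 individuals with a true causal effect of 0.25
log-hazard per g/L, a 38-variant score, two-stage Cox per cohort, then a
combined fixed-effects meta-analysis and the two-sample estimators:

```r
library(fibromr)

cfg <- simConfig(nIndividuals = 5000, nCohorts = 6, causalEffect = 0.25, seed = 42)
perCohort <- do.call(rbind, lapply(1:6, function(i) {
  coh <- simulateCohort(cfg, i)
  pan <- newVariantPanel(data.frame(variantId = colnames(dosages(coh)),
    effectAllele = "A", otherAllele = "G", beta = cfg@betaExposure, se = 0.005))
  fit <- twoStageCox(coh, computeAlleleScore(dosages(coh), pan))
  data.frame(cohort = cohortLabel(coh), estimate = estimate(fit), se = stdError(fit))
}))
combineDiscoveryReplication(perCohort[1:4, ], perCohort[5:6, ])$combined
#> Fixed-effects meta-analysis of 6 studies
#>   pooled 0.2321 (SE 0.0758, 95% CI 0.0835 to 0.3806); P = 0.0022
#>   Q = 4.324, P(Q) = 0.504, tau2 = 0

ss <- simulateSummaryStats(cfg)
mrIvw(ss)
#> MR estimate [ivw], 38 variants
#>   log OR 0.2522 (SE 0.0118); OR 1.287 (95% CI 1.257-1.317); P = 3.73e-101
mrEgger(ss)
#> MR estimate [egger], 38 variants
#>   log OR 0.1937 (SE 0.0319); OR 1.214 (95% CI 1.140-1.292); P = 1.25e-09
#>   Egger intercept 0.0036 (SE 0.0018)
mrPresso(ss, seed = 1)
#> MR estimate [presso], 38 variants
#>   log OR 0.2522 (SE 0.0118); OR 1.287 (95% CI 1.257-1.317); P = 3.73e-101
#>   PRESSO global P 0.447; outliers: none
```

The pooled two-stage log hazard ratio (0.232, CI 0.084–0.381) and every
two-sample estimate recover the generative effect of 0.25; with no
pleiotropy injected, the Egger intercept is near zero and MR-PRESSO flags
nothing, so its corrected estimate equals plain IVW. `runPipeline()`
drives the same flow end to end from a YAML or list configuration,
writing per-cohort estimates, meta-analyses, the two-sample method table,
a risk-factor screen and a seed-recording manifest.
`inst/scripts/fibromr-cli.R` exposes the stages as shell subcommands.

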