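---
title: "Methods: instruments, two-stage survival MR, and pleiotropy-robust estimators"
author: "fibromr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instruments, two-stage survival MR, and pleiotropy-robust estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromr)
```

# The causal question and the instrumental-variable model

Plasma fibrinogen (g/L) is robustly associated with incident coronary
heart disease, but the association is open to confounding (smoking,
adiposity, inflammation) and reverse causation. Mendelian randomization
treats genetic variants as instruments: a variant $G_j$ is a valid
instrument if it (i) associates with fibrinogen, (ii) is independent of
confounders of the fibrinogen–CHD relation, and (iii) affects CHD only
through fibrinogen (the exclusion restriction). Horizontal pleiotropy —
a direct path from variant to outcome — violates (iii) and is the central
threat this package's estimator suite is designed to expose.

Two study designs are implemented side by side:

* **One-sample, individual level.** Within each cohort, fibrinogen is
  residualized on age and sex, the residuals are regressed on an allele
  score (stage 1, OLS), and the incident outcome is regressed on the
  stage-1 fitted values with a Cox proportional-hazards model (stage 2,
  Efron tie handling). Because fitted values are in g/L, the stage-2
  coefficient is the log hazard ratio per 1 g/L genetically predicted
  fibrinogen. Cohorts are pooled by fixed-effects inverse-variance
  meta-analysis, with Cochran's $Q$ and its $P$ reported; a
  DerSimonian–Laird random-effects variant is available as a sensitivity
  analysis.
* **Two-sample, summary level.** With per-variant exposure effects
  $\hat\beta_j \pm \sigma_{x,j}$ and outcome effects
  $\hat\Gamma_j \pm \sigma_{y,j}$ harmonized to a shared effect allele,
  the package implements the Wald ratio, IVW, MR-Egger, the weighted
  median, the weighted mode-based estimate (MBE), and MR-PRESSO, each
  robust to a different pleiotropy configuration.

# Instrument construction

Candidate variants pass four filters, applied as independent flags so the
retained set does not depend on filter order (a property the test suite
asserts):

1. imputation quality, removed when MACH quality $< 0.3$ or IMPUTE
   quality $< 0.4$ (strict inequalities, as are all thresholds below);
2. Spearman correlation with six cardiovascular risk factors — BMI, LDL,
   HDL, type-2 diabetes, hypertension (0/1 coding), smoking (ordinal
   never $<$ former $<$ current) — removed when $|\rho| > 0.10$ in any
   cohort for any trait. The screen uses the magnitude of $\rho$: a
   protective correlation is as much a confounding concern as a harmful
   one, and the magnitude screen is the stricter reading. Constant
   traits within a cohort are skipped with a warning;
3. linkage disequilibrium with known CHD loci, removed when $r^2 > 0.20$
   against a user-supplied locus table (LD values are inputs; the
   package computes no LD itself);
4. mutual LD pruning: pairs with $r^2 > 0.70$ form graph edges, and each
   connected component keeps exactly one variant — the one from the
   highest-ranked source study (rank 1 = largest genome-wide scan). When
   ranks tie the variant with larger $|\hat\beta|$ is kept, then the
   lexicographically smallest id; the tie-break is deterministic so two
   runs can never disagree.

The score is the **unweighted** sum of effect-allele dosages, after
aligning each variant so its effect allele raises fibrinogen (dosage
$d \mapsto 2 - d$ and labels swapped when the published effect is
negative; alignment is an involution). Unweighted summation is the
primary definition; a $\beta$-weighted option exists but is not the
default. Per-individual missing dosages within an available variant are
mean-imputed with twice the within-cohort effect-allele frequency, which
preserves the score scale. An optional within-cohort rescaling divides by
half the observed range, so one rescaled unit spans 50% of the range —
useful when comparing a multi-variant score against a single variant on a
common footing; a constant score cannot be rescaled and errors. The
score is finally checked against the six risk factors by per-cohort
regressions pooled by fixed-effects meta-analysis, judged against the
Bonferroni cutoff $0.05/6$ (printed as 0.008).

# One-sample estimation details

*Standard errors.* The default stage-2 SE is the naive model-based Cox SE
of classical two-stage predictor substitution; it ignores stage-1
uncertainty, which is negligible when the instrument $F$ statistic is
large (hundreds, at the default generator settings) but not in weak
instrument regimes. A seeded nonparametric bootstrap over individuals
(500 resamples when enabled) propagates both stages.

*Stage-2 covariates.* The stage-2 model regresses on the fitted values
only: residualization has already removed age and sex from the exposure,
and adding them back is redundant under the generative model used here.
An `adjust = TRUE` option includes them for users whose outcomes depend
on age/sex beyond the exposure pathway.

*Interval censoring.* For cohorts followed by periodic examinations the
event is only known to lie between exams, $(L, R]$. Stage 2 then
maximizes the exponential accelerated-failure-time likelihood
(`survival::survreg`, exponential distribution; convergence is survreg's
default, relative tolerance $10^{-9}$). For the exponential distribution
the AFT coefficient equals minus the proportional-hazards log hazard
ratio *exactly*, so the returned log HR is the negated AFT coefficient —
the sign convention needed before pooling with Cox-based cohorts. The
test suite verifies the identity against an independent Poisson-offset
fit and checks that exactly observed times passed as tight intervals
reproduce the right-censored fit.

*Scale equivariance.* Multiplying the instrument by any $c \neq 0$
leaves the stage-2 estimate unchanged (fitted values are invariant), so
score rescaling never alters the causal estimate — asserted in the tests.

# Two-sample estimators: the exact recipes

The method names are standard but published descriptions leave freedom;
the recipes below are fixed so that two implementations produce identical
numbers.

**IVW.** Weighted least squares of $\hat\Gamma$ on $\hat\beta$ through
the origin with weights $w_j = 1/\sigma_{y,j}^2$:
$\hat\theta = \sum w_j \hat\beta_j \hat\Gamma_j / \sum w_j \hat\beta_j^2$,
fixed-effect SE $(\sum w_j \hat\beta_j^2)^{-1/2}$, inflated by the
multiplicative overdispersion factor $\max(1, \sqrt{Q/(k-1)})$ — the
convention of mainstream MR software, conservative under heterogeneity
and inert under homogeneity. With one variant IVW degrades to the Wald
ratio with a warning.

**MR-Egger.** Each variant is first oriented so $\hat\beta_j > 0$
(flipping both coordinates), then $\hat\Gamma$ is regressed on
$\hat\beta$ with a free intercept, weights $w_j$. The slope is the
pleiotropy-adjusted estimate, the intercept the average directional
pleiotropy; both are valid when instrument strength is independent of
the direct effects (InSIDE). SEs use the weighted-LS covariance scaled by
$\max(1, \mathrm{RSS}_w/(k-2))$. A panel with identical exposure effects
makes slope and intercept inseparable; the implementation returns the
common ratio with zero intercept and a warning rather than failing.

**Weighted median.** Ratio estimates $r_j = \hat\Gamma_j/\hat\beta_j$
with weights proportional to the inverse first-order delta-method
variance $\hat\beta_j^2/\sigma_{y,j}^2$ (a second-order option exists).
After sorting, cumulative percentiles $p_j = S_j - w_j/2$ (normalized
weights) are interpolated linearly at 0.5. Consistent when valid
instruments carry $\ge$ 50% of the weight. SE by seeded parametric
bootstrap (default 1000): $\hat\beta^*, \hat\Gamma^*$ are redrawn from
their reported SEs and the whole statistic — weights included —
recomputed.

**Weighted MBE.** The mode of the weighted normal-kernel density of the
$r_j$, bandwidth $h = \varphi \cdot 0.9\,\min(\mathrm{sd},
\mathrm{MAD}/0.6745)\,k^{-1/5}$ with $\varphi = 1$ by default (results
in the motivating analyses were insensitive to $\varphi$). The mode is
located on a 512-point grid spanning the ratios $\pm 3h$ and refined by
golden-section search to $10^{-10}$; inside the bootstrap a 256-point
grid without refinement is used, since SE estimation does not need
micro-precision. The bootstrap spread is summarized by the
normal-consistent MAD — the robust choice of the original mode-based
recipe, protecting the SE from stray bootstrap modes on minor density
peaks. With all ratios equal the bandwidth is zero and the common ratio
is returned directly.

**MR-PRESSO.** Observed residual sum of squares
$\mathrm{RSS} = \sum_j w_j(\hat\Gamma_j - \hat\theta_{(-j)}\hat\beta_j)^2$
with leave-one-out IVW slopes $\hat\theta_{(-j)}$. The null distribution
comes from `nSim` (default 1000) parametric draws under the fitted
no-pleiotropy model; the global $P$ is the add-one empirical exceedance
$(1 + \#\{\mathrm{RSS}^* \ge \mathrm{RSS}\})/(n_{sim}+1)$. Each
variant's RSS contribution is tested against its own simulated
distribution using the *raw* exceedance proportion — with an add-one
correction the attainable floor $1/(n_{sim}+1)$ could never pass the
Bonferroni cutoff $0.05/k$ at moderate `nSim`, and no outlier could ever
be flagged. Variants below $0.05/k$ are removed and IVW re-fitted; with
nothing flagged the corrected estimate is bit-identical to plain IVW. A
distortion $P$ compares the observed estimate shift against shifts from
removing random subsets of the same size.

*Harmonization.* Tables are matched on variant id; outcome rows reported
on the opposite allele get their sign flipped; allele-set mismatches are
dropped with a count. Palindromic (A/T, C/G) variants are retained by
default — no allele-frequency inference is attempted — with a
`dropPalindromic` switch. Duplicate ids are an error, not a silent
first-match.

# The synthetic-data generator

The generator stands in for consortium cohort data and defines the
conditions under which the estimators are validated:

* Genotypes: $G_j \sim \mathrm{Binomial}(2, p_j)$ under Hardy–Weinberg,
  default $p_j$ spread over $(0.1, 0.5)$ and $M = 38$ variants, the size
  of the motivating allele score.
* Exposure: $F = c + \sum_j \beta_j G_j + \gamma_U U + a\,(\mathrm{age}-55)
  + b\,\mathrm{sex} + \varepsilon$, with $U \sim N(0,1)$ a latent
  confounder, $\varepsilon \sim N(0, \sigma_F^2)$, $\sigma_F = 0.6$ g/L
  and an intercept centring the population mean at 3.0 g/L — matching the
  means and dispersions reported for large population cohorts. Age and
  sex effects default to 0.01 g/L per year and $-0.1$ g/L (male), small
  enough not to dominate but large enough that residualization is
  non-trivial. Per-allele effects default to 0.02–0.08 g/L, the scale of
  genome-wide-significant fibrinogen loci.
* Outcome: event times are exponential with hazard
  $\lambda_0 \exp(\theta F + \delta_U U + \sum_j \alpha_j G_j)$,
  administratively censored at 12 years; $\lambda_0 = 0.005$/person-year
  yields cumulative incidence near the 10–20% range typical of the
  cohorts that motivated the design. The exponential law is chosen
  because its AFT and PH parameterizations are analytically
  interconvertible, which supplies an exact oracle for the
  interval-censored path. The confounder acts on both exposure
  ($\gamma_U = 0.3$) and hazard ($\delta_U = 0.3$), so a naive Cox fit on
  observed fibrinogen is biased while the two-stage fit is not — the
  point of instrumenting, and an asserted test.
* Two-sample statistics: $\hat\beta_j \sim N(\beta_j, \sigma_{x,j}^2)$,
  $\hat\Gamma_j \sim N(\theta\beta_j + \alpha_j, \sigma_{y,j}^2)$ with
  the standard GWAS approximation for a standardized trait,
  $\sigma = (2p(1-p)n)^{-1/2}$, at effective sample sizes 50,000
  (exposure) and 184,305 (outcome, the case-plus-control count of the
  motivating outcome GWAS).
* Pleiotropy modes: `none` ($\alpha_j = 0$), `balanced`
  ($\alpha_j \sim N(0, 0.02)$), `directional`
  ($\alpha_j \sim N(0.05, 0.02)$, drawn independently of $\beta_j$ so
  InSIDE holds), `outliers` (all zero except a planted few at ten times
  the typical outcome effect).
* Reproducibility: all randomness flows from one explicit seed through
  counter-derived per-cohort streams; the global RNG state is saved and
  restored around every draw, and identical (config, seed) gives
  bit-identical output. One subtlety worth recording: the stream wrapper
  forces its seed argument *before* snapshotting the global state, so a
  caller that computes the seed inline from the global stream is not
  rolled back.
* The Spearman-correlated variant used to exercise the risk-factor
  filter comes from a Gaussian copula (latent bivariate normal, dosage by
  Hardy–Weinberg thresholding, BMI as a monotone transform), with the
  rank-correlation attenuation of the discretized margin calibrated once
  by Monte Carlo.

What the generator does **not** emulate: linkage disequilibrium between
instrument variants (LD enters only as explicit $r^2$ tables for the
pruning filters), case-control ascertainment of the outcome GWAS beyond
the log-odds parameterization, assay differences between fibrinogen
measurement methods, non-proportional hazards, competing risks, and
population stratification. Passing tests therefore demonstrate correct
estimator behaviour under a clean generative model, not robustness to
every failure mode of real consortium data.

# Validation suite and problem sizes

The acceptance tests (and `scripts/acceptance.R`, which recomputes the
same quantities and writes JSON) run at sizes chosen to make Monte-Carlo
error small relative to the bands being checked: 500 replicates for
null-calibration rejection rates (2SC at $n = 1000$; summary-statistic
estimators at $k = 30$); 100 replicates of six cohorts of 5,000 for
recovery of $\theta = 0.25$ and CI coverage; 500 replicates for the
directional-pleiotropy contrast of IVW against the Egger slope and
intercept; 60 replicates for MR-PRESSO planted-outlier recall. Exact
algebraic identities (closed-form IVW/Egger against independent weighted
least squares, the two-study meta-analysis closed form, the AFT/PH sign
identity, pooling transitivity) are checked at tolerances between
$10^{-10}$ and $10^{-6}$.

# Known limitations

* The weighted MBE's parametric-bootstrap SE is conservative: resampling
  around already-noisy estimates convolves the estimation noise twice,
  so under the causal null the MBE rejects at somewhat less than the
  nominal 5% (the acceptance script reports the measured rate alongside
  the other estimators). This mirrors the conservative behaviour
  documented for the estimator in its method literature; interpret MBE
  non-rejection accordingly.
* Naive two-stage Cox SEs ignore stage-1 uncertainty and the hazard
  ratio is non-collapsible, so with very strong effects or common events
  the pooled estimate can attenuate slightly; at the default settings
  the recovery simulations show coverage at the nominal level.
* The risk-factor correlation screen will remove a few variants by
  chance in small cohorts (|rho| > 0.10 is about 1.4 null SDs at
  n = 600); that is the filter's intended strictness, not a defect.
* No multivariable MR, Steiger filtering, correlated-instrument IVW, or
  overlap correction for shared controls between exposure and outcome
  samples.
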