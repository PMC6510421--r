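test_that("imputation-quality filter uses strict method-specific cutoffs", {
  pan <- makePanel(c("a", "b", "c", "d"), rep(0.03, 4))
  qt <- data.frame(variantId = c("a", "b", "c", "d"),
                   method = c("MACH", "MACH", "IMPUTE", "IMPUTE"),
                   quality = c(0.29, 0.30, 0.35, 0.40))
  pan <- filterImputationQuality(pan, qt)
  expect_identical(pan$flagLowImputation, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(filterImputationQuality(pan, data.frame(
    variantId = "a", method = "BEAGLE", quality = 0.5)), "unknown")
})

test_that("risk-factor correlation filter is strict at |rho| > 0.10", {
  # two variants: one engineered monotone with BMI, one independent
  n <- 400
  coh <- makeTinyCohort(n)
  dos <- dosages(coh)
  set.seed(4)
  dos[, 1] <- rep(0:2, length.out = n)           # tracks bmi (monotone)
  dos[, 2] <- sample(0:2, n, replace = TRUE)
  coh@dosages <- dos
  coh@phenotypes$bmi <- 20 + as.numeric(dos[, 1]) + rnorm(n, 0, 0.1)
  pan <- makePanel(colnames(dos), c(0.03, 0.03))
  pan <- filterRiskFactorCorrelation(pan, list(coh))
  expect_true(pan$flagRfCorrelated[1])
  expect_false(pan$flagRfCorrelated[2])
  # constant trait is skipped with a warning, not an error
  coh@phenotypes$diabetes <- 0
  expect_warning(filterRiskFactorCorrelation(pan, list(coh)), "constant")
})

test_that("CHD-locus LD filter flags r2 > 0.20 strictly", {
  pan <- makePanel(c("a", "b", "c"), rep(0.03, 3))
  ld <- data.frame(variantId = c("a", "b"), locus = c("chd1", "chd1"),
                   r2 = c(0.25, 0.20))
  pan2 <- filterChdLd(pan, ld)
  expect_identical(pan2$flagChdLd, c(TRUE, FALSE, FALSE))
  # empty locus table flags nothing
  expect_identical(filterChdLd(pan, ld[0, ])$flagChdLd, rep(FALSE, 3))
  expect_error(filterChdLd(pan, data.frame(variantId = "a", locus = "x",
                                           r2 = 1.2)), "\\[0,1\\]")
})

test_that("LD pruning keeps one variant per component by source rank", {
  pan <- makePanel(c("a", "b"), c(0.03, 0.05), sourceRank = c(1L, 2L))
  r2 <- data.frame(id1 = "a", id2 = "b", r2 = 0.71)
  pan2 <- pruneLdPairs(pan, r2)
  expect_identical(pan2$flagLdPruned, c(FALSE, TRUE))  # largest scan kept
  # exactly 0.70 is below the strict threshold: both retained
  pan3 <- pruneLdPairs(pan, data.frame(id1 = "a", id2 = "b", r2 = 0.70))
  expect_identical(pan3$flagLdPruned, c(FALSE, FALSE))
  # triangle from the same study: tie broken by |beta| then id
  tri <- makePanel(c("x", "y", "z"), c(0.02, 0.05, 0.05))
  r2t <- data.frame(id1 = c("x", "x", "y"), id2 = c("y", "z", "z"),
                    r2 = rep(0.9, 3))
  tri2 <- pruneLdPairs(tri, r2t)
  expect_identical(retainedVariants(tri2), "y")  # larger beta, then lexicographic
})

test_that("pruning matches a brute-force per-component rule on random graphs", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(4:12, 1)
    ids <- sprintf("v%02d", 1:k)
    pan <- makePanel(ids, runif(k, -0.1, 0.1) + 0.01,
                     sourceRank = sample(1:3, k, replace = TRUE))
    pairs <- t(combn(k, 2))
    r2 <- data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                     r2 = runif(nrow(pairs)))
    pruned <- retainedVariants(pruneLdPairs(pan, r2))
    # brute force: connected components by reachability, then argmax rule
    adj <- matrix(FALSE, k, k, dimnames = list(ids, ids))
    hi <- r2$r2 > 0.70
    for (e in which(hi)) {
      adj[r2$id1[e], r2$id2[e]] <- TRUE
      adj[r2$id2[e], r2$id1[e]] <- TRUE
    }
    reach <- adj | diag(k) > 0
    for (m in 1:k) reach <- reach | (reach %*% reach) > 0
    seen <- character(0); keep <- character(0)
    for (id in ids) {
      if (id %in% seen) next
      compIds <- ids[reach[id, ]]
      seen <- c(seen, compIds)
      sub <- pan[match(compIds, pan$variantId), ]
      best <- sub$variantId[order(sub$sourceRank, -abs(sub$beta),
                                  sub$variantId)][1]
      keep <- c(keep, best)
    }
    expect_setequal(pruned, keep)
  }
})

test_that("cross-cohort missingness flags variants absent anywhere", {
  c1 <- makeTinyCohort(6)
  c2 <- makeTinyCohort(6)
  c2@dosages <- c2@dosages[, "rsA", drop = FALSE]  # rsB missing here
  pan <- makePanel(c("rsA", "rsB"), c(0.03, 0.03))
  pan2 <- filterMissingness(pan, list(c1, c2))
  expect_identical(pan2$flagMissing, c(FALSE, TRUE))
  expect_identical(filterMissingness(pan, list(c1))$flagMissing, c(FALSE, FALSE))
  # nested replication score: a 38-variant score with 6 variants missing
  # in the replication arm leaves a 32-variant replication score
  ids <- sprintf("v%02d", 1:38)
  disc <- makeTinyCohort(6); repl <- makeTinyCohort(6)
  mk <- function(keep) {
    d <- matrix(1, 6, length(keep)); colnames(d) <- keep; d
  }
  disc@dosages <- mk(ids)
  repl@dosages <- mk(ids[-(1:6)])
  pan38 <- makePanel(ids, rep(0.03, 38))
  pan38 <- filterMissingness(pan38, list(disc))
  expect_length(retainedVariants(pan38), 38L)
  panRepl <- filterMissingness(pan38, list(repl))
  expect_length(retainedVariants(panRepl), 32L)
})

test_that("filters are idempotent and order-invariant", {
  set.seed(2)
  cfg <- simConfig(nIndividuals = 300, nVariants = 8, seed = 14)
  coh <- simulateCohort(cfg, 1)
  pan0 <- makePanel(colnames(dosages(coh)), cfg@betaExposure)
  qt <- data.frame(variantId = "var002", method = "MACH", quality = 0.1)
  ld <- data.frame(variantId = "var003", locus = "chd", r2 = 0.5)
  r2 <- data.frame(id1 = "var004", id2 = "var005", r2 = 0.9)
  apply1 <- function(p) filterImputationQuality(p, qt)
  apply2 <- function(p) filterChdLd(p, ld)
  apply3 <- function(p) pruneLdPairs(p, r2)
  apply4 <- function(p) filterMissingness(p, list(coh))
  once <- apply4(apply3(apply2(apply1(pan0))))
  twice <- apply1(apply1(once))
  expect_identical(once, apply4(apply3(apply2(apply1(once)))))  # idempotent
  expect_identical(once$flagLowImputation, twice$flagLowImputation)
  other <- apply1(apply2(apply4(apply3(pan0))))
  expect_setequal(retainedVariants(once), retainedVariants(other))
})

test_that("allele alignment reflects negative-beta variants and is an involution", {
  pan <- makePanel(c("p", "m", "q"), c(0.03, -0.03, 0.05),
                   effectAllele = c("A", "C", "A"),
                   otherAllele = c("G", "T", "G"))
  dos <- matrix(c(2, 1, 0.5, 2, 1, 0.5), 2, 3, byrow = TRUE)
  colnames(dos) <- c("p", "m", "q")
  al <- alignEffectAlleles(pan, dos)
  expect_equal(al$dosages[, "m"], c(1, 1))     # only middle column reflected: 2-1
  expect_equal(al$dosages[, "p"], dos[, "p"])
  expect_true(all(al$panel$beta > 0))
  expect_identical(al$panel$effectAllele[2], "T")
  twice <- alignEffectAlleles(al$panel, al$dosages)
  expect_equal(twice$dosages, al$dosages)      # already aligned: no-op
  expect_error(alignEffectAlleles(makePanel("z", 0), dos), "undefined")
})

test_that("allele score is the unweighted sum with mean imputation", {
  pan <- makePanel(c("a", "b", "c"), c(0.02, 0.03, 0.04))
  dos <- rbind(c(2, 1, 0.5), c(0, 0, 0))
  colnames(dos) <- c("a", "b", "c")
  sc <- computeAlleleScore(dos, pan)
  expect_equal(scores(sc), c(3.5, 0))
  expect_identical(variantIds(sc), c("a", "b", "c"))
  # bounds: 0 <= score <= 2M'
  expect_true(all(scores(sc) >= 0 & scores(sc) <= 6))
  # missing dosage imputed with the column mean (2 x within-cohort eaf)
  dosNA <- dos; dosNA[2, 1] <- NA
  expect_equal(scores(computeAlleleScore(dosNA, pan))[2], 2)
  # single variant, dosage 2 -> score 2
  expect_equal(scores(computeAlleleScore(dos[, 1, drop = FALSE],
                                         pan[1, ]))[1], 2)
  expect_error(computeAlleleScore(dos, pan[0, ]), "retained|empty|columns")
})

test_that("rescaled score uses half the within-cohort range as divisor", {
  sc <- new("AlleleScore", scores = c(10, 20, 30), variantIds = sprintf("v%d", 1:20),
            weighted = FALSE, rescaled = FALSE, divisor = 1)
  rs <- rescaleScore(sc)
  expect_equal(rs@divisor, 10)
  expect_equal(scores(rs), c(1, 2, 3))
  expect_lte(diff(range(scores(rs))), 2)
  # single-variant score spanning [0,2]: divisor 1, unchanged
  s1 <- new("AlleleScore", scores = c(0, 1, 2), variantIds = "v1",
            weighted = FALSE, rescaled = FALSE, divisor = 1)
  expect_equal(scores(rescaleScore(s1)), c(0, 1, 2))
  const <- new("AlleleScore", scores = rep(1, 3), variantIds = "v1",
               weighted = FALSE, rescaled = FALSE, divisor = 1)
  expect_error(rescaleScore(const), "range")
})

test_that("score risk-factor check reports the 0.008 Bonferroni cutoff and flags", {
  cfg <- simConfig(nIndividuals = 3000, nVariants = 6, seed = 51)
  cohs <- lapply(1:2, function(i) simulateCohort(cfg, i))
  scs <- lapply(cohs, function(co) cohortScore(co, cfg@betaExposure))
  chk <- scoreRiskFactorCheck(cohs, scs)
  expect_identical(attr(chk, "thresholdPrinted"), 0.008)
  expect_equal(attr(chk, "threshold"), 0.05 / 6)
  expect_identical(nrow(chk), 6L)
  # variants simulated independently of risk factors: nothing flagged
  expect_true(all(!chk$significant))
  # a variant built with rho = 0.3 to BMI at n = 10,000 is detected
  cfg2 <- simConfig(nIndividuals = 10000, nVariants = 6, seed = 52)
  cohB <- simulateCorrelatedVariant(cfg2, 0.3)
  scB <- cohortScore(cohB, cfg2@betaExposure)
  chkB <- scoreRiskFactorCheck(list(cohB), list(scB))
  expect_lt(chkB$p[chkB$trait == "bmi"], 0.008)
})
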