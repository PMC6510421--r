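test_that("harmonization aligns, flips and drops variants correctly", {
  expo <- data.frame(variantId = c("v1", "v2", "v3", "v4"),
                     effectAllele = c("A", "A", "A", "A"),
                     otherAllele = c("G", "G", "G", "T"),
                     eaf = c(0.3, 0.3, 0.3, 0.3),
                     beta = c(0.05, 0.05, 0.05, 0.05),
                     se = rep(0.01, 4))
  outc <- data.frame(variantId = c("v1", "v2", "v3", "v4"),
                     effectAllele = c("A", "G", "C", "T"),
                     otherAllele = c("G", "A", "A", "A"),
                     eaf = c(0.3, 0.7, 0.3, 0.7),
                     beta = c(0.1, 0.1, 0.1, 0.1),
                     se = rep(0.02, 4))
  h <- suppressMessages(harmonizeSummaryStats(expo, outc))
  d <- as.data.frame(h)
  expect_setequal(d$variantId, c("v1", "v2", "v4"))  # v3 allele mismatch
  expect_equal(d$betaOutcome[d$variantId == "v1"], 0.1)    # pass-through
  expect_equal(d$betaOutcome[d$variantId == "v2"], -0.1)   # swapped: sign flip
  # palindromic A/T variant retained by default, dropped on request
  h2 <- suppressMessages(harmonizeSummaryStats(expo, outc, dropPalindromic = TRUE))
  expect_false("v4" %in% variantIds(h2))
  dup <- rbind(expo, expo[1, ])
  expect_error(harmonizeSummaryStats(dup, outc), "duplicate")
})

test_that("Wald ratio and its delta-method SE follow the formulas", {
  s <- makeSummary(bx = 0.5, by = 0.1, sey = 0.05)
  w <- mrWaldRatio(s)
  expect_equal(estimate(w), 0.2)
  expect_equal(stdError(w), 0.1)
  expect_equal(estimate(mrWaldRatio(makeSummary(bx = 0.5, by = 0))), 0)
  expect_error(mrWaldRatio(makeSummary(bx = 0, by = 0.1)), "undefined")
})

test_that("IVW matches an independent weighted least-squares fit", {
  bx <- c(0.02, 0.05, 0.08, 0.03, 0.06)
  by <- c(0.010, 0.011, 0.025, 0.004, 0.018)
  sey <- c(0.004, 0.005, 0.006, 0.004, 0.005)
  s <- makeSummary(bx, by, sey = sey)
  fit <- mrIvw(s)
  oracle <- lm(by ~ 0 + bx, weights = 1 / sey^2)
  expect_equal(estimate(fit), unname(coef(oracle)), tolerance = 1e-10)
  # closed-form fixed-effect SE
  expect_equal(fit@extras$seFE, 1 / sqrt(sum(bx^2 / sey^2)), tolerance = 1e-12)
  # Q equals the weighted RSS
  expect_equal(fit@extras$Q,
               sum((by - estimate(fit) * bx)^2 / sey^2), tolerance = 1e-10)
  # single pair falls back to the Wald ratio
  expect_warning(one <- mrIvw(s[1]), "Wald")
  expect_equal(estimate(one), by[1] / bx[1])
  # exact proportionality: estimate c, Q = 0
  s0 <- makeSummary(bx, 0.3 * bx, sey = sey)
  f0 <- mrIvw(s0)
  expect_equal(estimate(f0), 0.3, tolerance = 1e-12)
  expect_equal(f0@extras$Q, 0, tolerance = 1e-12)
})

test_that("Egger regression matches weighted least squares with intercept", {
  bx <- c(0.02, 0.05, 0.08, 0.03)
  sey <- c(0.004, 0.005, 0.006, 0.004)
  a <- 0.03; cslope <- 0.4
  by <- a + cslope * bx
  fit <- mrEgger(makeSummary(bx, by, sey = sey))
  expect_equal(estimate(fit), cslope, tolerance = 1e-10)
  expect_equal(fit@extras$eggerIntercept, a, tolerance = 1e-10)
  # against an independent weighted lm on a noisy instance
  set.seed(3)
  byn <- a + cslope * bx + rnorm(4, 0, 0.01)
  fitn <- mrEgger(makeSummary(bx, byn, sey = sey))
  oracle <- lm(byn ~ bx, weights = 1 / sey^2)
  expect_equal(estimate(fitn), unname(coef(oracle)["bx"]), tolerance = 1e-10)
  expect_equal(fitn@extras$eggerIntercept, unname(coef(oracle)["(Intercept)"]),
               tolerance = 1e-10)
  expect_error(mrEgger(makeSummary(bx[1:2], by[1:2])), "3 variants")
  # orientation: flipping the sign of (bx, by) jointly changes nothing
  s <- sample(c(-1, 1), 4, replace = TRUE)
  fito <- mrEgger(makeSummary(s * bx, s * byn, sey = sey))
  expect_equal(estimate(fito), estimate(fitn), tolerance = 1e-12)
})

test_that("weighted median interpolates the 50th weighted percentile", {
  # equal weights, ratios {1, 2, 10}: percentile 0.5 lands on the middle
  s <- makeSummary(bx = c(1, 1, 1), by = c(1, 2, 10), sey = c(1, 1, 1))
  fit <- mrWeightedMedian(s, nBoot = 50, seed = 1)
  expect_equal(estimate(fit), 2)
  # all ratios equal r: estimate r
  s2 <- makeSummary(bx = c(0.5, 1, 2), by = 0.3 * c(0.5, 1, 2),
                    sey = c(0.01, 0.01, 0.01))
  expect_equal(estimate(mrWeightedMedian(s2, nBoot = 50, seed = 1)), 0.3,
               tolerance = 1e-10)
  # breakdown: 40% of weight contaminated, median still near the truth
  set.seed(14)
  k <- 20
  bx <- runif(k, 0.04, 0.08)
  by <- 0.25 * bx
  by[1:8] <- by[1:8] + 0.05           # shifted contaminated group
  sey <- rep(1e-4, k)
  est <- estimate(mrWeightedMedian(makeSummary(bx, by, sey = sey),
                                   nBoot = 50, seed = 2))
  expect_lt(abs(est - 0.25), 0.1 * 0.25)
})

test_that("mode-based estimate finds the dominant ratio cluster", {
  # single atom: estimate r for any bandwidth
  s <- makeSummary(bx = c(1, 2, 4), by = 0.7 * c(1, 2, 4),
                   sey = c(0.01, 0.01, 0.01))
  for (phi in c(0.5, 1, 2))
    expect_equal(estimate(mrWeightedMode(s, phi, nBoot = 50, seed = 1)), 0.7,
                 tolerance = 1e-8)
  # 25 of 30 ratios clustered at 1.0 (tight), 5 at 3.0
  set.seed(15)
  bx <- runif(30, 0.5, 1)
  by <- bx * c(rep(1, 25), rep(3, 5)) + rnorm(30, 0, 0.005)
  sm <- makeSummary(bx, by, sey = rep(0.01, 30))
  fit1 <- mrWeightedMode(sm, 1, nBoot = 50, seed = 3)
  expect_lt(abs(estimate(fit1) - 1.0), 0.1)
  # doubling the bandwidth still returns the heavier mode
  fit2 <- mrWeightedMode(sm, 2, nBoot = 50, seed = 3)
  expect_lt(abs(estimate(fit2) - 1.0), 0.25)
  expect_error(mrWeightedMode(sm, phi = 0), "> 0")
})

test_that("estimators collapse to the common ratio on identical pairs", {
  s <- makeSummary(bx = rep(0.05, 6), by = rep(0.02, 6),
                   sex = rep(0.01, 6), sey = rep(0.008, 6))
  r <- 0.02 / 0.05
  expect_equal(estimate(mrIvw(s)), r, tolerance = 1e-12)
  expect_equal(estimate(mrWeightedMedian(s, nBoot = 50, seed = 1)), r,
               tolerance = 1e-10)
  expect_equal(estimate(mrWeightedMode(s, 1, nBoot = 50, seed = 1)), r,
               tolerance = 1e-8)
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(16)
  for (i in 1:5) {
    k <- sample(5:12, 1)
    bx <- runif(k, 0.02, 0.1)
    by <- 0.3 * bx + rnorm(k, 0, 0.01)
    sey <- runif(k, 0.005, 0.02)
    s <- makeSummary(bx, by, sey = sey)
    neg <- makeSummary(bx, -by, sey = sey)
    cc <- 2.5
    scl <- makeSummary(cc * bx, by, sex = rep(0.01 * cc, k), sey = sey)
    for (f in list(mrIvw, mrEgger)) {
      expect_equal(estimate(f(neg)), -estimate(f(s)), tolerance = 1e-10)
      expect_equal(estimate(f(scl)), estimate(f(s)) / cc, tolerance = 1e-10)
    }
    expect_equal(estimate(mrWeightedMedian(neg, nBoot = 20, seed = 1)),
                 -estimate(mrWeightedMedian(s, nBoot = 20, seed = 1)),
                 tolerance = 1e-10)
    expect_equal(estimate(mrWeightedMedian(scl, nBoot = 20, seed = 1)),
                 estimate(mrWeightedMedian(s, nBoot = 20, seed = 1)) / cc,
                 tolerance = 1e-10)
  }
})

test_that("bootstrap standard errors are bit-identical under a fixed seed", {
  set.seed(17)
  bx <- runif(8, 0.02, 0.1)
  s <- makeSummary(bx, 0.2 * bx + rnorm(8, 0, 0.01))
  a <- mrWeightedMedian(s, nBoot = 100, seed = 7)
  b <- mrWeightedMedian(s, nBoot = 100, seed = 7)
  expect_identical(stdError(a), stdError(b))
  c1 <- mrWeightedMode(s, 1, nBoot = 100, seed = 7)
  c2 <- mrWeightedMode(s, 1, nBoot = 100, seed = 7)
  expect_identical(stdError(c1), stdError(c2))
  expect_false(identical(stdError(a),
                         stdError(mrWeightedMedian(s, nBoot = 100, seed = 8))))
})

test_that("risk-factor screen applies the familywise threshold", {
  cfgNull <- simConfig(nVariants = 20, causalEffect = 0, seed = 61)
  expoTab <- {
    d <- as.data.frame(simulateSummaryStats(cfgNull))
    data.frame(variantId = d$variantId, effectAllele = d$effectAllele,
               otherAllele = d$otherAllele, eaf = d$eaf,
               beta = d$betaExposure, se = d$seExposure)
  }
  outTab <- function(seed, theta) {
    cfg <- simConfig(nVariants = 20, causalEffect = theta, seed = seed)
    d <- as.data.frame(simulateSummaryStats(cfg))
    data.frame(variantId = d$variantId, effectAllele = d$effectAllele,
               otherAllele = d$otherAllele, eaf = d$eaf,
               beta = d$betaOutcome, se = d$seOutcome)
  }
  outs <- c(lapply(1:6, function(i) outTab(100 + i, 0)),
            list(strong = outTab(200, 1.0)))
  names(outs) <- c(paste0("rf", 1:6), "strong")
  scr <- riskFactorScreen(expoTab, outs, nBoot = 100, seed = 1)
  expect_equal(attr(scr, "threshold"), 0.05 / 7, tolerance = 1e-12)
  expect_identical(nrow(scr), 21L)  # 7 risk factors x 3 methods
  # the strongly caused risk factor is flagged by IVW with high power
  expect_true(scr$significant[scr$riskFactor == "strong" & scr$method == "ivw"])
})
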