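# In-code fixtures shared across test files.

makePanel <- function(ids, beta, se = rep(0.005, length(ids)),
                      sourceRank = rep(1L, length(ids)),
                      effectAllele = rep("A", length(ids)),
                      otherAllele = rep("G", length(ids))) {
  newVariantPanel(data.frame(
    variantId = ids, effectAllele = effectAllele, otherAllele = otherAllele,
    beta = beta, se = se, sourceRank = sourceRank, stringsAsFactors = FALSE))
}

makeSummary <- function(bx, by, sex = rep(0.01, length(bx)),
                        sey = rep(0.05, length(bx)),
                        ids = sprintf("var%03d", seq_along(bx))) {
  mrSummaryData(ids, rep("A", length(bx)), rep("G", length(bx)),
                rep(0.3, length(bx)), bx, sex, by, sey)
}

# Hand-built miniature cohort with fully controlled values.
makeTinyCohort <- function(n = 8, time = NULL, event = NULL, fib = NULL,
                           dos = NULL, label = "tiny") {
  if (is.null(dos)) {
    dos <- matrix(rep(c(0, 1, 2), length.out = 2 * n), n, 2)
    colnames(dos) <- c("rsA", "rsB")
  }
  if (is.null(fib)) fib <- 2.5 + 0.1 * rowSums(dos)
  if (is.null(time)) time <- seq(1, 10, length.out = n)
  if (is.null(event)) event <- rep(c(1, 0), length.out = n)
  new("CohortData", label = label, dosages = dos,
      phenotypes = data.frame(
        age = seq(40, 70, length.out = n), sex = rep(c(0, 1), length.out = n),
        fibrinogen = fib, bmi = rep(27, n) + seq_len(n) / 10,
        ldl = rep(130, n) + seq_len(n), hdl = rep(50, n) + seq_len(n) / 2,
        hypertension = rep(c(0, 1), length.out = n),
        diabetes = rep(c(0, 0, 1), length.out = n),
        smoking = rep(0:2, length.out = n)),
      outcomes = data.frame(time = time, event = event),
      censorType = "right")
}

# Score-building shorthand used by one-sample and pipeline tests.
cohortScore <- function(coh, beta) {
  pan <- makePanel(colnames(dosages(coh)), beta)
  al <- alignEffectAlleles(pan, dosages(coh))
  computeAlleleScore(al$dosages, al$panel)
}
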