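# TSV exchange format: header row, tab separator, "NA" for missing,
# numbers serialized at full double precision with deterministic
# formatting, so that write -> read -> write is bit-identical.

writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatNum(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write GWAS-style summary statistics
#'
#' Columns: `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se` for a single-trait table; a harmonized pair table written from an
#' [MRSummaryData-class] has `beta_exposure`, `se_exposure`,
#' `beta_outcome`, `se_outcome` instead of `beta`/`se`.
#'
#' @param path TSV file path.
#' @return `readSummaryStats`: data.frame with camelCase columns ready for
#'   [harmonizeSummaryStats()]. `readSummaryPairs`: an
#'   [MRSummaryData-class].
#' @export
readSummaryStats <- function(path) {
  df <- readTsv(path)
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  stopifnot(all(need %in% names(df)))
  data.frame(variantId = df$variant_id, effectAllele = df$effect_allele,
             otherAllele = df$other_allele, eaf = df$eaf, beta = df$beta,
             se = df$se, stringsAsFactors = FALSE)
}

#' @rdname readSummaryStats
#' @param df data.frame with the camelCase columns of `readSummaryStats`.
#' @export
writeSummaryStats <- function(df, path) {
  writeTsv(data.frame(variant_id = df$variantId,
                      effect_allele = df$effectAllele,
                      other_allele = df$otherAllele, eaf = df$eaf,
                      beta = df$beta, se = df$se), path)
}

#' @rdname readSummaryStats
#' @param x an [MRSummaryData-class].
#' @export
writeSummaryPairs <- function(x, path) {
  stopifnot(is(x, "MRSummaryData"))
  d <- as.data.frame(x)
  writeTsv(data.frame(variant_id = d$variantId,
                      effect_allele = d$effectAllele,
                      other_allele = d$otherAllele, eaf = d$eaf,
                      beta_exposure = d$betaExposure,
                      se_exposure = d$seExposure,
                      beta_outcome = d$betaOutcome,
                      se_outcome = d$seOutcome), path)
}

#' @rdname readSummaryStats
#' @export
readSummaryPairs <- function(path) {
  df <- readTsv(path)
  mrSummaryData(df$variant_id, df$effect_allele, df$other_allele, df$eaf,
                df$beta_exposure, df$se_exposure, df$beta_outcome,
                df$se_outcome)
}

#' Read / write one cohort as three TSV files
#'
#' A cohort directory holds `dosages.tsv` (one column per variant),
#' `phenotypes.tsv` and `outcomes.tsv`, all with one row per individual.
#'
#' @param cohort a [CohortData-class].
#' @param dir directory (created if needed).
#' @return `writeCohortData` returns the directory invisibly;
#'   `readCohortData` returns a [CohortData-class].
#' @export
writeCohortData <- function(cohort, dir) {
  stopifnot(is(cohort, "CohortData"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(as.data.frame(dosages(cohort)), file.path(dir, "dosages.tsv"))
  writeTsv(phenotypes(cohort), file.path(dir, "phenotypes.tsv"))
  out <- outcomes(cohort)
  meta <- data.frame(label = cohortLabel(cohort),
                     censor_type = cohort@censorType)
  writeTsv(out, file.path(dir, "outcomes.tsv"))
  writeTsv(meta, file.path(dir, "cohort.tsv"))
  invisible(dir)
}

#' @rdname writeCohortData
#' @export
readCohortData <- function(dir) {
  meta <- readTsv(file.path(dir, "cohort.tsv"))
  dos <- as.matrix(readTsv(file.path(dir, "dosages.tsv")))
  new("CohortData", label = as.character(meta$label[1L]), dosages = dos,
      phenotypes = readTsv(file.path(dir, "phenotypes.tsv")),
      outcomes = readTsv(file.path(dir, "outcomes.tsv")),
      censorType = as.character(meta$censor_type[1L]))
}

#' Read a variant panel TSV
#'
#' Columns: `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#' optionally `chr`, `pos`, `source_study`, `source_rank`.
#'
#' @param path TSV file path.
#' @return a variant panel (see [newVariantPanel()]).
#' @export
readVariantPanel <- function(path) {
  df <- readTsv(path)
  out <- data.frame(variantId = df$variant_id,
                    effectAllele = df$effect_allele,
                    otherAllele = df$other_allele,
                    beta = df$beta, se = df$se, stringsAsFactors = FALSE)
  if (!is.null(df$chr)) out$chr <- df$chr
  if (!is.null(df$pos)) out$pos <- df$pos
  if (!is.null(df$source_study)) out$sourceStudy <- df$source_study
  if (!is.null(df$source_rank)) out$sourceRank <- df$source_rank
  newVariantPanel(out)
}

#' Write a table of causal-effect estimates
#'
#' One row per (cohort, method) with columns `cohort`, `method`,
#' `estimate`, `se`, `ci_lower`, `ci_upper`, `p`, `n`, `n_events`.
#'
#' @param df estimate data.frame (camelCase columns as produced by the
#'   pipeline).
#' @param path TSV file path.
#' @export
writeEstimates <- function(df, path) {
  writeTsv(data.frame(cohort = df$cohort, method = df$method,
                      estimate = df$estimate, se = df$se,
                      ci_lower = df$ciLower, ci_upper = df$ciUpper,
                      p = df$p, n = df$n, n_events = df$nEvents), path)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) {
  df <- readTsv(path)
  data.frame(cohort = df$cohort, method = df$method, estimate = df$estimate,
             se = df$se, ciLower = df$ci_lower, ciUpper = df$ci_upper,
             p = df$p, n = df$n, nEvents = df$n_events,
             stringsAsFactors = FALSE)
}

#' Per-cohort sample sizes and event counts of the consortium study
#'
#' The published per-cohort participant and incident-event counts for the
#' eleven cohorts (discovery and replication arms, CHD and MI outcomes),
#' shipped as a plain-text table. `NA` marks an outcome a cohort did not
#' contribute to.
#'
#' @return data.frame with columns `cohort`, `arm`, `n`, `events_chd`,
#'   `events_mi`.
#' @examples
#' rows <- cohortSummaryTable()
#' table1Consistency(rows, "chd", "discovery")
#' @export
cohortSummaryTable <- function() {
  readTsv(system.file("extdata", "cohort_summary.tsv", package = "fibromr",
                      mustWork = TRUE))
}

#' Sum participants and events over one arm and outcome
#'
#' Restricts the cohort summary rows to those contributing the given
#' outcome in the given arm and sums participants and events; the totals
#' reproduce the study's reported arithmetic.
#'
#' @param rows data.frame as returned by [cohortSummaryTable()].
#' @param outcome `"chd"` or `"mi"`.
#' @param arm `"discovery"`, `"replication"` or `"all"`.
#' @return named numeric vector `c(n = , events = )`.
#' @export
table1Consistency <- function(rows, outcome = c("chd", "mi"),
                              arm = c("discovery", "replication", "all")) {
  outcome <- match.arg(outcome)
  arm <- match.arg(arm)
  stopifnot(all(c("cohort", "arm", "n") %in% names(rows)))
  if (anyDuplicated(rows$cohort)) stop("cohort labels must be unique")
  evcol <- paste0("events_", outcome)
  sel <- !is.na(rows[[evcol]]) & (arm == "all" | rows$arm == arm)
  if (!any(sel)) stop("empty selection: no cohorts match")
  if (any(rows[[evcol]][sel] > rows$n[sel])) stop("events exceed N")
  c(n = sum(rows$n[sel]), events = sum(rows[[evcol]][sel]))
}

#' Bonferroni significance threshold
#'
#' @param nTests number of tests (>= 1).
#' @param alpha familywise level in (0,1).
#' @return list with `threshold` (alpha/nTests at full precision) and
#'   `printed` (rounded to 3 decimal places, the form quoted in reports).
#' @examples
#' bonferroniThreshold(6)$printed  # 0.008
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnotScalar(nTests, "nTests")
  stopifnotScalar(alpha, "alpha")
  if (nTests < 1 || nTests != round(nTests)) stop("nTests must be an integer >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  thr <- alpha / nTests
  list(threshold = thr, printed = round(thr, 3))
}
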