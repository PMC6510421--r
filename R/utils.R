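# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream: the global .Random.seed is
# saved and restored so package randomness never disturbs user state.
withSeed <- function(seed, code) {
  # force the seed BEFORE snapshotting: evaluating a lazy seed expression
  # that itself consumes the global stream must not be rolled back
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Counter-based stream derivation: one explicit master seed, one stream per
# (purpose, counter). Kept strictly below 2^31 - 1.
deriveSeed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 99991 * (as.double(counter) %% 20011)
  as.integer(s %% 2147483647) + 1L
}

Z95 <- 1.96  # 95% CI multiplier, forest-plot convention

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Deterministic full-precision formatting for TSV serialization.
formatNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}
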