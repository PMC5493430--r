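#' @importFrom stats median pchisq p.adjust runif rnorm quantile
#' @importFrom utils read.delim write.table packageVersion
NULL

# Canonical unordered-pair key. Identifier tokens contain no whitespace
# (enforced at read time), so a single space is a safe separator.
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}

splitPairKey <- function(keys) {
  parts <- strsplit(keys, " ", fixed = TRUE)
  data.frame(
    protein_a = vapply(parts, `[`, character(1), 1L),
    protein_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state,
# so corruption experiments do not perturb user-level randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
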