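#' Permute a fraction of interaction confidence scores
#'
#' Chooses `floor(fraction * nPairs)` pairs uniformly without replacement and
#' reassigns each chosen pair a score drawn (with replacement) from the
#' empirical distribution of all original scores. The pair set itself is
#' unchanged. With `shuffle = TRUE`, the chosen pairs' own scores are
#' shuffled among them instead of resampled.
#'
#' @param scores An [InteractionScores-class] object.
#' @param fraction Fraction of pairs to corrupt, in [0, 1].
#' @param seed Integer RNG seed (the caller's RNG state is preserved).
#' @param shuffle Use the value-shuffle variant instead of resampling.
#' @return A new [InteractionScores-class] object.
#' @export
permuteScores <- function(scores, fraction, seed, shuffle = FALSE) {
  stopifnot(is(scores, "InteractionScores"))
  assertScalarNumber(fraction, "fraction", lower = 0, upper = 1)
  n <- nPairs(scores)
  k <- floor(fraction * n)
  if (k == 0L) return(scores)
  s <- scores@scores
  withSeed(seed, {
    pick <- sample.int(n, k)
    s[pick] <- if (shuffle) s[pick][sample.int(k)] else
      sample(unname(scores@scores), k, replace = TRUE)
  })
  new("InteractionScores", scores = s)
}

#' Purge a fraction of interaction pairs
#'
#' Deletes `floor(fraction * nPairs)` pairs chosen uniformly without
#' replacement; surviving scores are unchanged.
#'
#' @inheritParams permuteScores
#' @return A new [InteractionScores-class] object with fewer pairs.
#' @export
purgeScores <- function(scores, fraction, seed) {
  stopifnot(is(scores, "InteractionScores"))
  assertScalarNumber(fraction, "fraction", lower = 0, upper = 1)
  n <- nPairs(scores)
  k <- floor(fraction * n)
  if (k == 0L) return(scores)
  s <- withSeed(seed, scores@scores[-sample.int(n, k)])
  new("InteractionScores", scores = s)
}

#' Score-corruption robustness experiments
#'
#' Re-tests every pathway under repeatedly corrupted interaction scores and
#' reports, per pathway and corruption setting, the percentage of experiments
#' in which the pathway stayed significant at `config@alpha`. The expression
#' profile (and hence each pathway's test vector and qualification mask) is
#' computed once and reused: corrupting the score database alters only the
#' covariance matrices. Experiment e uses seed `baseSeed + e`, so a fixed
#' `baseSeed` reproduces the report bit-identically.
#'
#' @param profile An [ExpressionProfile-class] object.
#' @param collection A [PathwayCollection-class] object.
#' @param scores An [InteractionScores-class] object.
#' @param config A [T2Config-class] object.
#' @param fractions Corruption fractions (default `c(0.3, 0.6)`).
#' @param modes Subset of `c("permuted", "purged")` (default both).
#' @param nExperiments Experiments per (mode, fraction) setting (default 100).
#' @param baseSeed Master seed.
#' @param shuffle Passed to [permuteScores()].
#' @return data.frame with columns pathway_id, original_p, mode, fraction,
#'   n_experiments, retention_pct, ordered by (mode, fraction, pathway_id).
#' @export
robustnessExperiment <- function(profile, collection, scores,
                                 config = t2Config(),
                                 fractions = c(0.3, 0.6),
                                 modes = c("permuted", "purged"),
                                 nExperiments = 100L, baseSeed = 1L,
                                 shuffle = FALSE) {
  modes <- match.arg(modes, c("permuted", "purged"), several.ok = TRUE)
  stopifnot(nExperiments >= 1L)
  baseline <- testAllPathways(profile, collection, scores, config)
  ids <- baseline@table$pathway_id
  xs <- baseline@x
  orders <- baseline@mapped
  originalP <- stats::setNames(baseline@table$p_value, ids)
  pvalFor <- function(corrupted) {
    vapply(ids, function(id) {
      S <- buildCovariance(orders[[id]], xs[[id]], corrupted,
                           config@diagConstant)
      hotellingT2(xs[[id]], S)$p_value
    }, numeric(1))
  }
  out <- list()
  for (mode in modes) {
    for (f in fractions) {
      hits <- stats::setNames(numeric(length(ids)), ids)
      for (e in seq_len(nExperiments)) {
        corrupted <- if (mode == "permuted") {
          permuteScores(scores, f, seed = baseSeed + e, shuffle = shuffle)
        } else {
          purgeScores(scores, f, seed = baseSeed + e)
        }
        p <- pvalFor(corrupted)
        hits <- hits + (p <= config@alpha)
      }
      out[[length(out) + 1L]] <- data.frame(
        pathway_id = ids,
        original_p = unname(originalP[ids]),
        mode = mode, fraction = f,
        n_experiments = as.integer(nExperiments),
        retention_pct = 100 * unname(hits[ids]) / nExperiments,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$mode, rep$fraction, rep$pathway_id), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "baseSeed") <- as.integer(baseSeed)
  rep
}

#' Write a robustness report
#'
#' Tab-separated report of [robustnessExperiment()] output; a comment header
#' records the master seed from which per-experiment seeds were derived.
#'
#' @param report data.frame from [robustnessExperiment()].
#' @param path Output file.
#' @export
writeRobustnessReport <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(report, "baseSeed")
  if (!is.null(seed)) writeLines(sprintf("# base_seed=%d", seed), con)
  report$original_p <- formatC(report$original_p, digits = 9, format = "g")
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
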