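#' Simulation design for synthetic fixtures
#'
#' Bundles the parameters of the synthetic generators: a random scored
#' interaction network, a pathway collection with nested member sets, and
#' expression ratios with a mean shift for perturbed proteins. All generators
#' are pure functions of (design, seed).
#'
#' @param nProteins Number of proteins in the universe.
#' @param edgeDensity Probability that an unordered protein pair carries a
#'   confidence score.
#' @param scoreRange Interval within (0, 1] for uniform scores; default
#'   `c(0.4, 1)` (scores below the STRING medium-confidence cutoff would be
#'   discarded at read time anyway).
#' @param nPathways Number of generated pathways.
#' @param pathwaySize Range of member-set sizes.
#' @param nestedFraction Fraction of pathways generated as strict subsets of
#'   a previously generated pathway (guaranteeing integration test cases).
#' @param effectSize Mean shift, on the log2 scale, of perturbed proteins.
#' @param seed Integer seed fixing every draw.
#' @return A list of class "SimulationDesign".
#' @export
simulationDesign <- function(nProteins = 200L, edgeDensity = 0.05,
                             scoreRange = c(0.4, 1), nPathways = 20L,
                             pathwaySize = c(5L, 30L), nestedFraction = 0.3,
                             effectSize = 2, seed = 1L) {
  stopifnot(nProteins >= 2L, edgeDensity >= 0, edgeDensity <= 1,
            length(scoreRange) == 2L, scoreRange[1] > 0, scoreRange[2] <= 1,
            scoreRange[1] <= scoreRange[2], nPathways >= 1L,
            nestedFraction >= 0, nestedFraction <= 1, effectSize >= 0)
  structure(list(nProteins = as.integer(nProteins),
                 edgeDensity = edgeDensity, scoreRange = scoreRange,
                 nPathways = as.integer(nPathways),
                 pathwaySize = as.integer(pathwaySize),
                 nestedFraction = nestedFraction,
                 effectSize = effectSize, seed = as.integer(seed)),
            class = "SimulationDesign")
}

proteinUniverse <- function(design) {
  sprintf("SP%04d", seq_len(design$nProteins))
}

#' Generate a random scored interaction network
#'
#' Each of the C(n, 2) unordered pairs is included independently with
#' probability `edgeDensity`; included pairs receive scores drawn uniformly
#' on `scoreRange`.
#'
#' @param design A [simulationDesign()] object.
#' @return An [InteractionScores-class] object.
#' @export
generateInteractionNetwork <- function(design) {
  prot <- proteinUniverse(design)
  pairs <- t(utils::combn(prot, 2L))
  withSeed(design$seed, {
    keep <- stats::runif(nrow(pairs)) < design$edgeDensity
    score <- stats::runif(sum(keep), design$scoreRange[1], design$scoreRange[2])
    InteractionScores(pairs[keep, 1L], pairs[keep, 2L], score)
  })
}

#' Generate a pathway collection with nested member sets
#'
#' Member sets are drawn uniformly from the protein universe; a
#' `nestedFraction` share of pathways is instead generated as a strict subset
#' of a previously generated pathway, providing guaranteed delegate/absorbed
#' cases for integration.
#'
#' @param design A [simulationDesign()] object.
#' @return A [PathwayCollection-class] object.
#' @export
generatePathwayCollection <- function(design) {
  prot <- proteinUniverse(design)
  lo <- design$pathwaySize[1L]
  hi <- min(design$pathwaySize[2L], design$nProteins)
  withSeed(design$seed + 1L, {
    members <- vector("list", design$nPathways)
    for (i in seq_len(design$nPathways)) {
      nestable <- i > 1L && any(lengths(members[seq_len(i - 1L)]) > 2L)
      if (nestable && stats::runif(1) < design$nestedFraction) {
        parents <- which(lengths(members[seq_len(i - 1L)]) > 2L)
        parent <- members[[if (length(parents) > 1L)
          sample(parents, 1L) else parents]]
        k <- sample(seq(2L, length(parent) - 1L), 1L)
        members[[i]] <- sort(sample(parent, k))
      } else {
        k <- sample(seq(lo, hi), 1L)
        members[[i]] <- sort(sample(prot, k))
      }
    }
    PathwayCollection(sprintf("pw%03d", seq_len(design$nPathways)),
                      sprintf("synthetic pathway %d", seq_len(design$nPathways)),
                      members)
  })
}

#' Draw multivariate-normal ratio profiles
#'
#' Independent draws from MVN(mean, Sigma) via the Cholesky factor of Sigma.
#'
#' @param Sigma Symmetric positive-definite covariance matrix.
#' @param mean Mean vector (recycled scalar allowed; default 0).
#' @param nSamples Number of draws.
#' @param seed Integer seed.
#' @return Numeric matrix, `nSamples` rows, one column per variable.
#' @export
sampleProfiles <- function(Sigma, mean = 0, nSamples, seed = 1L) {
  q <- nrow(Sigma)
  stopifnot(ncol(Sigma) == q, max(abs(Sigma - t(Sigma))) < 1e-10)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("Sigma is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  }
  R <- chol(Sigma)
  mu <- rep_len(mean, q)
  withSeed(seed, {
    Z <- matrix(stats::rnorm(nSamples * q), nrow = nSamples)
    sweep(Z %*% R, 2L, mu, "+")
  })
}

#' Positive-definite version of a rule-built covariance
#'
#' Builds S by the four covariance rules and, when its smallest eigenvalue
#' is non-positive (possible because off-diagonal confidence scores may
#' exceed the diagonal constant), shifts the whole diagonal upward by
#' |lambda_min| + 1e-6. Needed by calibration studies, which must draw from
#' a genuine covariance.
#'
#' @param order Character vector of proteins (row/column order).
#' @param scores An [InteractionScores-class] object.
#' @param xSigns Numeric vector giving the expression directions used for
#'   the sign rules (only its signs matter).
#' @param diagConstant Diagonal constant.
#' @return The adjusted positive-definite matrix, with attribute `shift`
#'   giving the diagonal shift applied (0 when S was already PD).
#' @export
makePsdRulebookSigma <- function(order, scores, xSigns, diagConstant = 0.4) {
  S <- buildCovariance(order, xSigns, scores, diagConstant)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  shift <- if (min(ev) <= 0) abs(min(ev)) + 1e-6 else 0
  if (shift > 0) S <- S + diag(shift, nrow(S))
  attr(S, "shift") <- shift
  S
}

#' Equicorrelation calibration preset
#'
#' The reference design for the chi-squared calibration demonstration: 20
#' variables, covariance with unit diagonal and all off-diagonal entries
#' 0.5 (positive definite: eigenvalues 10.5 and 0.5), 10000 samples. Data
#' drawn from this Sigma and evaluated with the same Sigma follow chi-squared
#' with 20 degrees of freedom exactly; evaluated with the identity instead,
#' the statistic is miscalibrated.
#'
#' @param q Number of variables (default 20).
#' @param rho Common correlation (default 0.5).
#' @param nSamples Number of simulation draws (default 10000).
#' @return List with `Sigma`, `q`, `rho`, `nSamples`.
#' @export
calibrationPreset <- function(q = 20L, rho = 0.5, nSamples = 10000L) {
  Sigma <- matrix(rho, q, q)
  diag(Sigma) <- 1
  list(Sigma = Sigma, q = as.integer(q), rho = rho,
       nSamples = as.integer(nSamples))
}

#' Monte-Carlo rejection rate of the statistic under a simulated null
#'
#' Draws `nSamples` profiles from MVN(0, `SigmaData`), evaluates the
#' statistic of every draw against `SigmaEval` (degrees of freedom and
#' pseudoinverse handling exactly as in [hotellingT2()]; the factorization is
#' computed once since the evaluation matrix is fixed), and reports the
#' fraction of draws rejected at level `alpha`.
#'
#' @param SigmaData Positive-definite covariance generating the data.
#' @param SigmaEval Covariance matrix the statistic assumes.
#' @param nSamples Number of draws.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List with `rejectionRate`, `T2` (vector), `df`, `mcse` (the
#'   binomial Monte-Carlo standard error of the rate at `alpha`).
#' @export
calibrationExperiment <- function(SigmaData, SigmaEval, nSamples = 10000L,
                                  alpha = 0.05, seed = 1L) {
  X <- sampleProfiles(SigmaData, mean = 0, nSamples = nSamples, seed = seed)
  q <- ncol(X)
  rk <- numericRank(SigmaEval)
  degenerate <- rk < q
  Sinv <- if (degenerate) MASS::ginv(SigmaEval) else solve(SigmaEval)
  df <- if (degenerate) rk else q
  T2 <- rowSums((X %*% Sinv) * X)
  pvals <- stats::pchisq(T2, df = df, lower.tail = FALSE)
  pvals[T2 < 0] <- 1
  list(rejectionRate = mean(pvals <= alpha), T2 = T2, df = df,
       mcse = sqrt(alpha * (1 - alpha) / nSamples))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates an interaction network, a nested pathway collection, and an
#' expression table in which the members of the first pathway are perturbed
#' (log2 ratios centred at `effectSize`, everything else at 0, unit noise),
#' then writes them as expression TSV (fold scale), GMT, PPI TSV and a JSON
#' manifest recording the design and seed.
#'
#' @param design A [simulationDesign()] object.
#' @param dir Output directory (created if needed).
#' @return Named list of the written file paths (expression, geneSets, ppi,
#'   manifest), invisibly.
#' @export
writeFixtureBundle <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores <- generateInteractionNetwork(design)
  collection <- generatePathwayCollection(design)
  prot <- proteinUniverse(design)
  perturbed <- pathwayMembers(collection, pathwayIds(collection)[1L])
  mu <- ifelse(prot %in% perturbed, design$effectSize, 0)
  log2ratio <- withSeed(design$seed + 2L, stats::rnorm(length(prot), mu, 1))
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    geneSets = file.path(dir, "pathways.gmt"),
    ppi = file.path(dir, "ppi_scores.tsv"),
    manifest = file.path(dir, "fixture_manifest.json")
  )
  writeLines(sprintf("%s\t%.10g", prot, 2^log2ratio), paths$expression)
  writeGmt(collection, paths$geneSets)
  writeInteractionScores(scores, paths$ppi)
  jsonlite::write_json(
    list(generator = "pathT2::writeFixtureBundle",
         design = unclass(design), perturbed_pathway = pathwayIds(collection)[1L]),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
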