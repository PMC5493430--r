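#' Run the full pathway-analysis pipeline
#'
#' Reads the expression table, gene sets and interaction scores, builds the
#' processed profile, tests every pathway, integrates the results into
#' delegate-led groups, and writes the results table, the groups table and a
#' JSON run manifest (tool version, configuration echo, input digests, and
#' record/pathway/group counts). Re-running with identical inputs and
#' configuration reproduces the outputs byte-identically.
#'
#' @param expression Path to the expression-ratio table.
#' @param geneSets Path to the gene-set input.
#' @param dialect Gene-set dialect ("gmt", "kgml" or "reactome").
#' @param ppi Path to the interaction-score table.
#' @param idMap Optional path to an identifier-mapping table.
#' @param outDir Output directory (created if needed).
#' @param config A [T2Config-class] object.
#' @return Named list with the result objects (`profile`, `results`,
#'   `groups`) and the written paths (`resultsFile`, `groupsFile`,
#'   `manifestFile`).
#' @export
runPathwayAnalysis <- function(expression, geneSets, dialect = "gmt", ppi,
                               idMap = NULL, outDir = ".",
                               config = t2Config()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  records <- readExpressionTable(expression,
                                 alreadyLogged = config@alreadyLogged)
  collection <- readGeneSets(geneSets, dialect = dialect)
  scores <- readInteractionScores(ppi, minScore = config@minScore)
  mapping <- if (!is.null(idMap)) readIdMapping(idMap) else NULL
  profile <- buildProfile(records, mapping = mapping, config = config)
  results <- testAllPathways(profile, collection, scores, config)
  groups <- integratePathways(results,
                              qualifiedOnly = config@qualifiedOnlySubsets)
  resultsFile <- file.path(outDir, "results.tsv")
  groupsFile <- file.path(outDir, "groups.tsv")
  manifestFile <- file.path(outDir, "run_manifest.json")
  writeResults(results, resultsFile, groups = groups)
  writeGroups(groups, groupsFile)
  writeRunManifest(manifestFile, config = config,
                   inputs = c(expression = expression, gene_sets = geneSets,
                              ppi = ppi,
                              if (!is.null(idMap)) c(id_map = idMap)),
                   counts = list(
                     records_read = length(records) + profile@nDropped,
                     records_dropped = profile@nDropped,
                     proteins = length(profileValues(profile)),
                     pathways_tested = nrow(resultTable(results)),
                     pathways_unmapped = length(results@unmapped),
                     groups = nrow(resultTable(groups)),
                     groups_retained = sum(resultTable(groups)$retained)
                   ))
  list(profile = profile, results = results, groups = groups,
       resultsFile = resultsFile, groupsFile = groupsFile,
       manifestFile = manifestFile)
}

writeRunManifest <- function(path, config, inputs, counts, seed = NULL) {
  manifest <- list(
    tool = "pathT2",
    version = as.character(utils::packageVersion("pathT2")),
    config = list(
      winsor_threshold = config@winsorThreshold,
      fold_threshold = config@foldThreshold,
      already_logged = config@alreadyLogged,
      diag_constant = config@diagConstant,
      alpha = config@alpha,
      min_score = config@minScore,
      qualified_only_subsets = config@qualifiedOnlySubsets
    ),
    inputs = lapply(as.list(inputs), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    counts = counts
  )
  if (!is.null(seed)) manifest$seed <- seed
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run robustness experiments from input files
#'
#' File-level wrapper around [robustnessExperiment()]: reads the same inputs
#' as [runPathwayAnalysis()], runs the corruption experiments, and writes the
#' retention report plus a manifest.
#'
#' @inheritParams runPathwayAnalysis
#' @param fractions,modes,nExperiments,baseSeed See [robustnessExperiment()].
#' @return Named list with `report` (data.frame) and `reportFile`.
#' @export
runRobustness <- function(expression, geneSets, dialect = "gmt", ppi,
                          idMap = NULL, outDir = ".", config = t2Config(),
                          fractions = c(0.3, 0.6),
                          modes = c("permuted", "purged"),
                          nExperiments = 100L, baseSeed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  records <- readExpressionTable(expression,
                                 alreadyLogged = config@alreadyLogged)
  collection <- readGeneSets(geneSets, dialect = dialect)
  scores <- readInteractionScores(ppi, minScore = config@minScore)
  mapping <- if (!is.null(idMap)) readIdMapping(idMap) else NULL
  profile <- buildProfile(records, mapping = mapping, config = config)
  report <- robustnessExperiment(profile, collection, scores, config,
                                 fractions = fractions, modes = modes,
                                 nExperiments = nExperiments,
                                 baseSeed = baseSeed)
  reportFile <- file.path(outDir, "robustness.tsv")
  writeRobustnessReport(report, reportFile)
  manifestFile <- file.path(outDir, "robustness_manifest.json")
  writeRunManifest(manifestFile, config = config,
                   inputs = c(expression = expression, gene_sets = geneSets,
                              ppi = ppi,
                              if (!is.null(idMap)) c(id_map = idMap)),
                   counts = list(
                     pathways = length(unique(report$pathway_id)),
                     settings = nrow(unique(report[c("mode", "fraction")])),
                     n_experiments = nExperiments
                   ),
                   seed = baseSeed)
  list(report = report, reportFile = reportFile, manifestFile = manifestFile)
}
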