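#' @import methods
NULL

#' Symmetric protein-protein interaction confidence scores
#'
#' Stores a symmetric map from unordered protein pairs to confidence scores in
#' (0, 1]. Pairs are keyed canonically (lexicographically smaller protein
#' first), so looking up (a, b) and (b, a) returns the same value by
#' construction. Self-pairs are disallowed.
#'
#' @slot scores Named numeric vector; names are canonical pair keys.
#'
#' @seealso [readInteractionScores()], [scoreLookup()], [permuteScores()]
#' @export
setClass("InteractionScores", representation(scores = "numeric"))

setValidity("InteractionScores", function(object) {
  s <- object@scores
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || anyNA(s)) {
    return("scores must be a named numeric vector without NAs")
  }
  if (any(s <= 0 | s > 1)) return("all scores must lie in (0, 1]")
  pr <- splitPairKey(names(s))
  if (any(pr$protein_a == pr$protein_b)) return("self-pairs are not allowed")
  if (any(pr$protein_a > pr$protein_b)) return("pair keys must be canonical")
  if (anyDuplicated(names(s))) return("duplicate pairs")
  TRUE
})

#' Construct an InteractionScores object from pair vectors
#'
#' Duplicate pairs (in either orientation) are collapsed keeping the maximum
#' score; self-pairs are dropped.
#'
#' @param proteinA,proteinB Character vectors of interaction partners.
#' @param score Numeric vector of confidence scores in (0, 1].
#' @return An [InteractionScores-class] object.
#' @export
InteractionScores <- function(proteinA = character(), proteinB = character(),
                              score = numeric()) {
  stopifnot(length(proteinA) == length(proteinB),
            length(proteinA) == length(score))
  keep <- proteinA != proteinB
  key <- pairKey(proteinA[keep], proteinB[keep])
  score <- score[keep]
  if (length(key)) {
    score <- vapply(split(score, key), max, numeric(1))
    score <- score[sort(names(score))]
  } else {
    score <- numeric()
  }
  new("InteractionScores", scores = score)
}

#' A collection of named pathways
#'
#' Pathway membership sets over protein accessions, as read from GMT, KGML or
#' Reactome-style inputs or generated synthetically.
#'
#' @slot ids Character vector of unique pathway identifiers.
#' @slot titles Character vector of display titles (parallel to `ids`).
#' @slot members List of character vectors of member accessions (parallel to
#'   `ids`; each non-empty, no duplicates within a pathway).
#'
#' @seealso [readGeneSets()], [generatePathwayCollection()]
#' @export
setClass("PathwayCollection",
         representation(ids = "character", titles = "character",
                        members = "list"))

setValidity("PathwayCollection", function(object) {
  n <- length(object@ids)
  if (length(object@titles) != n || length(object@members) != n) {
    return("ids, titles and members must have equal length")
  }
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@ids)) return("pathway ids must be unique")
  if (any(!nzchar(object@ids))) return("pathway ids must be non-empty")
  ok <- vapply(object@members, function(m) {
    is.character(m) && length(m) > 0L && !anyDuplicated(m) && all(nzchar(m))
  }, logical(1))
  if (!all(ok)) return("each member set must be a non-empty character vector")
  TRUE
})

#' @rdname PathwayCollection-class
#' @param ids,titles,members See the slot descriptions.
#' @return A [PathwayCollection-class] object.
#' @export
PathwayCollection <- function(ids, titles = ids, members) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  names(members) <- ids
  new("PathwayCollection", ids = as.character(ids),
      titles = as.character(titles), members = members)
}

#' Processed per-protein expression profile
#'
#' Holds the standardized log2 expression ratios together with the
#' pre-standardization log2 ratios and the fold-change qualification mask.
#' The three maps share an identical key set.
#'
#' @slot values Named numeric vector of standardized log2 ratios.
#' @slot rawLog2 Named numeric vector of winsorized, pre-standardization
#'   log2 ratios.
#' @slot qualified Named logical vector: TRUE where |rawLog2| >=
#'   log2(fold threshold), i.e. the protein's direction enters the test
#'   vector; unqualified proteins contribute zero.
#' @slot nDropped Number of input records dropped during preprocessing.
#'
#' @seealso [buildProfile()]
#' @export
setClass("ExpressionProfile",
         representation(values = "numeric", rawLog2 = "numeric",
                        qualified = "logical", nDropped = "integer"))

setValidity("ExpressionProfile", function(object) {
  nm <- names(object@values)
  if (is.null(nm) || anyDuplicated(nm)) {
    return("values must be uniquely named by accession")
  }
  if (!identical(nm, names(object@rawLog2)) ||
      !identical(nm, names(object@qualified))) {
    return("values, rawLog2 and qualified must share identical names")
  }
  TRUE
})

#' Analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults: winsorization
#' threshold 10 on the log2 scale, fold-change qualification threshold 1.5 on
#' the fold scale, diagonal constant 0.4 (the STRING "medium confidence"
#' level), minimum retained interaction score 0.4, significance level 0.05.
#'
#' @slot winsorThreshold Positive real, log2 scale.
#' @slot foldThreshold Real >= 1, fold scale.
#' @slot alreadyLogged Whether input ratios are already log2 values.
#' @slot diagConstant Diagonal of the rule-built covariance, in (0, 1].
#' @slot alpha Significance level in (0, 1).
#' @slot minScore Minimum interaction confidence kept at read time.
#' @slot qualifiedOnlySubsets If TRUE, pathway-group subset relations are
#'   evaluated on qualified (non-zero) proteins only, rather than on all
#'   mapped proteins.
#' @export
setClass("T2Config",
         representation(winsorThreshold = "numeric", foldThreshold = "numeric",
                        alreadyLogged = "logical", diagConstant = "numeric",
                        alpha = "numeric", minScore = "numeric",
                        qualifiedOnlySubsets = "logical"))

setValidity("T2Config", function(object) {
  if (object@winsorThreshold <= 0) return("winsorThreshold must be > 0")
  if (object@foldThreshold < 1) return("foldThreshold must be >= 1")
  if (object@diagConstant <= 0 || object@diagConstant > 1) {
    return("diagConstant must be in (0, 1]")
  }
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  if (object@minScore < 0 || object@minScore > 1) {
    return("minScore must be in [0, 1]")
  }
  TRUE
})

#' @rdname T2Config-class
#' @param winsorThreshold,foldThreshold,alreadyLogged,diagConstant,alpha,minScore,qualifiedOnlySubsets
#'   See the slot descriptions.
#' @return A validated [T2Config-class] object.
#' @export
t2Config <- function(winsorThreshold = 10, foldThreshold = 1.5,
                     alreadyLogged = FALSE, diagConstant = 0.4,
                     alpha = 0.05, minScore = 0.4,
                     qualifiedOnlySubsets = FALSE) {
  new("T2Config", winsorThreshold = winsorThreshold,
      foldThreshold = foldThreshold, alreadyLogged = alreadyLogged,
      diagConstant = diagConstant, alpha = alpha, minScore = minScore,
      qualifiedOnlySubsets = qualifiedOnlySubsets)
}

#' Per-pathway test results
#'
#' One row per mapped pathway with the rule-built covariance diagnostics:
#' number of mapped proteins, numeric rank of S (the chi-squared degrees of
#' freedom), the T2 statistic, its p-value, a Benjamini-Hochberg adjusted
#' p-value (reported for convenience; the delegate-retention decision uses the
#' raw p-value), and flags for the pseudoinverse (degenerate S) and indefinite
#' (negative T2) paths.
#'
#' @slot table data.frame with columns pathway_id, title, n_mapped, rank_q,
#'   T2, p_value, p_adjust, degenerate, indefinite.
#' @slot mapped Named list (by pathway_id) of mapped accessions.
#' @slot qualifiedMembers Named list of the mapped accessions that passed the
#'   fold-change qualification.
#' @slot x Named list of the test vectors (standardized ratios, unqualified
#'   entries zeroed), each named by accession in covariance order.
#' @slot unmapped Character vector of pathway ids with no mapped member.
#' @slot alpha Significance level the run used.
#' @export
setClass("PathwayTestResults",
         representation(table = "data.frame", mapped = "list",
                        qualifiedMembers = "list", x = "list",
                        unmapped = "character", alpha = "numeric"))

setValidity("PathwayTestResults", function(object) {
  need <- c("pathway_id", "title", "n_mapped", "rank_q", "T2", "p_value",
            "p_adjust", "degenerate", "indefinite")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  ids <- object@table$pathway_id
  if (anyDuplicated(ids)) return("duplicate pathway ids")
  if (length(ids) && (!identical(names(object@mapped), ids) ||
                      !identical(names(object@x), ids))) {
    return("mapped and x must be named by the table's pathway ids, in order")
  }
  p <- object@table$p_value
  if (length(p) && (any(p < 0) || any(p > 1))) return("p-values outside [0, 1]")
  if (any(object@table$rank_q > object@table$n_mapped)) {
    return("rank_q cannot exceed n_mapped")
  }
  TRUE
})

#' Delegate-led pathway groups
#'
#' The outcome of pathway integration: each group has a delegate pathway whose
#' mapped-protein set is a superset of every member's, and is retained iff the
#' delegate's p-value is at most alpha. Groups partition the tested pathways.
#'
#' @slot table data.frame with columns delegate_id, delegate_p, n_members,
#'   retained.
#' @slot members Named list (by delegate_id) of member pathway ids, delegate
#'   first.
#' @slot alpha Significance level used for retention.
#' @export
setClass("PathwayGroups",
         representation(table = "data.frame", members = "list",
                        alpha = "numeric"))

setValidity("PathwayGroups", function(object) {
  need <- c("delegate_id", "delegate_p", "n_members", "retained")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(object@table) &&
      !identical(names(object@members), object@table$delegate_id)) {
    return("members must be named by delegate_id, in table order")
  }
  firsts <- vapply(object@members, function(m) m[[1L]], character(1))
  if (length(firsts) && !identical(unname(firsts), object@table$delegate_id)) {
    return("each member list must start with its delegate")
  }
  all_ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_ids)) return("groups must be pairwise disjoint")
  TRUE
})

setMethod("show", "InteractionScores", function(object) {
  s <- object@scores
  cat(sprintf("InteractionScores with %d pair(s)\n", length(s)))
  if (length(s)) {
    cat(sprintf("  score range: [%.3g, %.3g]\n", min(s), max(s)))
  }
})

setMethod("show", "PathwayCollection", function(object) {
  cat(sprintf("PathwayCollection with %d pathway(s)\n", length(object@ids)))
  if (length(object@ids)) {
    sizes <- lengths(object@members)
    cat(sprintf("  member-set sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  }
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile with %d protein(s), %d qualified, %d record(s) dropped\n",
              length(object@values), sum(object@qualified), object@nDropped))
})

setMethod("show", "PathwayTestResults", function(object) {
  tab <- object@table
  cat(sprintf("PathwayTestResults: %d tested, %d unmapped, %d significant at alpha = %g\n",
              nrow(tab), length(object@unmapped),
              sum(tab$p_value <= object@alpha), object@alpha))
  if (nrow(tab)) {
    print(utils::head(tab[order(tab$p_value, tab$pathway_id),
                          c("pathway_id", "n_mapped", "rank_q", "T2", "p_value")],
                      6L), row.names = FALSE)
  }
})

setMethod("show", "PathwayGroups", function(object) {
  cat(sprintf("PathwayGroups: %d group(s), %d retained at alpha = %g\n",
              nrow(object@table), sum(object@table$retained), object@alpha))
})
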