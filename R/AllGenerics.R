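#' Number of stored interaction pairs
#' @param x An [InteractionScores-class] object.
#' @return Integer count of unordered pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "InteractionScores", function(x) length(x@scores))

#' Look up confidence scores for protein pairs
#'
#' Symmetric lookup: `scoreLookup(x, a, b)` and `scoreLookup(x, b, a)` are
#' identical. Vectorized over `a`/`b`.
#'
#' @param x An [InteractionScores-class] object.
#' @param a,b Character vectors of protein accessions (recycled to a common
#'   length).
#' @return Numeric vector of scores, `NA` where the pair is not stored.
#' @export
setGeneric("scoreLookup", function(x, a, b) standardGeneric("scoreLookup"))

#' @rdname scoreLookup
#' @export
setMethod("scoreLookup", "InteractionScores", function(x, a, b) {
  unname(x@scores[pairKey(a, b)])
})

#' Interaction pairs as a data frame
#' @param x An [InteractionScores-class] object.
#' @return data.frame with columns protein_a, protein_b, score (canonical
#'   orientation, sorted by key).
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "InteractionScores", function(x) {
  if (!length(x@scores)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- splitPairKey(names(x@scores))
  out$score <- unname(x@scores)
  out
})

#' Pathway ids of a collection
#' @param x A [PathwayCollection-class] object.
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname pathwayIds
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x) x@ids)

#' Pathway titles of a collection
#' @param x A [PathwayCollection-class] object.
#' @export
setGeneric("pathwayTitles", function(x) standardGeneric("pathwayTitles"))

#' @rdname pathwayTitles
#' @export
setMethod("pathwayTitles", "PathwayCollection", function(x) {
  stats::setNames(x@titles, x@ids)
})

#' Member accessions of one or all pathways
#' @param x A [PathwayCollection-class] object.
#' @param id Optional single pathway id; if omitted, the full named list.
#' @export
setGeneric("pathwayMembers", function(x, id) standardGeneric("pathwayMembers"))

#' @rdname pathwayMembers
#' @export
setMethod("pathwayMembers", "PathwayCollection", function(x, id) {
  if (missing(id)) return(x@members)
  if (!id %in% x@ids) stop("unknown pathway id: ", id, call. = FALSE)
  x@members[[id]]
})

#' Standardized expression values of a profile
#' @param x An [ExpressionProfile-class] object.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname profileValues
#' @export
setMethod("profileValues", "ExpressionProfile", function(x) x@values)

#' Pre-standardization (winsorized) log2 ratios of a profile
#' @param x An [ExpressionProfile-class] object.
#' @export
setGeneric("profileRawLog2", function(x) standardGeneric("profileRawLog2"))

#' @rdname profileRawLog2
#' @export
setMethod("profileRawLog2", "ExpressionProfile", function(x) x@rawLog2)

#' Fold-change qualification mask of a profile
#' @param x An [ExpressionProfile-class] object.
#' @export
setGeneric("profileQualified", function(x) standardGeneric("profileQualified"))

#' @rdname profileQualified
#' @export
setMethod("profileQualified", "ExpressionProfile", function(x) x@qualified)

#' Result table accessor
#' @param x A [PathwayTestResults-class] or [PathwayGroups-class] object.
#' @return The underlying data.frame.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname resultTable
#' @export
setMethod("resultTable", "PathwayTestResults", function(x) x@table)

#' @rdname resultTable
#' @export
setMethod("resultTable", "PathwayGroups", function(x) x@table)

#' Mapped accessions per tested pathway
#' @param x A [PathwayTestResults-class] object.
#' @export
setGeneric("mappedMembers", function(x) standardGeneric("mappedMembers"))

#' @rdname mappedMembers
#' @export
setMethod("mappedMembers", "PathwayTestResults", function(x) x@mapped)

#' Member pathway ids per group (delegate first)
#' @param x A [PathwayGroups-class] object.
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname groupMembers
#' @export
setMethod("groupMembers", "PathwayGroups", function(x) x@members)
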