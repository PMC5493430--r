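#' Inclusive subset relation on accession sets
#'
#' @param a,b Character vectors (treated as sets).
#' @return TRUE iff every element of `a` is in `b` (equality counts).
#' @export
isSubsetOf <- function(a, b) {
  all(a %in% b)
}

#' Collapse tested pathways into delegate-led pathway groups
#'
#' Greedy integration over the mapped-protein sets: repeatedly pick the
#' remaining pathway with the largest mapped set (ties broken by
#' lexicographic pathway id) as a delegate, absorb every remaining pathway
#' whose mapped set is an inclusive subset of the delegate's, and remove the
#' group from the pool. A pathway absorbed by a delegate is never revisited,
#' even when the delegate turns out non-significant. After the pool is
#' exhausted, a group is marked retained iff its delegate's p-value is at
#' most `alpha`. All groups are returned, retained or not; together they
#' partition the tested pathways.
#'
#' The rationale: a pathway whose expressed proteins are all shared with a
#' larger pathway shows no distinctive protein of its own, so its
#' significance may simply be inherited from the larger pathway's regulation.
#'
#' @param results A [PathwayTestResults-class] object.
#' @param alpha Significance level; defaults to the level stored in
#'   `results`. The raw p-value is used (no multiplicity adjustment).
#' @param qualifiedOnly If TRUE, subset relations are evaluated on the
#'   qualified (non-zero) mapped proteins instead of all mapped proteins.
#' @return A [PathwayGroups-class] object, groups ordered by size
#'   (descending) then delegate id.
#' @export
integratePathways <- function(results, alpha = NULL, qualifiedOnly = FALSE) {
  stopifnot(is(results, "PathwayTestResults"))
  if (is.null(alpha)) alpha <- results@alpha
  assertScalarNumber(alpha, "alpha", lower = 0, upper = 1)
  sets <- if (qualifiedOnly) results@qualifiedMembers else results@mapped
  pvals <- stats::setNames(results@table$p_value, results@table$pathway_id)
  pool <- names(sets)
  delegates <- character()
  members <- list()
  while (length(pool)) {
    sizes <- lengths(sets[pool])
    cand <- pool[sizes == max(sizes)]
    dg <- min(cand)  # lexicographic tie-break
    pool <- setdiff(pool, dg)
    absorbed <- pool[vapply(pool, function(p) {
      isSubsetOf(sets[[p]], sets[[dg]])
    }, logical(1))]
    pool <- setdiff(pool, absorbed)
    delegates <- c(delegates, dg)
    members <- c(members, list(c(dg, sort(absorbed))))
  }
  names(members) <- delegates
  tab <- data.frame(
    delegate_id = delegates,
    delegate_p = unname(pvals[delegates]),
    n_members = lengths(members),
    retained = unname(pvals[delegates] <= alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(-tab$n_members, tab$delegate_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  new("PathwayGroups", table = tab, members = members[ord], alpha = alpha)
}

#' Write a pathway-group table
#'
#' Tab-separated columns: delegate_id, delegate_p, retained, member_ids
#' (comma-joined, delegate first).
#'
#' @param groups A [PathwayGroups-class] object.
#' @param path Output file.
#' @export
writeGroups <- function(groups, path) {
  stopifnot(is(groups, "PathwayGroups"))
  tab <- groups@table
  out <- data.frame(
    delegate_id = tab$delegate_id,
    delegate_p = formatC(tab$delegate_p, digits = 9, format = "g"),
    retained = tab$retained,
    member_ids = vapply(groups@members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
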