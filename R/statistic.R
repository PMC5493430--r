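#' Map an expression profile onto a pathway
#'
#' Intersects the pathway's member set with the profile's accessions. The
#' mapped members are ordered lexicographically (fixing row/column order of
#' the covariance matrix); the test vector carries the standardized ratio for
#' qualified proteins and exactly zero for unqualified ones, which stay in the
#' mapping.
#'
#' @param profile An [ExpressionProfile-class] object.
#' @param members Character vector of pathway member accessions.
#' @return List with `order` (character) and `x` (named numeric), or NULL if
#'   no member is present in the profile.
#' @export
mapProfileToPathway <- function(profile, members) {
  stopifnot(is(profile, "ExpressionProfile"))
  ord <- sort(intersect(members, names(profile@values)))
  if (!length(ord)) return(NULL)
  x <- ifelse(profile@qualified[ord], profile@values[ord], 0)
  names(x) <- ord
  list(order = ord, x = x)
}

#' Build the knowledge-based covariance matrix for one pathway
#'
#' The q x q matrix S over the mapped proteins is filled by four rules:
#' diagonal entries are the constant `diagConstant` (default 0.4, STRING's
#' medium-confidence level, expressing the confidence placed in the data
#' itself); an off-diagonal entry for a pair with a stored confidence score c
#' is +c when the two ratios do not disagree in sign (x_i * x_j >= 0, so a
#' zeroed, unqualified protein never induces a negative entry) and -c when
#' they have opposite signs; pairs without a stored score get 0.
#'
#' @param order Character vector of mapped accessions (row/column order).
#' @param x Numeric test vector aligned with `order`.
#' @param scores An [InteractionScores-class] object.
#' @param diagConstant Diagonal constant in (0, 1].
#' @return Symmetric numeric matrix with dimnames `order`.
#' @export
buildCovariance <- function(order, x, scores, diagConstant = 0.4) {
  stopifnot(is(scores, "InteractionScores"), length(order) == length(x),
            length(order) >= 1L)
  assertScalarNumber(diagConstant, "diagConstant",
                     lower = .Machine$double.eps, upper = 1)
  q <- length(order)
  S <- diag(diagConstant, q)
  dimnames(S) <- list(order, order)
  if (q > 1L && nPairs(scores) > 0L) {
    idx <- which(upper.tri(S), arr.ind = TRUE)
    c_ij <- scoreLookup(scores, order[idx[, 1L]], order[idx[, 2L]])
    hit <- !is.na(c_ij)
    if (any(hit)) {
      sgn <- ifelse(x[idx[hit, 1L]] * x[idx[hit, 2L]] >= 0, 1, -1)
      vals <- sgn * c_ij[hit]
      S[idx[hit, , drop = FALSE]] <- vals
      S[idx[hit, c(2L, 1L), drop = FALSE]] <- vals
    }
  }
  S
}

#' Numeric rank of a symmetric matrix
#'
#' Counts singular values exceeding `relTol` times the largest singular
#' value. The default tolerance is 1e-10 times the matrix dimension.
#'
#' @param S Symmetric numeric matrix.
#' @param relTol Relative tolerance; default `1e-10 * nrow(S)`.
#' @return Integer rank.
#' @export
numericRank <- function(S, relTol = NULL) {
  if (is.null(relTol)) relTol <- 1e-10 * nrow(S)
  sv <- svd(S, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > relTol * max(sv))
}

#' Hotelling-type statistic with chi-squared reference
#'
#' Computes T2 = x' S^-1 x and refers it to a chi-squared distribution. When
#' S is numerically nonsingular the degrees of freedom equal its dimension;
#' when S is degenerate the Moore-Penrose pseudoinverse replaces the inverse
#' and the degrees of freedom become the numeric rank of S. Because the
#' rule-built S need not be positive semidefinite, T2 can come out negative;
#' such results are flagged `indefinite` and assigned p = 1 rather than a
#' fabricated significance.
#'
#' @param x Numeric vector aligned with S.
#' @param S Symmetric numeric matrix.
#' @return List with `T2`, `rank_q`, `p_value`, `degenerate`, `indefinite`.
#' @export
hotellingT2 <- function(x, S) {
  stopifnot(length(x) == nrow(S), nrow(S) == ncol(S))
  q <- length(x)
  rk <- numericRank(S)
  if (rk == 0L) {
    return(list(T2 = 0, rank_q = 0L, p_value = 1,
                degenerate = TRUE, indefinite = FALSE))
  }
  degenerate <- rk < q
  Sinv <- if (degenerate) MASS::ginv(S) else solve(S)
  T2 <- drop(crossprod(x, Sinv %*% x))
  df <- if (degenerate) rk else q
  indefinite <- T2 < 0
  p <- if (indefinite) 1 else stats::pchisq(T2, df = df, lower.tail = FALSE)
  list(T2 = T2, rank_q = as.integer(df), p_value = p,
       degenerate = degenerate, indefinite = indefinite)
}

#' Test one pathway
#'
#' Maps the profile to the pathway, builds the knowledge-based covariance,
#' and evaluates the statistic. Returns NULL for an unmapped pathway (no
#' member present in the profile); callers skip those.
#'
#' @param profile An [ExpressionProfile-class] object.
#' @param members Character vector of pathway member accessions.
#' @param scores An [InteractionScores-class] object.
#' @param config A [T2Config-class] object (`diagConstant` is consumed here).
#' @return List with `order`, `x`, `S`, and the [hotellingT2()] fields, or
#'   NULL if unmapped.
#' @export
testPathway <- function(profile, members, scores, config = t2Config()) {
  m <- mapProfileToPathway(profile, members)
  if (is.null(m)) return(NULL)
  S <- buildCovariance(m$order, m$x, scores, config@diagConstant)
  c(m, list(S = S), hotellingT2(m$x, S))
}

#' Test every pathway of a collection
#'
#' Runs [testPathway()] over the collection. Pathways with no mapped member
#' are recorded in the `unmapped` slot. P-values are raw (no multiplicity
#' adjustment is applied to the significance decision; a Benjamini-Hochberg
#' column is reported alongside for reference).
#'
#' @param profile An [ExpressionProfile-class] object.
#' @param collection A [PathwayCollection-class] object.
#' @param scores An [InteractionScores-class] object.
#' @param config A [T2Config-class] object.
#' @return A [PathwayTestResults-class] object (rows in collection order,
#'   normalized to lexicographic pathway id).
#' @export
testAllPathways <- function(profile, collection, scores,
                            config = t2Config()) {
  stopifnot(is(collection, "PathwayCollection"))
  if (!length(collection@ids)) stop("empty pathway collection", call. = FALSE)
  ids <- sort(collection@ids)
  titles <- stats::setNames(collection@titles, collection@ids)[ids]
  fits <- lapply(ids, function(id) {
    testPathway(profile, collection@members[[id]], scores, config)
  })
  names(fits) <- ids
  mappedMask <- !vapply(fits, is.null, logical(1))
  unmapped <- ids[!mappedMask]
  if (any(!mappedMask)) {
    message(sum(!mappedMask), " pathway(s) had no mapped protein and were skipped")
  }
  fits <- fits[mappedMask]
  ids <- ids[mappedMask]
  tab <- data.frame(
    pathway_id = ids,
    title = unname(titles[ids]),
    n_mapped = vapply(fits, function(f) length(f$order), integer(1)),
    rank_q = vapply(fits, `[[`, integer(1), "rank_q"),
    T2 = vapply(fits, `[[`, numeric(1), "T2"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    indefinite = vapply(fits, `[[`, logical(1), "indefinite"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$p_adjust <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- tab[, c("pathway_id", "title", "n_mapped", "rank_q", "T2",
                 "p_value", "p_adjust", "degenerate", "indefinite")]
  qual <- lapply(fits, function(f) f$order[profile@qualified[f$order]])
  new("PathwayTestResults", table = tab,
      mapped = lapply(fits, `[[`, "order"),
      qualifiedMembers = qual,
      x = lapply(fits, `[[`, "x"),
      unmapped = unmapped, alpha = config@alpha)
}
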