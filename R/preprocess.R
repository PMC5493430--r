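#' Log2-transform raw ratio records
#'
#' Replaces each record's fold-scale ratio by its log2. When `alreadyLogged`
#' is TRUE the input is returned unchanged. Records with non-positive ratios
#' on the fold scale cannot be logged; they are dropped with a warning and
#' counted.
#'
#' @param records List of raw ratio records as returned by
#'   [readExpressionTable()]: each a list with elements `identifiers`
#'   (character) and `ratio` (numeric scalar).
#' @param alreadyLogged Logical flag.
#' @return The records on the log2 scale, with attribute `nDropped` giving the
#'   number of records removed.
#' @export
log2Transform <- function(records, alreadyLogged = FALSE) {
  if (alreadyLogged) {
    attr(records, "nDropped") <- 0L
    return(records)
  }
  ratios <- vapply(records, `[[`, numeric(1), "ratio")
  bad <- !is.finite(ratios) | ratios <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive ratio dropped before log2",
            call. = FALSE)
  }
  out <- lapply(records[!bad], function(r) {
    r$ratio <- log2(r$ratio)
    r
  })
  attr(out, "nDropped") <- sum(bad)
  out
}

#' Winsorize a vector of log2 ratios
#'
#' Values beyond the threshold are replaced by the maximum permitted value
#' observed within it: the largest absolute in-range value M serves as the
#' replacement magnitude, with the extreme value's own sign kept (+M for
#' values above the threshold, -M for values below its negative). In-range
#' values and the input order are untouched. If no in-range value exists at
#' all, the replacement falls back to the threshold itself (with a warning).
#'
#' For example, (-7, -1, 3, 4, 6) with threshold 5 becomes (-4, -1, 3, 4, 4):
#' 6 is replaced by the maximum permitted value 4, and -7 by -4.
#'
#' @param values Numeric vector of signed log2 ratios.
#' @param threshold Positive real on the log2 scale.
#' @return Numeric vector of the same length, all entries in
#'   `[-threshold, threshold]`.
#' @export
winsorize <- function(values, threshold) {
  assertScalarNumber(threshold, "threshold", lower = .Machine$double.eps)
  if (!length(values)) return(values)
  out <- values
  extreme <- abs(values) > threshold
  if (any(extreme)) {
    inRange <- abs(values)[!extreme]
    if (length(inRange)) {
      M <- max(inRange)
    } else {
      warning("no value within the winsorization threshold; ",
              "clamping to +/-threshold", call. = FALSE)
      M <- threshold
    }
    out[extreme] <- sign(values[extreme]) * M
  }
  out
}

#' Resolve multi-identifier records and multi-ratio identifiers
#'
#' Each record's (log2) ratio is first fanned out to all its identifiers: a
#' ratio reported for several accessions is assigned to each of them. An
#' accession that then carries several ratios receives their median (for even
#' counts, the midpoint of the two central values).
#'
#' @param records List of log2-scale ratio records.
#' @return Named numeric vector: accession to log2 ratio.
#' @export
resolveIdentifiers <- function(records) {
  if (!length(records)) return(stats::setNames(numeric(), character()))
  ids <- lapply(records, `[[`, "identifiers")
  ratios <- vapply(records, `[[`, numeric(1), "ratio")
  acc <- unlist(ids, use.names = FALSE)
  val <- rep(ratios, lengths(ids))
  med <- vapply(split(val, acc), stats::median, numeric(1))
  med[sort(names(med))]
}

#' Standardize a ratio map to unit sample standard deviation
#'
#' Divides every value by the sample standard deviation (n - 1 denominator)
#' of all values. The mean is deliberately not subtracted: a log2 ratio of
#' zero means "unchanged", and the null hypothesis is centred at zero.
#'
#' @param values Named numeric vector (accession to log2 ratio), length >= 2
#'   with at least two distinct values.
#' @return The values divided by their sample SD (resulting SD is 1).
#' @export
standardizeValues <- function(values) {
  if (length(values) < 2L) {
    stop("standardization needs at least two proteins", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("standard deviation of the ratios is zero; ",
         "all values identical - nothing to standardize", call. = FALSE)
  }
  values / s
}

#' Fold-change qualification of expression directions
#'
#' A protein is qualified to carry its ratio into the test vector iff its
#' pre-standardization |log2 ratio| is at least log2(foldThreshold), i.e. it
#' shows at least a `foldThreshold`-fold change in either direction.
#' Unqualified proteins remain mapped pathway members but contribute zero.
#'
#' @param rawLog2 Named numeric vector of pre-standardization log2 ratios.
#' @param foldThreshold Real >= 1 on the fold scale (default 1.5).
#' @return Named logical vector parallel to `rawLog2`.
#' @export
qualifyDirections <- function(rawLog2, foldThreshold = 1.5) {
  assertScalarNumber(foldThreshold, "foldThreshold", lower = 1)
  abs(rawLog2) >= log2(foldThreshold)
}

#' Build a processed expression profile from raw records
#'
#' Applies, in order: identifier mapping (optional), log2 transformation,
#' winsorization, multi-identifier/multi-ratio resolution, fold-change
#' qualification (computed on the pre-standardization log2 values), and
#' standardization.
#'
#' @param records List of raw ratio records ([readExpressionTable()]).
#' @param mapping Optional identifier multimap from [readIdMapping()]; source
#'   identifiers are replaced by all their targets, identifiers absent from
#'   the map pass through unchanged.
#' @param config A [T2Config-class] object; `alreadyLogged`, `winsorThreshold`
#'   and `foldThreshold` are consumed here.
#' @return An [ExpressionProfile-class] object.
#' @export
buildProfile <- function(records, mapping = NULL, config = t2Config()) {
  stopifnot(is(config, "T2Config"))
  if (!is.null(mapping)) records <- applyIdMapping(records, mapping)
  nReadDropped <- attr(records, "nDropped")
  if (is.null(nReadDropped)) nReadDropped <- 0L
  records <- log2Transform(records, alreadyLogged = config@alreadyLogged)
  nDropped <- nReadDropped + attr(records, "nDropped")
  ratios <- vapply(records, `[[`, numeric(1), "ratio")
  wins <- winsorize(ratios, config@winsorThreshold)
  for (i in seq_along(records)) records[[i]]$ratio <- wins[[i]]
  rawLog2 <- resolveIdentifiers(records)
  qualified <- qualifyDirections(rawLog2, config@foldThreshold)
  values <- standardizeValues(rawLog2)
  new("ExpressionProfile", values = values, rawLog2 = rawLog2,
      qualified = qualified, nDropped = as.integer(nDropped))
}
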