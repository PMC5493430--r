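#' Read an expression-ratio table
#'
#' Parses a tab-separated table whose first column holds one or more protein
#' identifiers (semicolon-delimited when a ratio was reported for several
#' accessions) and whose second column holds the expression ratio of the
#' experimental group over the control. Rows whose ratio does not parse as a
#' finite number (including any header line) are dropped and counted.
#'
#' @param path Path to the table.
#' @param alreadyLogged If TRUE, ratios are taken as signed log2 values;
#'   otherwise they must be positive fold ratios.
#' @return A list of raw ratio records (each with `identifiers`, `ratio`),
#'   with attribute `nDropped` (dropped-row count).
#' @export
readExpressionTable <- function(path, alreadyLogged = FALSE) {
  if (!file.exists(path)) stop("expression table not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nDropped <- 0L
  records <- list()
  for (f in fields) {
    if (length(f) < 2L) {
      nDropped <- nDropped + 1L
      next
    }
    ratio <- suppressWarnings(as.numeric(f[[2L]]))
    ids <- trimws(strsplit(f[[1L]], ";", fixed = TRUE)[[1L]])
    ids <- ids[nzchar(ids)]
    ok <- length(ids) > 0L && !any(grepl("\\s", ids)) &&
      is.finite(ratio) && (alreadyLogged || ratio > 0)
    if (!ok) {
      nDropped <- nDropped + 1L
      next
    }
    records[[length(records) + 1L]] <- list(identifiers = ids, ratio = ratio)
  }
  if (!length(records)) {
    stop("no parsable expression rows in ", path, call. = FALSE)
  }
  attr(records, "nDropped") <- nDropped
  records
}

#' Read gene sets in GMT, KEGG KGML or Reactome dialect
#'
#' * `gmt`: one pathway per line — name, description, then member accessions,
#'   tab-separated.
#' * `kgml`: KEGG pathway XML; `path` may be a single file or a directory of
#'   `.xml` files, one pathway per file. Members are the union of identifiers
#'   from `entry` elements of type `gene`, `enzyme` and `group` (group entries
#'   are expanded to the identifiers of their component entries); other entry
#'   types (`map`, `compound`, ...) are ignored.
#' * `reactome`: tab-separated accumulation rows pathway_id, protein
#'   accession, and optionally a pathway title in a third column.
#'
#' Pathways that end up with an empty member set are skipped with a warning.
#'
#' @param path File (or, for kgml, directory) to read.
#' @param dialect One of "gmt", "kgml", "reactome".
#' @return A [PathwayCollection-class] object.
#' @export
readGeneSets <- function(path, dialect = c("gmt", "kgml", "reactome")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene-set input not found: ", path,
                               call. = FALSE)
  switch(dialect,
         gmt = readGmt(path),
         kgml = readKgml(path),
         reactome = readReactomeTable(path))
}

readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(); titles <- character(); members <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    mem <- unique(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    if (length(f) < 3L || !length(mem)) {
      warning("skipping gene set with empty member list: ",
              if (length(f)) f[[1L]] else "<empty line>", call. = FALSE)
      next
    }
    ids <- c(ids, f[[1L]])
    titles <- c(titles, f[[2L]])
    members <- c(members, list(mem))
  }
  PathwayCollection(ids, titles, members)
}

readKgml <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else {
    path
  }
  ids <- character(); titles <- character(); members <- list()
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f), error = function(e) {
      stop("malformed KGML in ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    root <- xml2::xml_attrs(doc)
    pid <- if ("name" %in% names(root)) root[["name"]] else basename(f)
    title <- if ("title" %in% names(root)) root[["title"]] else pid
    entries <- xml2::xml_find_all(doc, ".//entry")
    type <- xml2::xml_attr(entries, "type")
    entryName <- xml2::xml_attr(entries, "name")
    entryId <- xml2::xml_attr(entries, "id")
    nameTokens <- function(nm) {
      tok <- unlist(strsplit(nm, "\\s+"))
      tok[nzchar(tok)]
    }
    mem <- character()
    direct <- type %in% c("gene", "enzyme")
    if (any(direct)) mem <- c(mem, unlist(lapply(entryName[direct], nameTokens)))
    # group entries reference component entries by id; expand to the
    # identifiers of those component entries
    for (g in entries[type %in% "group"]) {
      compIds <- xml2::xml_attr(xml2::xml_find_all(g, ".//component"), "id")
      hit <- entryId %in% compIds & type %in% c("gene", "enzyme")
      if (any(hit)) mem <- c(mem, unlist(lapply(entryName[hit], nameTokens)))
    }
    mem <- unique(mem)
    if (!length(mem)) {
      warning("skipping KGML pathway with no gene/enzyme/group members: ", f,
              call. = FALSE)
      next
    }
    ids <- c(ids, pid)
    titles <- c(titles, title)
    members <- c(members, list(mem))
  }
  PathwayCollection(ids, titles, members)
}

readReactomeTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Reactome mapping file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) stop("malformed Reactome mapping rows in ", path, call. = FALSE)
  pid <- vapply(fields, `[`, character(1), 1L)
  prot <- vapply(fields, `[`, character(1), 2L)
  title <- vapply(fields, function(f) {
    if (length(f) >= 3L && nzchar(f[[3L]])) f[[3L]] else f[[1L]]
  }, character(1))
  ids <- unique(pid)
  members <- split(prot, factor(pid, levels = ids))
  titles <- vapply(ids, function(i) title[match(i, pid)], character(1))
  keep <- lengths(lapply(members, function(m) m[nzchar(m)])) > 0L
  if (!all(keep)) {
    warning("skipping pathway with empty member set: ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)
  }
  PathwayCollection(ids[keep], unname(titles[keep]), members[keep])
}

#' Write a pathway collection in GMT format
#'
#' @param collection A [PathwayCollection-class] object.
#' @param path Output file.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  lines <- vapply(seq_along(collection@ids), function(i) {
    paste(c(collection@ids[[i]], collection@titles[[i]],
            collection@members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction confidence-score table
#'
#' Expects three tab-separated columns: protein_a, protein_b, score. Scores on
#' the STRING 0-1000 integer scale are auto-detected (any score > 1 present)
#' and divided by 1000; otherwise they are taken as-is on the (0, 1] scale.
#' Self-pairs are dropped, duplicate pairs collapsed keeping the maximum
#' score, and pairs below `minScore` excluded.
#'
#' @param path Path to the table.
#' @param minScore Minimum retained confidence (default 0.4, STRING's "medium
#'   confidence" cutoff), applied on the normalized (0, 1] scale.
#' @return An [InteractionScores-class] object.
#' @export
readInteractionScores <- function(path, minScore = 0.4) {
  assertScalarNumber(minScore, "minScore", lower = 0, upper = 1)
  if (!file.exists(path)) stop("interaction table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("a", "b", "score"),
                           colClasses = c("character", "character", "numeric"))
  if (anyNA(tab$score)) stop("unparsable score values in ", path, call. = FALSE)
  if (any(tab$score < 0 | tab$score > 1000)) {
    stop("scores must lie in [0, 1000]: ", path, call. = FALSE)
  }
  if (any(tab$score > 1)) tab$score <- tab$score / 1000
  tab <- tab[tab$score >= minScore & tab$score > 0, , drop = FALSE]
  obj <- InteractionScores(tab$a, tab$b, tab$score)
  if (nPairs(obj) == 0L) {
    warning("no interaction pairs retained at minScore = ", minScore,
            call. = FALSE)
  }
  obj
}

#' Write an interaction-score table
#'
#' @param scores An [InteractionScores-class] object.
#' @param path Output file (tab-separated: protein_a, protein_b, score).
#' @export
writeInteractionScores <- function(scores, path) {
  stopifnot(is(scores, "InteractionScores"))
  tab <- scoreTable(scores)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column identifier-mapping table
#'
#' Columns: source identifier, target (canonical) accession; tab-separated,
#' one-to-many allowed in both directions.
#'
#' @param path Path to the table.
#' @return A named list: source identifier to character vector of targets.
#' @export
readIdMapping <- function(path) {
  if (!file.exists(path)) stop("id-mapping table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("source", "target"),
                           colClasses = c("character", "character"))
  if (!nrow(tab)) stop("empty id-mapping table: ", path, call. = FALSE)
  lapply(split(tab$target, tab$source), function(x) sort(unique(x)))
}

#' Apply an identifier multimap to raw ratio records
#'
#' Each identifier with map entries is replaced by all its targets (a source
#' mapping to several accessions fans the ratio out to each of them);
#' identifiers absent from the map are kept unchanged.
#'
#' @param records List of raw ratio records.
#' @param mapping Named list from [readIdMapping()].
#' @return The records with mapped identifier sets.
#' @export
applyIdMapping <- function(records, mapping) {
  nDropped <- attr(records, "nDropped")
  out <- lapply(records, function(r) {
    mapped <- unlist(lapply(r$identifiers, function(id) {
      if (!is.null(mapping[[id]])) mapping[[id]] else id
    }), use.names = FALSE)
    r$identifiers <- unique(mapped)
    r
  })
  attr(out, "nDropped") <- nDropped
  out
}

#' Write the combined results / pathway-group table
#'
#' One row per tested pathway, annotated with the delegate of the group it
#' belongs to. Rows are ordered by group size (descending), then pathway id,
#' so re-running on identical input yields a byte-identical file. Floating
#' values are printed with 9 significant digits.
#'
#' @param results A [PathwayTestResults-class] object.
#' @param path Output file.
#' @param groups Optional [PathwayGroups-class] object from
#'   [integratePathways()]; if omitted every pathway is written as its own
#'   singleton group.
#' @return The path, invisibly.
#' @export
writeResults <- function(results, path, groups = NULL) {
  stopifnot(is(results, "PathwayTestResults"))
  tab <- results@table
  if (!nrow(tab)) stop("no results to write", call. = FALSE)
  if (is.null(groups)) {
    delegate <- stats::setNames(tab$pathway_id, tab$pathway_id)
    groupMem <- stats::setNames(as.list(tab$pathway_id), tab$pathway_id)
  } else {
    stopifnot(is(groups, "PathwayGroups"))
    groupMem <- groups@members
    delegate <- stats::setNames(
      rep(names(groupMem), lengths(groupMem)),
      unlist(groupMem, use.names = FALSE)
    )
  }
  delegate_id <- unname(delegate[tab$pathway_id])
  groupSize <- lengths(groupMem)[delegate_id]
  group_members <- vapply(groupMem[delegate_id], paste, character(1),
                          collapse = ",")
  num <- function(x) formatC(x, digits = 9, format = "g")
  out <- data.frame(
    pathway_id = tab$pathway_id, title = tab$title, n_mapped = tab$n_mapped,
    rank_q = tab$rank_q, T2 = num(tab$T2), p_value = num(tab$p_value),
    delegate_id = delegate_id, group_members = unname(group_members),
    stringsAsFactors = FALSE
  )
  ord <- order(-groupSize, out$pathway_id)
  utils::write.table(out[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#'
#' @param path Path to the results TSV.
#' @return data.frame with the written columns (T2 and p_value numeric).
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(pathway_id = "character",
                                          title = "character",
                                          delegate_id = "character",
                                          group_members = "character"))
  tab$T2 <- as.numeric(tab$T2)
  tab$p_value <- as.numeric(tab$p_value)
  tab
}
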