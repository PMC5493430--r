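# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra paths (solve/ginv/svd).

# Cofactor (adjugate) inverse for symmetric matrices up to 3x3, written out
# by hand, and the quadratic form x' S^-1 x built from it.
cofactorInverse <- function(S) {
  q <- nrow(S)
  if (q == 1L) return(matrix(1 / S[1, 1], 1, 1))
  if (q == 2L) {
    det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    return(matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det)
  }
  if (q == 3L) {
    det <- S[1, 1] * (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2]) -
      S[1, 2] * (S[2, 1] * S[3, 3] - S[2, 3] * S[3, 1]) +
      S[1, 3] * (S[2, 1] * S[3, 2] - S[2, 2] * S[3, 1])
    cof <- matrix(NA_real_, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      minor <- S[-i, -j, drop = FALSE]
      cof[i, j] <- (-1)^(i + j) *
        (minor[1, 1] * minor[2, 2] - minor[1, 2] * minor[2, 1])
    }
    return(t(cof) / det)
  }
  stop("cofactor oracle only covers q <= 3")
}

oracleT2 <- function(x, S) {
  drop(t(x) %*% cofactorInverse(S) %*% x)
}

# Direct four-rule covariance construction by double loop.
oracleCovariance <- function(order, x, scores, diagConstant = 0.4) {
  q <- length(order)
  S <- matrix(0, q, q, dimnames = list(order, order))
  tab <- scoreTable(scores)
  lookup <- function(a, b) {
    hit <- (tab$protein_a == a & tab$protein_b == b) |
      (tab$protein_a == b & tab$protein_b == a)
    if (any(hit)) tab$score[hit][1] else NA_real_
  }
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) {
        S[i, j] <- diagConstant
      } else {
        c_ij <- lookup(order[i], order[j])
        if (!is.na(c_ij)) {
          S[i, j] <- if (x[i] * x[j] >= 0) c_ij else -c_ij
        }
      }
    }
  }
  S
}

# A tiny deterministic fixture shared by several files: five proteins, two
# up, two down, one below the 1.5-fold qualification threshold.
toyRecords <- function() {
  list(
    list(identifiers = "P1", ratio = 4),     # log2 = 2
    list(identifiers = "P2", ratio = 2),     # log2 = 1
    list(identifiers = "P3", ratio = 0.25),  # log2 = -2
    list(identifiers = "P4", ratio = 0.5),   # log2 = -1
    list(identifiers = "P5", ratio = 1.2)    # |log2| < log2(1.5): unqualified
  )
}

toyScores <- function() {
  InteractionScores(c("P1", "P1", "P3"), c("P2", "P3", "P4"),
                    c(0.9, 0.6, 0.5))
}

toyCollection <- function() {
  PathwayCollection(
    ids = c("pwA", "pwB", "pwC"),
    titles = c("big pathway", "subset pathway", "disjoint pathway"),
    members = list(c("P1", "P2", "P3", "P4", "P5"), c("P1", "P2"),
                   c("Q1", "Q2"))
  )
}

writeTempLines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
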