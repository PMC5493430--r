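test_that("profile-to-pathway mapping orders members and zeroes unqualified ones", {
  prof <- buildProfile(toyRecords())
  m <- mapProfileToPathway(prof, c("P3", "P1", "P5", "ZZ"))
  expect_equal(m$order, c("P1", "P3", "P5"))
  expect_equal(unname(m$x[c("P1", "P3")]),
               unname(profileValues(prof)[c("P1", "P3")]))
  expect_identical(unname(m$x["P5"]), 0)  # unqualified but still mapped
  expect_null(mapProfileToPathway(prof, c("ZZ", "YY")))
})

test_that("the four covariance rules fill S entry by entry", {
  sc <- toyScores()
  x <- c(P1 = 1.2, P2 = 0.8, P3 = -0.9, P4 = -1.1, P5 = 0)
  ord <- names(x)
  S <- buildCovariance(ord, x, sc, diagConstant = 0.4)
  expect_equal(unname(diag(S)), rep(0.4, 5))
  expect_equal(S["P1", "P2"], 0.9)    # same sign -> +score
  expect_equal(S["P1", "P3"], -0.6)   # opposite signs -> -score
  expect_equal(S["P3", "P4"], 0.5)    # both down -> +score
  expect_equal(S["P2", "P4"], 0)      # no stored score
  # zeroed ratio: x_i * x_j = 0 >= 0, never a negative entry
  x2 <- x; x2["P1"] <- 0
  expect_equal(buildCovariance(ord, x2, sc, 0.4)["P1", "P3"], 0.6)
})

test_that("randomized covariance matrices match the four-rule oracle", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    prot <- paste0("R", seq_len(n))
    pairs <- t(utils::combn(prot, 2))
    keep <- stats::runif(nrow(pairs)) < 0.5
    sc <- InteractionScores(pairs[keep, 1], pairs[keep, 2],
                            stats::runif(sum(keep), 0.4, 1))
    x <- round(stats::rnorm(n), 2)
    x[stats::runif(n) < 0.3] <- 0
    S <- buildCovariance(prot, x, sc, 0.4)
    expect_equal(S, oracleCovariance(prot, x, sc, 0.4))
    expect_identical(S, t(S))  # exact symmetry
  }
})

test_that("numeric rank counts singular values above the relative tolerance", {
  expect_equal(numericRank(diag(0.4, 3)), 3L)
  expect_equal(numericRank(matrix(0.4, 2, 2)), 1L)
  expect_equal(numericRank(matrix(0, 2, 2)), 0L)
})

test_that("T2 reproduces hand-computed and pseudoinverse cases", {
  # zero vector: no evidence, p = 1
  r0 <- hotellingT2(c(0, 0), diag(0.4, 2))
  expect_equal(r0$T2, 0)
  expect_equal(r0$p_value, 1)

  # independence: T2 = sum x_i^2 / 0.4
  r1 <- hotellingT2(c(1, 1), diag(0.4, 2))
  expect_equal(r1$T2, 5)
  expect_equal(r1$rank_q, 2L)
  expect_false(r1$degenerate)
  expect_equal(r1$p_value, stats::pchisq(5, 2, lower.tail = FALSE))

  # correlated 2x2, inverse by hand: 0.2 / 0.07
  r2 <- hotellingT2(c(1, 1), matrix(c(0.4, 0.3, 0.3, 0.4), 2))
  expect_equal(r2$T2, 0.2 / 0.07, tolerance = 1e-12)

  # singular S: pseudoinverse, df drops to the rank
  r3 <- hotellingT2(c(1, 1), matrix(0.4, 2, 2))
  expect_equal(r3$T2, 2.5, tolerance = 1e-9)
  expect_equal(r3$rank_q, 1L)
  expect_true(r3$degenerate)

  # scalar pathway
  r4 <- hotellingT2(2, matrix(0.4, 1, 1))
  expect_equal(r4$T2, 10)
  expect_equal(r4$rank_q, 1L)
})

test_that("T2 matches the cofactor-inverse oracle for q <= 3", {
  set.seed(99)
  for (i in 1:40) {
    q <- sample(1:3, 1)
    repeat {
      S <- diag(0.4, q)
      if (q > 1) {
        off <- sample(c(0, stats::runif(1, 0.4, 1) *
                          sample(c(-1, 1), 1)), q * (q - 1) / 2,
                      replace = TRUE)
        S[upper.tri(S)] <- off
        S <- S + t(S) - diag(diag(S))
      }
      if (numericRank(S) == q) break
    }
    x <- round(stats::rnorm(q), 2)
    expect_equal(hotellingT2(x, S)$T2, oracleT2(x, S), tolerance = 1e-9)
  }
})

test_that("pseudoinverse path agrees with direct inverse on nonsingular S", {
  set.seed(5)
  for (i in 1:20) {
    q <- sample(2:6, 1)
    A <- matrix(stats::rnorm(q * q, sd = 0.2), q)
    S <- crossprod(A) + diag(0.4, q)
    x <- stats::rnorm(q)
    direct <- drop(crossprod(x, solve(S) %*% x))
    viaPinv <- drop(crossprod(x, MASS::ginv(S) %*% x))
    expect_equal(hotellingT2(x, S)$T2, direct, tolerance = 1e-9)
    expect_equal(direct, viaPinv, tolerance = 1e-9)
  }
})

test_that("T2 is permutation-invariant and scales quadratically in x", {
  set.seed(17)
  prot <- paste0("P", 1:6)
  sc <- toyScores()
  x <- c(P1 = 2, P2 = 1.1, P3 = -1.4, P4 = -0.7, P5 = 0, P6 = 0.9)
  S <- buildCovariance(prot, x, sc, 0.4)
  base <- hotellingT2(x, S)
  for (i in 1:10) {
    p <- sample(6)
    expect_equal(hotellingT2(x[p], S[p, p])$T2, base$T2, tolerance = 1e-9)
  }
  for (c in c(0.5, 2, 10)) {
    expect_equal(hotellingT2(c * x, S)$T2, c^2 * base$T2, tolerance = 1e-9)
  }
})

test_that("indefinite S yields a flagged result with p forced to 1", {
  S <- matrix(c(0.4, 0.9, 0.9, 0.4), 2)  # eigenvalues 1.3 and -0.5
  r <- hotellingT2(c(1, -1), S)
  expect_true(r$T2 < 0)
  expect_true(r$indefinite)
  expect_equal(r$p_value, 1)
})

test_that("testPathway composes mapping, covariance and statistic", {
  prof <- buildProfile(toyRecords())
  cfg <- t2Config()
  # two-member pathway without stored interactions: independence closed form
  fit <- testPathway(prof, c("P2", "P4"), InteractionScores(), cfg)
  expect_equal(fit$T2, sum(profileValues(prof)[c("P2", "P4")]^2) / 0.4)
  expect_equal(fit$rank_q, 2L)

  # all members unqualified: zero vector
  fit2 <- testPathway(prof, "P5", toyScores(), cfg)
  expect_equal(fit2$T2, 0)
  expect_equal(fit2$p_value, 1)

  expect_null(testPathway(prof, c("ZZ"), toyScores(), cfg))
})

test_that("testAllPathways reports mapped pathways and skips unmapped ones", {
  prof <- buildProfile(toyRecords())
  expect_message(res <- testAllPathways(prof, toyCollection(), toyScores()),
                 "skipped")
  tab <- resultTable(res)
  expect_equal(tab$pathway_id, c("pwA", "pwB"))
  expect_equal(res@unmapped, "pwC")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$rank_q <= tab$n_mapped))
  # BH column present but raw p-values drive downstream decisions
  expect_equal(tab$p_adjust, stats::p.adjust(tab$p_value, "BH"))

  # collection order does not matter: results are normalized
  shuffled <- PathwayCollection(
    ids = c("pwC", "pwB", "pwA"),
    titles = c("disjoint pathway", "subset pathway", "big pathway"),
    members = list(c("Q1", "Q2"), c("P1", "P2"),
                   c("P1", "P2", "P3", "P4", "P5"))
  )
  res2 <- suppressMessages(testAllPathways(prof, shuffled, toyScores()))
  expect_identical(resultTable(res2), tab)

  expect_error(PathwayCollection(c("a", "a"), members = list("P1", "P2")),
               "unique")
})
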