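test_that("interaction-network generation respects density and seed", {
  d0 <- simulationDesign(nProteins = 10L, edgeDensity = 0, seed = 3)
  expect_equal(nPairs(generateInteractionNetwork(d0)), 0L)

  d1 <- simulationDesign(nProteins = 4L, edgeDensity = 1, seed = 3)
  expect_equal(nPairs(generateInteractionNetwork(d1)), 6L)  # C(4, 2)

  d <- simulationDesign(nProteins = 40L, edgeDensity = 0.2, seed = 9)
  expect_identical(generateInteractionNetwork(d),
                   generateInteractionNetwork(d))
  sc <- generateInteractionNetwork(d)
  expect_true(all(sc@scores >= 0.4 & sc@scores <= 1))
})

test_that("pathway-collection generation produces guaranteed nesting", {
  d <- simulationDesign(nProteins = 30L, nPathways = 2L,
                        pathwaySize = c(5L, 10L), nestedFraction = 1,
                        seed = 21)
  col <- generatePathwayCollection(d)
  m <- pathwayMembers(col)
  expect_true(isSubsetOf(m[[2]], m[[1]]))
  expect_lt(length(m[[2]]), length(m[[1]]))  # strict subset

  expect_identical(generatePathwayCollection(d),
                   generatePathwayCollection(d))
})

test_that("multivariate-normal draws match their target moments", {
  X <- sampleProfiles(diag(4), mean = 0, nSamples = 10000, seed = 8)
  expect_equal(dim(X), c(10000L, 4L))
  expect_true(max(abs(stats::cov(X) - diag(4))) < 0.05)
  expect_true(max(abs(colMeans(X))) < 0.05)

  expect_equal(dim(sampleProfiles(diag(3), 0, 1, seed = 1)), c(1L, 3L))
  expect_identical(sampleProfiles(diag(3), 0, 5, seed = 4),
                   sampleProfiles(diag(3), 0, 5, seed = 4))
  expect_error(sampleProfiles(matrix(c(1, 2, 2, 1), 2), 0, 5),
               "not positive definite")
})

test_that("rule-built Sigma is shifted to positive definite only when needed", {
  sc <- InteractionScores(c("A", "A"), c("B", "C"), c(0.3, 0.5))
  # diagonal-only: no stored pair among (D, E)
  S0 <- makePsdRulebookSigma(c("D", "E"), sc, c(1, 1), 0.4)
  expect_equal(attr(S0, "shift"), 0)
  expect_equal(unname(S0[1, 1]), 0.4)

  # off-diagonal 0.3 < diag 0.4: eigenvalues 0.1 and 0.7, already PD
  S1 <- makePsdRulebookSigma(c("A", "B"), sc, c(1, 1), 0.4)
  expect_equal(attr(S1, "shift"), 0)
  expect_equal(sort(eigen(S1, only.values = TRUE)$values), c(0.1, 0.7))

  # off-diagonal 0.5 > diag 0.4: lambda_min = -0.1, shifted
  S2 <- makePsdRulebookSigma(c("A", "C"), sc, c(1, 1), 0.4)
  expect_equal(attr(S2, "shift"), 0.1 + 1e-6, tolerance = 1e-9)
  expect_gt(min(eigen(S2, only.values = TRUE)$values), 0)
})

test_that("the equicorrelation calibration preset has the stated spectrum", {
  pre <- calibrationPreset()
  expect_equal(dim(pre$Sigma), c(20L, 20L))
  expect_equal(pre$Sigma[1, 2], 0.5)
  expect_equal(unname(diag(pre$Sigma)), rep(1, 20))
  ev <- eigen(pre$Sigma, only.values = TRUE)$values
  expect_equal(max(ev), 1 + 19 * 0.5)  # 10.5
  expect_equal(min(ev), 0.5)
  expect_equal(pre$nSamples, 10000L)
})

test_that("calibration fast path equals per-draw hotellingT2", {
  pre <- calibrationPreset(q = 6L, nSamples = 50L)
  cal <- calibrationExperiment(pre$Sigma, pre$Sigma, nSamples = 50,
                               seed = 13)
  X <- sampleProfiles(pre$Sigma, 0, 50, seed = 13)
  perDraw <- apply(X, 1L, function(x) hotellingT2(x, pre$Sigma)$T2)
  expect_equal(cal$T2, perDraw, tolerance = 1e-9)
  expect_equal(cal$df, 6L)
})

test_that("a synthetic null with a rulebook Sigma is calibrated", {
  sc <- withr::with_seed(55, {
    prot <- paste0("N", 1:10)
    pairs <- t(utils::combn(prot, 2))
    keep <- stats::runif(nrow(pairs)) < 0.3
    InteractionScores(pairs[keep, 1], pairs[keep, 2],
                      stats::runif(sum(keep), 0.4, 0.9))
  })
  signs <- rep(1, 10)
  Sigma <- makePsdRulebookSigma(paste0("N", 1:10), sc, signs, 0.4)
  attr(Sigma, "shift") <- NULL
  cal <- calibrationExperiment(Sigma, Sigma, nSamples = 10000,
                               alpha = 0.05, seed = 29)
  expect_lt(abs(cal$rejectionRate - 0.05), 3 * cal$mcse)
})

test_that("raising the effect size raises the perturbed pathway's average T2", {
  members <- paste0("E", 1:8)
  sc <- InteractionScores()  # independence keeps the oracle simple
  nReps <- 200
  meanT2 <- vapply(c(0, 1, 2), function(eff) {
    t2s <- vapply(seq_len(nReps), function(r) {
      log2ratio <- withr::with_seed(1000 + r,
                                    stats::rnorm(8, mean = eff, sd = 1))
      x <- log2ratio / stats::sd(log2ratio)
      hotellingT2(x, diag(0.4, 8))$T2
    }, numeric(1))
    mean(t2s)
  }, numeric(1))
  expect_true(all(diff(meanT2) > 0))
})

test_that("fixture bundles are complete, readable and seed-reproducible", {
  d <- simulationDesign(nProteins = 40L, edgeDensity = 0.15, nPathways = 5L,
                        pathwaySize = c(4L, 10L), seed = 33)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- writeFixtureBundle(d, dir1)
  p2 <- writeFixtureBundle(d, dir2)
  for (k in c("expression", "geneSets", "ppi")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  rec <- readExpressionTable(p1$expression)
  expect_length(rec, 40L)
  col <- readGeneSets(p1$geneSets, "gmt")
  expect_length(pathwayIds(col), 5L)
  expect_gt(nPairs(readInteractionScores(p1$ppi)), 0L)
  manifest <- jsonlite::read_json(p1$manifest)
  expect_equal(manifest$design$seed, 33L)
})
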