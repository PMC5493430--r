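test_that("winsorization replaces extremes by the most extreme permitted value", {
  expect_equal(winsorize(c(-7, -1, 3, 4, 6), 5), c(-4, -1, 3, 4, 4))
  expect_equal(winsorize(c(-1, 0, 1), 10), c(-1, 0, 1))
  expect_warning(out <- winsorize(12, 5), "clamping")
  expect_equal(out, 5)
  # replacement magnitude comes from the in-range values, sign is kept
  expect_equal(winsorize(c(-12, 3), 5), c(-3, 3))
})

test_that("winsorization is idempotent, sign-preserving and non-expanding", {
  set.seed(42)
  for (i in 1:50) {
    v <- round(stats::rnorm(sample(1:12, 1), sd = 6), 2)
    t <- stats::runif(1, 0.5, 8)
    w <- suppressWarnings(winsorize(v, t))
    expect_equal(suppressWarnings(winsorize(w, t)), w)
    expect_true(all(abs(w) <= t + 1e-12))
    expect_true(all(abs(w) <= abs(v) + 1e-12))
    expect_true(all(sign(w) == sign(v) | w == 0 | v == 0))
  }
})

test_that("log2 transform maps fold ratios and drops non-positive values", {
  rec <- list(list(identifiers = "A", ratio = 1),
              list(identifiers = "B", ratio = 2),
              list(identifiers = "C", ratio = -0.5))
  expect_warning(out <- log2Transform(rec), "dropped")
  expect_length(out, 2L)
  expect_equal(vapply(out, `[[`, numeric(1), "ratio"), c(0, 1))
  expect_equal(attr(out, "nDropped"), 1L)
  expect_identical(log2Transform(rec, alreadyLogged = TRUE)[[3]]$ratio, -0.5)
})

test_that("identifier resolution fans out then takes the median", {
  rec <- list(list(identifiers = c("A", "B"), ratio = 1.0))
  expect_equal(resolveIdentifiers(rec), c(A = 1, B = 1))

  rec2 <- list(list(identifiers = "A", ratio = 0.5),
               list(identifiers = "A", ratio = 1.0),
               list(identifiers = "A", ratio = 2.0))
  expect_equal(resolveIdentifiers(rec2), c(A = 1.0))

  rec3 <- list(list(identifiers = "A", ratio = 0.0),
               list(identifiers = "A", ratio = 1.0))
  expect_equal(resolveIdentifiers(rec3), c(A = 0.5))  # even-count midpoint

  # fan-out happens before the median collapse
  rec4 <- list(list(identifiers = c("A", "B"), ratio = 2.0),
               list(identifiers = "A", ratio = 0.0),
               list(identifiers = "A", ratio = 1.0))
  expect_equal(resolveIdentifiers(rec4), c(A = 1.0, B = 2.0))
})

test_that("standardization divides by the sample SD and rejects degenerate input", {
  v <- c(A = -1, B = 1)
  expect_equal(standardizeValues(v), c(A = -1, B = 1) / sqrt(2))
  expect_equal(stats::sd(standardizeValues(c(A = 0.3, B = 2, C = -4))), 1)
  expect_error(standardizeValues(c(A = 2, B = 2)), "zero")
  expect_error(standardizeValues(c(A = 2)), "at least two")
})

test_that("standardization is scale-equivariant", {
  set.seed(7)
  v <- stats::setNames(stats::rnorm(9), paste0("P", 1:9))
  for (c in c(0.1, 3, 250)) {
    expect_equal(standardizeValues(c * v), standardizeValues(v))
  }
})

test_that("fold-change qualification compares |log2 ratio| to log2(threshold)", {
  raw <- c(weak = 0.3, strong = 1.0, down = -0.7)
  q <- qualifyDirections(raw, 1.5)
  expect_equal(unname(q), c(FALSE, TRUE, TRUE))  # log2(1.5) ~ 0.585
  expect_true(all(qualifyDirections(raw, 1.0)))  # threshold 1 qualifies all

  # monotone: raising the threshold never adds qualified accessions
  set.seed(11)
  raw2 <- stats::rnorm(40)
  prev <- qualifyDirections(raw2, 1)
  for (ft in c(1.2, 1.5, 2, 4)) {
    cur <- qualifyDirections(raw2, ft)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("buildProfile composes the processing steps in order", {
  rec <- list(list(identifiers = "A", ratio = 2.0),
              list(identifiers = "B", ratio = 0.5))
  prof <- buildProfile(rec)
  expect_equal(profileValues(prof), c(A = 1, B = -1) / sqrt(2))
  expect_equal(profileRawLog2(prof), c(A = 1, B = -1))
  expect_equal(profileQualified(prof), c(A = TRUE, B = TRUE))

  # all equal ratios cannot be standardized
  same <- list(list(identifiers = "A", ratio = 1),
               list(identifiers = "B", ratio = 1))
  expect_error(buildProfile(same), "zero")

  # extreme ratio is winsorized before qualification and standardization
  rec2 <- list(list(identifiers = "A", ratio = 2^12),
               list(identifiers = "B", ratio = 2),
               list(identifiers = "C", ratio = 0.5))
  prof2 <- buildProfile(rec2, config = t2Config(winsorThreshold = 10))
  expect_equal(unname(profileRawLog2(prof2)["A"]), 1)  # largest in-range log2

  # deterministic: identical input gives identical profiles
  expect_identical(buildProfile(toyRecords()), buildProfile(toyRecords()))
})

test_that("buildProfile qualification mask uses pre-standardization ratios", {
  # log2 ratios (3, 0.6, -3): sd > 1 shrinks standardized values below
  # log2(1.5), but qualification must be decided on the raw scale
  rec <- list(list(identifiers = "A", ratio = 2^3),
              list(identifiers = "B", ratio = 2^0.6),
              list(identifiers = "C", ratio = 2^-3))
  prof <- buildProfile(rec)
  expect_equal(profileQualified(prof), c(A = TRUE, B = TRUE, C = TRUE))
  expect_lt(abs(profileValues(prof)["B"]), log2(1.5))
})
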