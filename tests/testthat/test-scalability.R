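test_that("maxCovariance matches hand-derived comonotonic couplings", {
  ## exhaustive-search values frozen from the coupling oracle
  expect_equal(maxCovariance(c(2, 2), c(2, 2), levels = 1:2), 0.25)
  expect_equal(maxCovariance(c(1, 1, 1), c(1, 1, 1), levels = 1:3), 2 / 3)
  ## one constant marginal: zero variance, zero maximum
  expect_equal(maxCovariance(c(4, 0), c(2, 2), levels = 1:2), 0)
  expect_error(maxCovariance(c(2, 2), c(3, 2), levels = 1:2), "totals differ")
})

test_that("maxCovariance equals the exhaustive coupling oracle on small marginals", {
  withr::with_seed(31L, {
    for (rep in 1:40) {
      nLev <- sample(2:4, 1L)
      n <- sample(4:8, 1L)
      fi <- randomMarginal(n, nLev)
      fj <- randomMarginal(n, nLev)
      expect_equal(maxCovariance(fi, fj, levels = seq_len(nLev)),
                   oracleMaxCov(fi, fj, seq_len(nLev)),
                   tolerance = 1e-12)
    }
  })
})

test_that("Hij is 1 for comonotonic data, 0 for orthogonal data", {
  m <- ResponseMatrix(cbind(c(1, 1, 2, 2), c(1, 1, 2, 2)),
                      levelMax = 2L, itemLabels = c("a", "b"))
  expect_equal(computeHPair(m, "a", "b"), 1)
  m0 <- ResponseMatrix(cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                       levelMax = 2L, itemLabels = c("a", "b"))
  expect_equal(computeHPair(m0, "a", "b"), 0)
})

test_that("Hij vanishes for independent items at large N", {
  m <- independentFixture(20000L, j = 2L, seed = 5L)
  expect_lt(abs(computeHPair(m, 1L, 2L)), 0.02)
})

test_that("perfect Guttman data give H = 1 at all three levels", {
  m <- guttmanFixture()
  sc <- computeHScale(m)
  expect_equal(unname(hItem(sc)), rep(1, 5), tolerance = 1e-12)
  expect_equal(hScale(sc), 1, tolerance = 1e-12)
  hp <- hPair(sc)
  expect_equal(unname(hp[upper.tri(hp)]), rep(1, 10), tolerance = 1e-12)
})

test_that("with two items the pair, item and scale coefficients coincide", {
  m <- independentFixture(200L, j = 2L, seed = 6L)
  sc <- computeHScale(m)
  h12 <- hPair(sc)[1, 2]
  expect_equal(unname(hItem(sc)), c(h12, h12))
  expect_equal(hScale(sc), h12)
})

test_that("Hs lies between min and max Hi (weighted-mean property)", {
  for (seed in 1:5) {
    m <- simulateGrm(uniSpec(), 400L, seed = seed)
    sc <- computeHScale(m)
    expect_gte(hScale(sc), min(hItem(sc)) - 1e-12)
    expect_lte(hScale(sc), max(hItem(sc)) + 1e-12)
    expect_true(all(hItem(sc) <= 1 + 1e-12))
  }
})

test_that("H coefficients are invariant under level shifts of an item", {
  m <- simulateGrm(grmSpec(a = rep(2, 3),
                           b = equallySpacedThresholds(3, nSteps = 2L),
                           itemLabels = c("a", "b", "c"), levelMax = 3L),
                   500L, seed = 9L)
  v <- responseValues(m)
  shifted <- v; shifted[, 2L] <- shifted[, 2L] + 2L
  m2 <- ResponseMatrix(shifted, levelMin = 1L, levelMax = 5L,
                       itemLabels = itemLabels(m))
  expect_equal(hPair(computeHScale(m2)), hPair(computeHScale(m)),
               tolerance = 1e-12)
  expect_equal(hScale(computeHScale(m2)), hScale(computeHScale(m)),
               tolerance = 1e-12)
})

test_that("strong unidimensional data clear the Hi > 0.3 sufficiency bound", {
  m <- simulateGrm(uniSpec(a = 2), 5000L, seed = 21L)
  expect_true(all(hItem(computeHScale(m)) > 0.3))
})

test_that("negative Hij pairs are reported as model violations", {
  ## an item scored against the scale direction associates negatively
  m <- simulateGrm(uniSpec(j = 3L), 2000L, seed = 13L)
  v <- responseValues(m)
  v[, 3L] <- 6L - v[, 3L]
  sc <- computeHScale(ResponseMatrix(v))
  expect_lt(hPair(sc)[1L, 3L], 0)
  expect_lt(hItem(sc)[[3L]], 0)
  expect_output(show(sc), "negative Hij")
})

test_that("zero-variance items are flagged undefined, not dropped", {
  v <- cbind(rep(3L, 100L), sample(1:5, 100L, replace = TRUE),
             sample(1:5, 100L, replace = TRUE))
  sc <- computeHScale(ResponseMatrix(v))
  expect_true(sc@undefinedItems[[1L]])
  expect_true(is.na(hItem(sc)[[1L]]))
  expect_length(hItem(sc), 3L)
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  m <- simulateGrm(uniSpec(), 300L, seed = 2L)
  s1 <- scalabilitySE(m, B = 50L, seed = 42L)
  s2 <- scalabilitySE(m, B = 50L, seed = 42L)
  expect_identical(seItem(s1), seItem(s2))
  expect_identical(seScale(s1), seScale(s2))
  expect_error(scalabilitySE(m, B = 1L), "at least 2")
})

test_that("a constant dataset yields zero SEs with undefined flags", {
  m <- ResponseMatrix(matrix(2L, 50L, 3L))
  sc <- scalabilitySE(m, B = 20L, seed = 1L)
  expect_true(all(sc@undefinedItems))
  expect_true(all(seItem(sc) == 0))
  expect_equal(seScale(sc), 0)
  expect_true(is.na(hScale(sc)))
})

test_that("bootstrap SE shrinks with sample size (about 1/sqrt(N))", {
  spec <- uniSpec()
  mSmall <- simulateGrm(spec, 1000L, seed = 3L)
  mLarge <- simulateGrm(spec, 4000L, seed = 4L)
  seSmall <- seScale(scalabilitySE(mSmall, B = 120L, seed = 8L))
  seLarge <- seScale(scalabilitySE(mLarge, B = 120L, seed = 8L))
  expect_lt(seLarge, seSmall)
})

test_that("scale classification follows the rules of thumb at the boundaries", {
  expect_identical(classifyScale(0.559), "strong")
  expect_identical(classifyScale(0.299), "unscalable")
  expect_identical(classifyScale(0.45), "moderate")
  expect_identical(classifyScale(0.3), "weak")
  expect_identical(classifyScale(0.5), "strong")
  expect_identical(classifyScale(-0.2), "unscalable")
  expect_error(classifyScale(NA_real_), "finite")
})

test_that("the long-format scalability table carries all three levels", {
  m <- simulateGrm(uniSpec(j = 3L), 300L, seed = 14L)
  tab <- scalabilityTable(scalabilitySE(m, B = 30L, seed = 1L))
  expect_equal(sum(tab$level == "pair"), 3L)
  expect_equal(sum(tab$level == "item"), 3L)
  expect_equal(sum(tab$level == "scale"), 1L)
  expect_true(all(is.finite(tab$se)))
})
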