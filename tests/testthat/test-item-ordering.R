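test_that("well-separated equal-discrimination items show no ordering violations", {
  m <- simulateGrm(iioTrueSpec(), 5000L, seed = 501L)
  rep <- checkMiio(m)
  expect_true(all(rep@pairTable$vi == 0L))
  expect_true(all(rep@itemSummary$crit == 0))
  expect_gt(rep@ht, 0.5)
  expect_identical(rep@htClass, "high")
  ## items are ordered easiest (highest mean) first
  expect_true(all(diff(rep@itemMeans[rep@itemOrder]) <= 0))
})

test_that("a crossing-IRF item is flagged and removed first", {
  spec <- injectViolation(iioTrueSpec(), "crossing_irf", item = 2L,
                          magnitude = 3)
  m <- simulateGrm(spec, 5000L, seed = 502L)
  rep <- checkMiio(m)
  bad <- rep@pairTable$vi > 0L
  expect_true(any(bad))
  expect_true(all(rep@pairTable$itemA[bad] == "it2" |
                  rep@pairTable$itemB[bad] == "it2"))
  back <- backwardSelection(m, report = rep)
  expect_identical(back@removedItems[[1L]], "it2")
  ## fixed point: the survivors re-check clean
  expect_true(all(back@pairTable$vi == 0L))
  survivors <- setdiff(itemLabels(m), back@removedItems)
  recheck <- checkMiio(m[, survivors])
  expect_true(all(recheck@pairTable$vi == 0L))
})

test_that("backward selection leaves a violation-free report untouched", {
  m <- simulateGrm(iioTrueSpec(), 2000L, seed = 503L)
  back <- backwardSelection(m)
  expect_length(back@removedItems, 0L)
})

test_that("two independently crossing items are both removed", {
  ## two steep items, each crossing its own shallow twin in a different
  ## region of the trait range, so the violation sets are disjoint
  spec <- grmSpec(a = c(1.5, 8, 1.5, 1.5, 8, 1.5),
                  b = equallySpacedThresholds(6, lo = -1, hi = 1,
                        centers = c(-1.6, -0.5, -0.5, 0, 0.5, 0.5)),
                  itemLabels = paste0("it", 1:6))
  m <- simulateGrm(spec, 6000L, seed = 504L)
  back <- backwardSelection(m)
  expect_setequal(back@removedItems, c("it2", "it5"))
  expect_true(all(back@pairTable$vi == 0L))
})

test_that("the pairwise check needs at least three items", {
  m <- independentFixture(100L, j = 2L)
  expect_error(checkMiio(m), "at least 3 items")
})

test_that("a generous minvi suppresses all pair violations", {
  spec <- injectViolation(iioTrueSpec(), "crossing_irf", item = 2L,
                          magnitude = 3)
  m <- simulateGrm(spec, 3000L, seed = 505L)
  rep <- checkMiio(m, minvi = 4)
  expect_true(all(rep@pairTable$vi == 0L))
})

test_that("HT equals the scale H of the transposed filtered matrix", {
  m <- eq5d5lPreset(250L, seed = 510L)
  direct <- suppressMessages(coefficientHt(m))
  viaTranspose <- hScale(computeHScale(
    suppressMessages(transposeResponses(m))))
  expect_equal(direct, viaTranspose, tolerance = 1e-10)
})

test_that("HT is invariant under person and item permutations", {
  m <- eq5d5lPreset(400L, seed = 511L)
  base <- suppressMessages(coefficientHt(m))
  withr::with_seed(1L, {
    pPerm <- sample(nPersons(m))
    iPerm <- sample(nItems(m))
  })
  expect_equal(suppressMessages(coefficientHt(m[pPerm, ])), base,
               tolerance = 1e-12)
  expect_equal(suppressMessages(coefficientHt(m[, iPerm])), base,
               tolerance = 1e-12)
})

test_that("constant-pattern persons are removed before HT; all-constant is undefined", {
  v <- rbind(c(1L, 2L, 3L), c(3L, 2L, 1L), c(2L, 2L, 2L), c(5L, 5L, 5L))
  expect_message(ht <- coefficientHt(ResponseMatrix(v)), "2 constant-pattern")
  expect_true(is.finite(ht))
  allConst <- ResponseMatrix(rbind(c(2L, 2L, 2L), c(4L, 4L, 4L)))
  expect_warning(htc <- suppressMessages(coefficientHt(allConst)),
                 "undefined")
  expect_true(is.na(htc))
})

test_that("paired IRFs: duplicates coincide, ordered pairs nest, crossings cross", {
  base <- withr::with_seed(52L, sample(1:5, 400L, replace = TRUE))
  other <- withr::with_seed(53L, sample(1:5, 400L, replace = TRUE))
  dup <- ResponseMatrix(cbind(a = base, b = base, c = other))
  tab <- pairedIrf(dup, "a", "b", minsize = 40L)
  expect_equal(tab$meanA, tab$meanB, tolerance = 1e-12)

  mTrue <- simulateGrm(iioTrueSpec(), 4000L, seed = 512L)
  ## it1 has the lowest thresholds: easiest, so its IRF dominates it5's
  tab2 <- pairedIrf(mTrue, "it1", "it5")
  expect_true(all(tab2$meanA >= tab2$meanB - 0.02))

  spec <- injectViolation(iioTrueSpec(), "crossing_irf", item = 2L,
                          magnitude = 3)
  mx <- simulateGrm(spec, 6000L, seed = 513L)
  tab3 <- pairedIrf(mx, "it2", "it3")
  d <- tab3$meanA - tab3$meanB
  expect_true(min(d) < -0.02 && max(d) > 0.02)
})
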