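test_that("profile codec round-trips and rejects out-of-bounds levels", {
  expect_identical(encodeProfile(c(1, 1, 1, 1, 1)), "11111")
  expect_identical(encodeProfile(c(5, 5, 5, 5, 5)), "55555")
  expect_error(encodeProfile(c(1, 1, 1, 6, 1)), "item 4")
  expect_error(decodeProfile("11061"), "position 3")
  for (p in c("11121", "54321", "11111", "55555"))
    expect_identical(encodeProfile(decodeProfile(p)), p)
})

test_that("profile enumeration yields exactly 5^J distinct profiles", {
  p3 <- enumerateProfiles(3L)
  expect_length(p3, 5^3)
  expect_equal(anyDuplicated(p3), 0L)
  expect_identical(vapply(p3, function(s)
    encodeProfile(decodeProfile(s)), character(1L), USE.NAMES = FALSE), p3)
})

test_that("level sum score matches the profile arithmetic and its bounds", {
  m <- ResponseMatrix(rbind(c(1, 1, 1, 1, 1), c(5, 5, 5, 5, 5),
                            c(1, 1, 1, 2, 1)))
  expect_identical(levelSumScore(m), c(5L, 25L, 6L))
  big <- independentFixture(500L)
  lss <- levelSumScore(big)
  expect_true(all(lss >= 5L & lss <= 25L))
  perm <- big[, c(3, 1, 5, 2, 4)]
  expect_identical(levelSumScore(perm), lss)
})

test_that("rest scores subtract the inspected items and satisfy the identity", {
  m <- ResponseMatrix(rbind(c(1, 1, 1, 2, 1), c(5, 5, 5, 5, 5)),
                      itemLabels = c("MO", "SC", "UA", "PD", "AD"))
  expect_identical(restScores(m, "PD"), c(4L, 20L))
  expect_identical(restScores(m, "MO"), c(5L, 20L))
  expect_error(restScores(m, c("MO", "SC", "UA", "PD", "AD")), "all items")
  big <- independentFixture(300L)
  for (i in seq_len(nItems(big)))
    expect_identical(restScores(big, i) + responseValues(big)[, i],
                     as.integer(levelSumScore(big)))
})

test_that("ResponseMatrix validity enforces bounds and shape", {
  expect_error(ResponseMatrix(rbind(c(1, 0), c(2, 2))), "out of bounds")
  expect_error(ResponseMatrix(matrix(1:4, 4, 1)), "two items")
  expect_s4_class(ResponseMatrix(matrix(1L, 1, 2)), "ResponseMatrix")
})

test_that("delimited reading validates columns and applies listwise deletion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,MO,SC,UA,PD,AD,country",
               "1,1,1,1,2,1,DE",
               "2,2,1,2,3,2,DE",
               "3,5,5,5,5,5,NO"), path)
  m <- readResponses(path, itemColumns = c("MO", "SC", "UA", "PD", "AD"),
                     groupColumns = "country")
  expect_equal(nPersons(m), 3L)
  expect_identical(levelSumScore(m), c(6L, 10L, 25L))
  expect_identical(groupInfo(m)$country, c("DE", "DE", "NO"))

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MO,SC", "1,2", ",3", "2,2"), miss)
  expect_warning(m2 <- readResponses(miss, itemColumns = c("MO", "SC")),
                 "listwise")
  expect_equal(nPersons(m2), 2L)
  expect_error(suppressWarnings(
    readResponses(miss, itemColumns = c("MO", "SC"), missing = "fail")),
    "missing")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MO,SC", "0,2", "1,3"), bad)
  expect_error(readResponses(bad, itemColumns = c("MO", "SC")),
               "out of bounds")
  expect_error(readResponses(path, itemColumns = c("MO", "XX")), "XX")
})

test_that("score tables round-trip through the writer", {
  m <- independentFixture(20L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScores(m, path)
  tab <- read.delim(path)
  expect_equal(tab$lss, levelSumScore(m))
  expect_equal(tab$rest_it1, restScores(m, 1L))
})
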