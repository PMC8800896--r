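test_that("simulation is byte-identical under a fixed seed and spec", {
  spec <- uniSpec()
  m1 <- simulateGrm(spec, 500L, seed = 71L)
  m2 <- simulateGrm(spec, 500L, seed = 71L)
  expect_identical(responseValues(m1), responseValues(m2))
  m3 <- simulateGrm(spec, 500L, seed = 72L)
  expect_false(identical(responseValues(m1), responseValues(m3)))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  withr::with_seed(1L, {
    before <- runif(1)
  })
  withr::with_seed(1L, {
    invisible(simulateGrm(uniSpec(), 50L, seed = 99L))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("invalid specifications are rejected", {
  expect_error(grmSpec(a = c(2, -1), b = equallySpacedThresholds(2)),
               "positive")
  expect_error(grmSpec(a = c(2, 2),
                       b = matrix(c(0, 1, 1, 0.5), 2L, 2L, byrow = TRUE)),
               "increasing")
  expect_error(injectViolation(uniSpec(), "nonmonotone_step", 1L, 1.2),
               "magnitude")
  expect_error(injectViolation(uniSpec(), "crossing_irf", 1L, 0.5),
               "multiplier")
  expect_error(injectViolation(uniSpec(), "second_dimension", 1L, 2),
               "loading")
})

test_that("simulated step endorsement rates match the quadrature oracle", {
  spec <- uniSpec(a = 2)
  n <- 5000L
  m <- simulateGrm(spec, n, seed = 73L)
  v <- responseValues(m)
  for (i in 1:5) for (k in 2:5) {
    pHat <- mean(v[, i] >= k)
    p <- grmMarginalStep(spec@a[i], spec@b[i, k - 1L])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(pHat - p), 2.5 * se + 1e-9,
              label = sprintf("item %d step %d", i, k))
  }
})

test_that("huge discriminations give near-deterministic Guttman responses", {
  spec <- grmSpec(a = rep(50, 5), b = equallySpacedThresholds(5),
                  itemLabels = paste0("it", 1:5))
  m <- simulateGrm(spec, 3000L, seed = 74L)
  expect_gt(hScale(computeHScale(m)), 0.95)
})

test_that("committed preset thresholds reproduce the calibration targets", {
  spec <- eq5d5lSpec()
  recal <- calibrateGrmThresholds(eq5d5lTargets(), a = spec@a)
  expect_equal(unname(spec@b), unname(recal), tolerance = 1e-5)
  ## and the quadrature marginals hit the targets (thresholds are committed
  ## to 6 decimals, so agreement is to ~1e-5 absolute)
  for (it in seq_len(5L)) for (k in 1:4)
    expect_lt(abs(grmMarginalStep(spec@a[it], spec@b[it, k]) -
                  eq5d5lTargets()[[it]][k]), 2e-5)
})

test_that("zero-magnitude violations leave the generator unchanged", {
  spec <- uniSpec()
  s0 <- injectViolation(spec, "nonmonotone_step", 2L, 0)
  s1 <- injectViolation(spec, "second_dimension", 2L, 0)
  s2 <- injectViolation(spec, "crossing_irf", 2L, 1)
  for (s in list(s0, s1, s2))
    expect_identical(responseValues(simulateGrm(s, 300L, seed = 75L)),
                     responseValues(simulateGrm(spec, 300L, seed = 75L)))
})

test_that("a second-dimension violation depresses the item's scalability", {
  spec <- injectViolation(uniSpec(a = 2), "second_dimension", 3L,
                          magnitude = 0.85)
  m <- simulateGrm(spec, 5000L, seed = 76L)
  hi <- hItem(computeHScale(m))
  expect_equal(unname(which.min(hi)), 3L)
})

test_that("the preset sample reproduces the published severity shares", {
  m <- eq5d5lPreset(20000L, seed = 77L)
  v <- responseValues(m)
  targets <- eq5d5lTargets()
  for (it in names(targets)) {
    noProblems <- 1 - targets[[it]][1L]
    expect_lt(abs(mean(v[, it] == 1L) - noProblems), 0.02)
  }
  expect_error(eq5d5lPreset(50L), "n >= 100")
})

test_that("preset subgroups shift the latent health distribution", {
  groups <- list(
    healthy = list(prop = 0.5, thetaShift = -0.8),
    depression = list(prop = 0.5, thetaShift = 0.2, adShift = 1.5))
  m <- eq5d5lPreset(8000L, seed = 78L, groups = groups)
  gi <- groupInfo(m)
  expect_setequal(unique(gi$group), c("healthy", "depression"))
  v <- responseValues(m)
  lss <- levelSumScore(m)
  expect_lt(mean(lss[gi$group == "healthy"]),
            mean(lss[gi$group == "depression"]))
  ## the depression-like group endorses AD more readily than MO
  dep <- gi$group == "depression"
  expect_gt(mean(v[dep, "AD"]), mean(v[dep, "MO"]))
})
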