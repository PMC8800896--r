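test_that("rest-score grouping merges left to right to reach minsize", {
  ## hand-traced merge: counts 3,2,3,2 at minsize 3 -> {4}, {5,6}, {7} has an
  ## undersized tail, so the final partition is {4}, {5,6,7}
  g <- makeRestGroups(c(4, 4, 4, 5, 5, 6, 6, 6, 7, 7), minsize = 3L)
  expect_equal(nGroups(g), 2L)
  expect_equal(g@valueGroup$group, c(1L, 2L, 2L, 2L))
  expect_equal(g@counts, c(3L, 7L))
})

test_that("rest-score groups respect the minimum size on realistic data", {
  withr::with_seed(17L, {
    rest <- sample(4:20, 1700L, replace = TRUE)
    g <- makeRestGroups(rest, minsize = 100L)
    expect_true(all(g@counts >= 100L))
    expect_equal(sum(g@counts), 1700L)
    ## contiguity: group ids are non-decreasing over sorted values
    expect_true(all(diff(g@valueGroup$group) %in% c(0L, 1L)))
  })
})

test_that("degenerate rest scores collapse to a single group", {
  g <- makeRestGroups(rep(7L, 120L), minsize = 50L)
  expect_equal(nGroups(g), 1L)
  expect_warning(gs <- makeRestGroups(c(1, 2, 3), minsize = 50L), "minsize")
  expect_equal(nGroups(gs), 1L)
})

test_that("latent-monotone data show no manifest violations", {
  m <- simulateGrm(uniSpec(a = 2), 5000L, seed = 401L)
  rep <- checkMonotonicity(m)
  expect_true(all(rep@summary$vi == 0L))
  expect_true(all(rep@summary$crit == 0))
  expect_true(all(rep@summary$ac > 0L))
})

test_that("an injected ISRF dip is flagged as a manifest violation", {
  spec <- injectViolation(uniSpec(a = 3), "nonmonotone_step", item = 3L,
                          magnitude = 0.2)
  m <- simulateGrm(spec, 5000L, seed = 402L)
  rep <- checkMonotonicity(m, items = 3L)
  expect_gte(rep@summary$vi, 1L)
  expect_gt(rep@summary$maxvi, 0.03)
  expect_gt(rep@summary$crit, 0)
})

test_that("minvi = 1 suppresses every violation", {
  spec <- injectViolation(uniSpec(), "nonmonotone_step", item = 2L,
                          magnitude = 0.3)
  m <- simulateGrm(spec, 3000L, seed = 403L)
  rep <- checkMonotonicity(m, minvi = 1)
  expect_true(all(rep@summary$vi == 0L))
  expect_true(all(rep@summary$crit == 0))
})

test_that("ISRFs are non-increasing in the step within every group", {
  for (seed in c(1L, 2L)) {
    m <- simulateGrm(uniSpec(), 1200L, seed = seed)
    rep <- checkMonotonicity(m)
    for (it in names(rep@isrf)) {
      tab <- rep@isrf[[it]]
      for (g in unique(tab$group)) {
        p <- tab$prob[tab$group == g][order(tab$step[tab$group == g])]
        expect_true(all(diff(p) <= 1e-12))
      }
    }
  }
})

test_that("the IRF equals levelMin plus the summed ISRFs", {
  m <- simulateGrm(uniSpec(), 1500L, seed = 5L)
  tabs <- irfTable(m, 2L)
  bySum <- tapply(tabs$isrf$prob, tabs$isrf$group, sum) + 1
  expect_equal(as.numeric(bySum), tabs$irf$irf, tolerance = 1e-12)
})

test_that("Guttman data produce step-function ISRFs hitting 0 and 1", {
  m <- guttmanFixture(n = 300L)
  tabs <- irfTable(m, 1L, minsize = 30L)
  expect_true(all(tabs$isrf$prob %in% c(0, 1)))
  ## and the IRF is non-decreasing across groups
  expect_true(all(diff(tabs$irf$irf) >= -1e-12))
})

test_that("IRFs from monotone generators rise across rest-score groups", {
  m <- simulateGrm(uniSpec(a = 2), 4000L, seed = 19L)
  for (i in 1:5) {
    tab <- irfTable(m, i)$irf
    expect_true(all(diff(tab$irf) > -0.05))
  }
})

test_that("crit is zero exactly when no violation is flagged", {
  expect_equal(critComposite(0.5, 40L, 0L, 0, 0), 0)
  expect_gt(critComposite(0.5, 40L, 1L, 0.05, 2), 0)
  ## monotone in the violation count and size
  expect_gte(critComposite(0.4, 40L, 4L, 0.1, 3),
             critComposite(0.4, 40L, 2L, 0.1, 3))
  expect_gte(critComposite(0.4, 40L, 2L, 0.2, 3),
             critComposite(0.4, 40L, 2L, 0.1, 3))
})

test_that("a constant item is reported as undefined, not crashed", {
  v <- cbind(rep(2L, 600L), sample(1:5, 600L, replace = TRUE),
             sample(1:5, 600L, replace = TRUE))
  rep <- checkMonotonicity(ResponseMatrix(v))
  expect_true(rep@summary$undefined[[1L]])
  expect_false(any(rep@summary$undefined[2:3]))
})
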