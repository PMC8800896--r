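#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Ordinal questionnaire responses
#'
#' An N persons by J items matrix of integer response levels, together with
#' the admissible level range and optional per-person grouping variables
#' (e.g. disease, country) used for stratified analyses. For the EQ-5D-5L the
#' five items are mobility (MO), self-care (SC), usual activities (UA),
#' pain/discomfort (PD) and anxiety/depression (AD), each scored 1 ("no
#' problems") to 5 ("extreme problems"/"unable to"); the level sum score
#' (LSS) of a person is the plain sum of their J levels.
#'
#' @slot values integer matrix, persons in rows, items in columns; every
#'   entry lies in `[levelMin, levelMax]`.
#' @slot levelMin,levelMax integer level bounds (defaults 1 and 5).
#' @slot groupInfo optional `data.frame` with one row per person holding
#'   categorical grouping columns, or `NULL`.
#'
#' @seealso [ResponseMatrix()] for the user-facing constructor,
#'   [levelSumScore()], [restScores()], [readResponses()].
#' @export
setClass("ResponseMatrix",
  slots = c(values = "matrix",
            levelMin = "integer",
            levelMax = "integer",
            groupInfo = "data.frameOrNULL"),
  prototype = prototype(levelMin = 1L, levelMax = 5L, groupInfo = NULL))

setValidity("ResponseMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  else {
    if (nrow(v) < 1L) msgs <- c(msgs, "need at least one person (N >= 1)")
    if (ncol(v) < 2L) msgs <- c(msgs, "need at least two items (J >= 2)")
    if (anyNA(v)) msgs <- c(msgs, "missing responses are not allowed inside a ResponseMatrix; handle them at read time")
    else if (any(v != round(v))) msgs <- c(msgs, "responses must be integer levels")
    else {
      bad <- which(v < object@levelMin | v > object@levelMax, arr.ind = TRUE)
      if (nrow(bad) > 0L)
        msgs <- c(msgs, sprintf(
          "response out of bounds [%d, %d] at person %d, item %d (value %g)",
          object@levelMin, object@levelMax, bad[1L, 1L], bad[1L, 2L],
          v[bad[1L, , drop = FALSE]]))
    }
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msgs <- c(msgs, "items must carry unique labels (column names)")
  }
  if (length(object@levelMin) != 1L || length(object@levelMax) != 1L ||
      object@levelMin >= object@levelMax)
    msgs <- c(msgs, "levelMin must be a single integer < levelMax")
  if (!is.null(object@groupInfo) && nrow(object@groupInfo) != nrow(v))
    msgs <- c(msgs, "groupInfo must have one row per person")
  if (length(msgs)) msgs else TRUE
})

#' Loevinger scalability coefficients
#'
#' Holds the pairwise (`Hij`), item (`Hi`) and scale (`Hs`) scalability
#' coefficients of a set of ordinal items: each is the observed covariance
#' normalized by its maximum given the item marginals. Standard-error slots
#' are filled by [scalabilitySE()]; `zPair` carries one-sided positivity test
#' statistics for `Hij > 0`. Items with zero variance have undefined
#' coefficients and are flagged in `undefinedItems` rather than dropped.
#'
#' @slot covPair,covmaxPair J x J matrices of observed and maximal pairwise
#'   covariances (population convention; diagonals hold item variances and 0).
#' @slot hPair J x J symmetric matrix of Hij (diagonal `NA`).
#' @slot hItem named numeric vector of Hi.
#' @slot hScale scalar Hs (ratio of summed covariances over item pairs).
#' @slot sePair,seItem,seScale bootstrap standard errors (`NA` until
#'   [scalabilitySE()] is run).
#' @slot zPair positivity-test z statistics per pair.
#' @slot undefinedItems logical flags for zero-variance items.
#' @slot nPersons,nBoot sample size and bootstrap replicate count.
#' @export
setClass("ScalabilityResult",
  slots = c(covPair = "matrix", covmaxPair = "matrix", hPair = "matrix",
            hItem = "numeric", hScale = "numeric",
            sePair = "matrix", seItem = "numeric", seScale = "numeric",
            zPair = "matrix", undefinedItems = "logical",
            nPersons = "integer", nBoot = "integer"))

#' Automated item selection result
#'
#' Partition of the items into Mokken scales at a lower bound `c` on the item
#' scalability coefficient: `scaleAssignment[i]` is the 1-based id of the
#' scale item i was assigned to, or 0 for unscalable items.
#'
#' @slot scaleAssignment named integer vector over items.
#' @slot scaleH per-scale Hs values.
#' @slot lbound the lower bound c used.
#' @slot zCrit critical value of the pairwise positivity test used during
#'   selection.
#' @export
setClass("AispResult",
  slots = c(scaleAssignment = "integer", scaleH = "numeric",
            lbound = "numeric", zCrit = "numeric"))

#' Lower-bound sweep of the automated item selection procedure
#'
#' @slot grid the lower-bound values swept.
#' @slot assignments items x grid matrix of scale ids (0 = unscalable).
#' @slot results list of [AispResult-class] objects, one per grid value.
#' @export
setClass("AispSweep",
  slots = c(grid = "numeric", assignments = "matrix", results = "list"))

#' Rest-score grouping
#'
#' Deterministic partition of observed rest scores into contiguous ordered
#' groups, each holding at least `minsize` persons (adjacent rest-score
#' values are merged left to right; an undersized trailing group is merged
#' backwards).
#'
#' @slot valueGroup `data.frame` with columns `value` (rest score) and
#'   `group` (1-based ordered group id).
#' @slot counts persons per group.
#' @slot minsize the minimum group size requested.
#' @export
setClass("RestScoreGrouping",
  slots = c(valueGroup = "data.frame", counts = "integer", minsize = "integer"))

#' Manifest monotonicity report
#'
#' Item step response functions (ISRFs) estimated over rest-score groups and
#' the violation summary per item: active comparisons (`ac`), violations
#' exceeding `minvi` (`vi`), the largest violation (`maxvi`), the largest
#' violation z statistic (`zmax`) and the composite `crit` severity index.
#'
#' @slot summary per-item `data.frame` (item, mean, Hi, ac, vi, maxvi, zmax,
#'   nsig, crit, undefined).
#' @slot isrf named list of per-item ISRF tables (group, rest range, n, step,
#'   probability).
#' @slot irf named list of per-item IRF tables (group, conditional mean).
#' @slot grouping named list of [RestScoreGrouping-class] objects.
#' @slot minvi,minsize,alpha the thresholds used.
#' @export
setClass("MonotonicityReport",
  slots = c(summary = "data.frame", isrf = "list", irf = "list",
            grouping = "list", minvi = "numeric", minsize = "integer",
            alpha = "numeric"))

#' Manifest invariant item ordering report
#'
#' Items are ordered by their overall mean score (highest mean = easiest to
#' endorse, listed first); each ordered pair is checked for reversals of the
#' conditional means across joint rest-score groups. `ht` is the HT
#' coefficient: the scale scalability of the transposed (persons as items)
#' matrix, measuring how accurately the sample follows one item ordering.
#'
#' @slot itemOrder item labels, easiest first.
#' @slot itemMeans named mean scores.
#' @slot pairTable per ordered pair: groups compared (`ac`), violations
#'   (`vi`), `maxvi`, largest reversal t statistic (`tmax`), significant
#'   reversals (`nsig`).
#' @slot itemSummary per-item aggregation with the composite `crit`.
#' @slot removedItems items removed by [backwardSelection()], in order.
#' @slot ht,htClass HT coefficient and its accuracy label.
#' @slot minvi,minsize,alpha thresholds used (default minvi is
#'   `0.03 * (levelMax - levelMin)`).
#' @export
setClass("IIOReport",
  slots = c(itemOrder = "character", itemMeans = "numeric",
            pairTable = "data.frame", itemSummary = "data.frame",
            removedItems = "character", ht = "numeric", htClass = "character",
            minvi = "numeric", minsize = "integer", alpha = "numeric"))

#' Scale reliability estimates
#'
#' @slot lambda2 Guttman's lambda-2 (unclipped).
#' @slot lambda2Clipped lambda-2 clipped to `[0, 1]`.
#' @slot msRho Molenaar-Sijtsma rho.
#' @slot alpha Cronbach's alpha (internal cross-check; lambda2 >= alpha).
#' @slot nPersons sample size.
#' @slot defined `FALSE` when the total-score variance is zero.
#' @export
setClass("ReliabilityReport",
  slots = c(lambda2 = "numeric", lambda2Clipped = "numeric",
            msRho = "numeric", alpha = "numeric", nPersons = "integer",
            defined = "logical"))

#' Graded response model generator specification
#'
#' Defines an item bank for the logistic graded response model used as the
#' monotone-homogeneity-true data source: step k of item i is endorsed with
#' probability `plogis(a_i * (t_i - b_ik))`, where the item trait `t_i =
#' loading_i * theta + sqrt(1 - loading_i^2) * noise` mixes the dominant
#' latent health factor theta ~ N(0,1) with an item-specific second factor.
#' Violation descriptors (non-monotone step, crossing IRF, second dimension)
#' may be attached via [injectViolation()].
#'
#' @slot a positive per-item discriminations.
#' @slot b J x (levels-1) matrix of strictly increasing step locations.
#' @slot traitLoading per-item loading on the dominant factor, in `[0, 1]`.
#' @slot itemLabels item names.
#' @slot levelMin,levelMax response level bounds.
#' @slot violations list of attached violation descriptors.
#' @export
setClass("GrmSpec",
  slots = c(a = "numeric", b = "matrix", traitLoading = "numeric",
            itemLabels = "character", levelMin = "integer",
            levelMax = "integer", violations = "list"),
  prototype = prototype(levelMin = 1L, levelMax = 5L, violations = list()))

setValidity("GrmSpec", function(object) {
  j <- length(object@a)
  msgs <- character(0)
  if (any(object@a <= 0)) msgs <- c(msgs, "discriminations must be positive")
  if (nrow(object@b) != j)
    msgs <- c(msgs, "threshold matrix must have one row per item")
  if (ncol(object@b) != object@levelMax - object@levelMin)
    msgs <- c(msgs, "need levelMax - levelMin step locations per item")
  if (ncol(object@b) > 1L && any(t(apply(object@b, 1L, diff)) <= 0))
    msgs <- c(msgs, "step locations must be strictly increasing within item")
  if (length(object@traitLoading) != j ||
      any(object@traitLoading < 0 | object@traitLoading > 1))
    msgs <- c(msgs, "traitLoading must lie in [0, 1] for every item")
  if (length(object@itemLabels) != j || anyDuplicated(object@itemLabels))
    msgs <- c(msgs, "itemLabels must be unique, one per item")
  if (length(msgs)) msgs else TRUE
})

#' Full study report
#'
#' Result of [runFullAnalysis()]: the pooled analysis battery plus one block
#' per stratum of each grouping variable, each holding scalability,
#' monotonicity, invariant item ordering, HT, reliability and level-sum-score
#' summaries, and (when configured) the same battery with listed items
#' excluded.
#'
#' @slot results named list of analysis blocks; the pooled block is named
#'   `"pooled"`.
#' @slot config the resolved analysis configuration.
#' @slot seed the master seed used.
#' @export
setClass("StudyReport",
  slots = c(results = "list", config = "list", seed = "numeric"))
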