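#' Automated item selection procedure (AISP)
#'
#' Mokken's hierarchical bottom-up clustering of items into scales at a lower
#' bound `c` on the item scalability coefficient. The first scale is seeded
#' with the largest significantly positive Hij that is at least `c`; items
#' are then added one at a time, choosing the candidate that maximizes the
#' scale's Hs among those whose (a) Hi with the current selection is at least
#' `c` and (b) pairwise associations with all selected items are
#' significantly positive. When no candidate remains, a new scale is started
#' on the leftover items. Significance uses a one-sided Fisher-z positivity
#' test with a Bonferroni correction over the item pairs active at seeding;
#' ties on H are broken by the lowest item index, so the procedure is fully
#' deterministic.
#'
#' @param m a [ResponseMatrix-class].
#' @param lbound lower bound c in `[0, 1)` (default 0.3).
#' @param alpha significance level for the positivity test (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return an [AispResult-class]; `scaleAssignment` gives 0 for unscalable
#'   items. An all-unscalable result is valid.
#' @export
runAisp <- function(m, lbound = 0.3, alpha = 0.05,
                    correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (lbound < 0 || lbound >= 1) stop("lbound must lie in [0, 1)")
  ps <- pairStatistics(responseValues(m), m@levelMin, m@levelMax)
  aispFromStats(ps, lbound, alpha, correction, itemLabels(m))
}

## Core AISP on precomputed pair statistics (reused by sweeps/refinement so
## the covariance surface is computed once per dataset).
aispFromStats <- function(ps, lbound, alpha, correction, labs) {
  j <- length(labs)
  assign <- stats::setNames(integer(j), labs)
  usable <- ps$var > 0
  remaining <- which(usable)
  nPairsAll <- sum(usable) * (sum(usable) - 1) / 2
  zCrit <- if (correction == "bonferroni" && nPairsAll >= 1)
    stats::qnorm(1 - alpha / nPairsAll) else stats::qnorm(1 - alpha)
  sid <- 0L
  while (length(remaining) >= 2L) {
    ## seed pair: max Hij among significantly positive pairs with Hij >= c
    best <- NULL; bestH <- -Inf
    for (a in remaining) for (b in remaining) {
      if (a >= b) next
      if (ps$covmax[a, b] <= 0) next
      h <- ps$cov[a, b] / ps$covmax[a, b]
      z <- ps$z[a, b]
      if (is.finite(h) && is.finite(z) && h >= lbound && z > zCrit &&
          h > bestH + 1e-12) {
        bestH <- h; best <- c(a, b)
      }
    }
    if (is.null(best)) break
    sel <- best
    repeat {
      cand <- setdiff(remaining, sel)
      bestItem <- NA_integer_; bestScaleH <- -Inf
      for (u in cand) {
        zu <- ps$z[u, sel]
        if (any(!is.finite(zu)) || any(zu <= zCrit)) next
        den <- sum(ps$covmax[u, sel])
        if (den <= 0) next
        hiU <- sum(ps$cov[u, sel]) / den
        if (hiU < lbound) next
        trial <- c(sel, u)
        pr <- utils::combn(trial, 2L)
        hsT <- sum(ps$cov[cbind(pr[1L, ], pr[2L, ])]) /
          sum(ps$covmax[cbind(pr[1L, ], pr[2L, ])])
        if (hsT > bestScaleH + 1e-12) { bestScaleH <- hsT; bestItem <- u }
      }
      if (is.na(bestItem)) break
      sel <- c(sel, bestItem)
    }
    sid <- sid + 1L
    assign[sel] <- sid
    remaining <- setdiff(remaining, sel)
  }
  scaleH <- numeric(0)
  if (sid > 0L) {
    scaleH <- vapply(seq_len(sid), function(s) {
      it <- which(assign == s)
      pr <- utils::combn(it, 2L)
      sum(ps$cov[cbind(pr[1L, ], pr[2L, ])]) /
        sum(ps$covmax[cbind(pr[1L, ], pr[2L, ])])
    }, numeric(1L))
    names(scaleH) <- paste0("scale", seq_len(sid))
  }
  new("AispResult", scaleAssignment = assign, scaleH = scaleH,
      lbound = lbound, zCrit = zCrit)
}

#' @rdname AispResult-class
#' @export
setMethod("scaleAssignment", "AispResult",
          function(object) object@scaleAssignment)

setMethod("show", "AispResult", function(object) {
  cat(sprintf("AISP at lower bound c = %.3f\n", object@lbound))
  for (s in seq_along(object@scaleH))
    cat(sprintf("  scale %d (Hs = %.3f): %s\n", s, object@scaleH[s],
                paste(names(object@scaleAssignment)[object@scaleAssignment == s],
                      collapse = ", ")))
  un <- names(object@scaleAssignment)[object@scaleAssignment == 0L]
  if (length(un)) cat("  unscalable:", paste(un, collapse = ", "), "\n")
})

#' Sweep the AISP lower bound over a grid
#'
#' Re-runs the selection at each grid value of the lower bound (default 0 to
#' 0.55 in steps of 0.05, i.e. twelve runs) and tabulates scale membership
#' against c — the coarse stage of locating per-item exclusion thresholds.
#'
#' @param m a [ResponseMatrix-class].
#' @param gridStart,gridStop,gridStep sweep grid (requires
#'   `0 <= gridStart < gridStop`, `gridStep > 0`).
#' @inheritParams runAisp
#' @return an [AispSweep-class].
#' @export
sweepLbound <- function(m, gridStart = 0, gridStop = 0.55, gridStep = 0.05,
                        alpha = 0.05, correction = "bonferroni") {
  if (gridStart < 0 || gridStart >= gridStop || gridStep <= 0)
    stop("need 0 <= gridStart < gridStop and gridStep > 0")
  grid <- seq(gridStart, gridStop, by = gridStep)
  if (!length(grid)) stop("empty lower-bound grid")
  ps <- pairStatistics(responseValues(m), m@levelMin, m@levelMax)
  labs <- itemLabels(m)
  results <- lapply(grid, function(cc)
    aispFromStats(ps, cc, alpha, correction, labs))
  assignments <- vapply(results, scaleAssignment, integer(length(labs)))
  dimnames(assignments) <- list(labs, sprintf("%.3f", grid))
  new("AispSweep", grid = grid, assignments = assignments, results = results)
}

setMethod("show", "AispSweep", function(object) {
  cat(sprintf("AISP lower-bound sweep over %d values (%.2f..%.2f)\n",
              length(object@grid), min(object@grid), max(object@grid)))
  print(object@assignments)
})

#' Pinpoint an item's exclusion threshold
#'
#' The fine stage of the two-stage sweep: starting from the coarsest grid
#' value at which `item` is no longer selected into any scale, the lower
#' bound is decreased in steps of `resolution` (default 0.001) until the item
#' is selected again; the smallest bound at which the item stays excluded is
#' returned. Returns `Inf` (sentinel: never excluded) if the item is selected
#' at every bound on `[gridStart, gridStop]`.
#'
#' @param m a [ResponseMatrix-class].
#' @param item item label or index.
#' @param resolution threshold resolution (default 0.001).
#' @inheritParams sweepLbound
#' @return scalar threshold (or `Inf`).
#' @export
refineExclusionThreshold <- function(m, item, resolution = 0.001,
                                     gridStart = 0, gridStop = 0.75,
                                     gridStep = 0.05, alpha = 0.05,
                                     correction = "bonferroni") {
  idx <- resolveItems(m, item)
  if (length(idx) != 1L) stop("need a single item")
  ps <- pairStatistics(responseValues(m), m@levelMin, m@levelMax)
  labs <- itemLabels(m)
  selectedAt <- function(cc)
    aispFromStats(ps, cc, alpha, correction, labs)@scaleAssignment[idx] > 0L
  grid <- seq(gridStart, gridStop, by = gridStep)
  excl <- which(!vapply(grid, selectedAt, logical(1L)))
  if (!length(excl)) return(Inf)
  ## walk down from the coarse cutoff in integer multiples of `resolution`;
  ## the last still-excluded bound wins
  k <- roundHalfUp(grid[excl[1L]] / resolution)
  threshold <- k * resolution
  k <- k - 1L
  while (k * resolution >= gridStart) {
    if (selectedAt(k * resolution)) break
    threshold <- k * resolution
    k <- k - 1L
  }
  threshold
}
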