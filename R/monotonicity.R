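#' Default minimum rest-score group size
#'
#' `floor(N/10)` for samples of 500 or more, otherwise `floor(N/5)` with a
#' floor of 50.
#'
#' @param n sample size.
#' @return integer minimum group size.
#' @export
defaultMinsize <- function(n) {
  if (n >= 500L) n %/% 10L else max(n %/% 5L, 50L)
}

#' Build rest-score groups
#'
#' Adjacent rest-score values are merged left to right (ascending) until
#' every group holds at least `minsize` persons; if the trailing group ends
#' up undersized it is merged backwards into its neighbour. The partition is
#' contiguous, ordered, covers all persons, and is deterministic.
#'
#' @param rest integer vector of rest scores.
#' @param minsize minimum persons per group (default [defaultMinsize()]).
#' @return a [RestScoreGrouping-class]. If fewer than `minsize` persons exist
#'   altogether, a single-group result is returned with a warning.
#' @export
makeRestGroups <- function(rest, minsize = defaultMinsize(length(rest))) {
  minsize <- as.integer(minsize)
  tab <- table(rest)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  if (length(rest) < minsize) {
    warning("fewer persons than minsize; returning a single rest-score group")
    vg <- data.frame(value = vals, group = 1L)
    return(new("RestScoreGrouping", valueGroup = vg,
               counts = length(rest), minsize = minsize))
  }
  group <- integer(length(vals))
  g <- 1L; acc <- 0L
  for (i in seq_along(vals)) {
    group[i] <- g
    acc <- acc + cnt[i]
    if (acc >= minsize && i < length(vals)) { g <- g + 1L; acc <- 0L }
  }
  ## undersized trailing group: merge backwards
  if (acc > 0L && acc < minsize && g > 1L) group[group == g] <- g - 1L
  ids <- unique(group)
  group <- match(group, ids)
  counts <- vapply(seq_along(ids), function(k) sum(cnt[group == k]),
                   integer(1L))
  new("RestScoreGrouping",
      valueGroup = data.frame(value = vals, group = group),
      counts = counts, minsize = minsize)
}

#' Number of groups in a rest-score grouping
#' @param grouping a [RestScoreGrouping-class].
#' @export
nGroups <- function(grouping) length(grouping@counts)

#' Assign persons to rest-score groups
#'
#' @param grouping a [RestScoreGrouping-class].
#' @param rest rest scores (must only contain values seen when the grouping
#'   was built).
#' @return integer group ids.
#' @export
assignGroups <- function(grouping, rest) {
  idx <- match(rest, grouping@valueGroup$value)
  if (anyNA(idx)) stop("rest score outside the grouping's support")
  grouping@valueGroup$group[idx]
}

setMethod("show", "RestScoreGrouping", function(object) {
  cat(sprintf("RestScoreGrouping: %d groups (minsize %d)\n",
              length(object@counts), object@minsize))
  for (g in seq_along(object@counts)) {
    v <- object@valueGroup$value[object@valueGroup$group == g]
    cat(sprintf("  group %d: rest %d..%d, n = %d\n", g, min(v), max(v),
                object@counts[g]))
  }
})

## ISRF/IRF estimates for one item over a grouping. Returns list(isrf, irf).
isrfEstimates <- function(x, item, groupId, nG, levelMin, levelMax) {
  steps <- (levelMin + 1L):levelMax
  xi <- x[, item]
  nPer <- tabulate(groupId, nG)
  prob <- matrix(NA_real_, nG, length(steps),
                 dimnames = list(NULL, paste0("step", steps)))
  for (s in seq_along(steps))
    prob[, s] <- tapply(xi >= steps[s], factor(groupId, seq_len(nG)), mean)
  irf <- levelMin + rowSums(prob)
  list(prob = prob, irf = irf, n = nPer, steps = steps)
}

#' Check manifest monotonicity
#'
#' For every item: persons are grouped by the item's rest score, the item
#' step response functions P(X >= k | group) are estimated per group, and
#' every ordered group pair (g < g') at every step is compared. A violation
#' is flagged when the estimated probability drops by more than `minvi`
#' (default 0.03) from the lower to the higher group; each flagged comparison
#' gets a one-sided two-proportion z test. Per item the summary reports the
#' active comparisons (`ac`), violations (`vi`), `maxvi`, `zmax`, the number
#' of significant violations (`nsig`) and a composite `crit` severity index
#' (see [critComposite()]); `crit` is 0 exactly when no violation is flagged.
#'
#' @param m a [ResponseMatrix-class].
#' @param items item labels/indices to check (default: all).
#' @param minvi minimum probability drop counted as a violation.
#' @param minsize minimum rest-score group size (default [defaultMinsize()]).
#' @param alpha significance level for the violation z tests.
#' @return a [MonotonicityReport-class].
#' @export
checkMonotonicity <- function(m, items = itemLabels(m), minvi = 0.03,
                              minsize = defaultMinsize(nPersons(m)),
                              alpha = 0.05) {
  idx <- resolveItems(m, items)
  x <- responseValues(m)
  labs <- itemLabels(m)
  sc <- computeHScale(m)
  lss <- rowSums(x)
  isrfs <- list(); irfs <- list(); groupings <- list()
  rows <- list()
  for (i in idx) {
    lab <- labs[i]
    if (sc@undefinedItems[i]) {
      rows[[lab]] <- data.frame(item = lab, mean = mean(x[, i]),
                                Hi = NA_real_, ac = 0L, vi = 0L,
                                maxvi = 0, zmax = 0, nsig = 0L, crit = NA_real_,
                                undefined = TRUE)
      next
    }
    rest <- lss - x[, i]
    grouping <- makeRestGroups(rest, minsize)
    gid <- assignGroups(grouping, rest)
    nG <- nGroups(grouping)
    est <- isrfEstimates(x, i, gid, nG, m@levelMin, m@levelMax)
    ac <- 0L; vi <- 0L; maxvi <- 0; zmax <- 0; nsig <- 0L
    zc <- stats::qnorm(1 - alpha)
    if (nG >= 2L) {
      for (s in seq_along(est$steps)) {
        p <- est$prob[, s]
        for (g in seq_len(nG - 1L)) for (h in (g + 1L):nG) {
          ac <- ac + 1L
          d <- p[g] - p[h]
          if (is.finite(d) && d > minvi) {
            vi <- vi + 1L
            maxvi <- max(maxvi, d)
            n1 <- est$n[g]; n2 <- est$n[h]
            pb <- (p[g] * n1 + p[h] * n2) / (n1 + n2)
            se <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
            z <- if (se > 0) d / se else 0
            zmax <- max(zmax, z)
            if (z > zc) nsig <- nsig + 1L
          }
        }
      }
    }
    grpVals <- grouping@valueGroup
    restMin <- vapply(seq_len(nG), function(g)
      min(grpVals$value[grpVals$group == g]), integer(1L))
    restMax <- vapply(seq_len(nG), function(g)
      max(grpVals$value[grpVals$group == g]), integer(1L))
    isrfs[[lab]] <- data.frame(
      group = rep(seq_len(nG), length(est$steps)),
      restMin = rep(restMin, length(est$steps)),
      restMax = rep(restMax, length(est$steps)),
      restMid = rep((restMin + restMax) / 2, length(est$steps)),
      n = rep(est$n, length(est$steps)),
      step = rep(est$steps, each = nG),
      prob = as.vector(est$prob))
    irfs[[lab]] <- data.frame(group = seq_len(nG), restMin = restMin,
                              restMax = restMax,
                              restMid = (restMin + restMax) / 2,
                              n = est$n, irf = est$irf)
    groupings[[lab]] <- grouping
    rows[[lab]] <- data.frame(
      item = lab, mean = mean(x[, i]), Hi = sc@hItem[i], ac = ac, vi = vi,
      maxvi = maxvi, zmax = zmax, nsig = nsig,
      crit = critComposite(sc@hItem[i], ac, vi, maxvi, zmax),
      undefined = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  new("MonotonicityReport", summary = summary, isrf = isrfs, irf = irfs,
      grouping = groupings, minvi = minvi, minsize = as.integer(minsize),
      alpha = alpha)
}

#' Composite violation severity index
#'
#' A documented weighted composite in the tradition of the MSP manual:
#' `crit = round(w1 * max(0, 0.3 - Hi) + w2 * sqrt(vi) + w3 * vi / ac +
#' w4 * maxvi + w5 * sqrt(max(zmax, 0)))` with default weights
#' `(50, 1, 100, 100, 10)`, and 0 whenever no violation was flagged. Larger
#' values indicate more serious model misfit; the exact constants are a
#' convention, exposed via `weights`.
#'
#' @param hi item scalability coefficient.
#' @param ac,vi active comparisons and flagged violations.
#' @param maxvi largest violation.
#' @param zmax largest violation test statistic.
#' @param weights the five weights.
#' @return non-negative integer-valued severity.
#' @export
critComposite <- function(hi, ac, vi, maxvi, zmax,
                          weights = c(50, 1, 100, 100, 10)) {
  if (vi == 0L || ac == 0L) return(0)
  hiTerm <- if (is.finite(hi)) max(0, 0.3 - hi) else 0.3
  roundHalfUp(weights[1L] * hiTerm + weights[2L] * sqrt(vi) +
              weights[3L] * vi / ac + weights[4L] * maxvi +
              weights[5L] * sqrt(max(zmax, 0)))
}

#' ISRF/IRF plotting table for one item
#'
#' @param m a [ResponseMatrix-class].
#' @param item item label or index.
#' @param minsize minimum rest-score group size.
#' @return list with `isrf` and `irf` data frames (group midpoints, step
#'   endorsement probabilities, conditional means).
#' @export
irfTable <- function(m, item, minsize = defaultMinsize(nPersons(m))) {
  rep <- checkMonotonicity(m, items = item, minsize = minsize)
  lab <- itemLabels(m)[resolveItems(m, item)]
  list(isrf = rep@isrf[[lab]], irf = rep@irf[[lab]])
}

setMethod("show", "MonotonicityReport", function(object) {
  cat(sprintf("Manifest monotonicity (minvi = %.3f, minsize = %d)\n",
              object@minvi, object@minsize))
  print(object@summary[, c("item", "mean", "Hi", "ac", "vi", "maxvi",
                           "zmax", "crit")], digits = 3)
})
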