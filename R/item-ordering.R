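#' Check manifest invariant item ordering (MIIO)
#'
#' Items are ordered by their overall mean scores (highest mean = easiest to
#' endorse, listed first; for the EQ-5D-5L "easy" means problems are reported
#' readily, so pain/discomfort is typically easiest and self-care hardest).
#' Every ordered pair is then inspected over the rest score computed from the
#' other J - 2 items: within each rest-score group a violation is flagged
#' when the harder item's conditional mean exceeds the easier item's by more
#' than `minvi` (default `0.03 * (levelMax - levelMin)`, i.e. the number of
#' item steps times 0.03 — 0.12 for five levels). Flagged reversals receive a
#' one-sided paired t test. Per item the pairs are aggregated into `ac`,
#' `vi`, `maxvi`, `tmax`, `nsig` and the composite `crit`; the HT coefficient
#' (see [coefficientHt()]) summarizes how accurately the sample follows a
#' single item ordering.
#'
#' @param m a [ResponseMatrix-class] with at least 3 items (with J = 2 the
#'   pair rest score would be computed from zero items).
#' @param minvi minimum conditional-mean reversal counted as a violation
#'   (`NULL` for the default).
#' @param minsize minimum rest-score group size.
#' @param alpha significance level for the reversal t tests (uncorrected;
#'   see `correction`).
#' @param correction `"none"` (default) or `"bonferroni"` over all group
#'   comparisons.
#' @return an [IIOReport-class].
#' @export
checkMiio <- function(m, minvi = NULL,
                      minsize = defaultMinsize(nPersons(m)), alpha = 0.05,
                      correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  j <- nItems(m)
  if (j < 3L)
    stop("manifest invariant item ordering needs at least 3 items ",
         "(the pair rest score uses the other J - 2 items)")
  if (is.null(minvi)) minvi <- 0.03 * (m@levelMax - m@levelMin)
  x <- responseValues(m)
  labs <- itemLabels(m)
  means <- colMeans(x)
  names(means) <- labs
  ord <- order(-means, seq_len(j))
  if (anyDuplicated(means[ord]))
    message("tied item means: invariant ordering is ill-defined under ties; ",
            "ties broken by item index")
  sc <- computeHScale(m)
  lss <- rowSums(x)
  pairRows <- list()
  comparisons <- list()
  for (ai in seq_len(j - 1L)) for (bi in (ai + 1L):j) {
    a <- ord[ai]; b <- ord[bi]  # a easier (higher mean) than b
    rest <- lss - x[, a] - x[, b]
    grouping <- makeRestGroups(rest, minsize)
    gid <- assignGroups(grouping, rest)
    nG <- nGroups(grouping)
    ac <- nG
    vi <- 0L; maxvi <- 0; tmax <- 0; nsig <- 0L
    tstats <- rep(NA_real_, nG)
    for (g in seq_len(nG)) {
      inG <- gid == g
      d <- x[inG, b] - x[inG, a]
      reversal <- mean(d)
      if (reversal > minvi) {
        vi <- vi + 1L
        maxvi <- max(maxvi, reversal)
        sdd <- stats::sd(d)
        tg <- if (is.finite(sdd) && sdd > 0) mean(d) / (sdd / sqrt(length(d)))
              else Inf
        tstats[g] <- tg
        tmax <- max(tmax, tg)
      }
    }
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      itemA = labs[a], itemB = labs[b], ac = ac, vi = vi, maxvi = maxvi,
      tmax = tmax, stringsAsFactors = FALSE)
    comparisons[[length(comparisons) + 1L]] <-
      list(a = a, b = b, tstats = tstats, nG = nG)
  }
  totalComparisons <- sum(vapply(comparisons, function(cm) cm$nG, integer(1L)))
  tCrit <- if (correction == "bonferroni")
    stats::qnorm(1 - alpha / max(totalComparisons, 1L)) else
    stats::qnorm(1 - alpha)
  pairTable <- do.call(rbind, pairRows)
  pairTable$nsig <- vapply(comparisons, function(cm)
    sum(cm$tstats > tCrit, na.rm = TRUE), integer(1L))
  itemSummary <- do.call(rbind, lapply(seq_len(j), function(i) {
    lab <- labs[i]
    sel <- pairTable$itemA == lab | pairTable$itemB == lab
    ac <- sum(pairTable$ac[sel]); vi <- sum(pairTable$vi[sel])
    maxvi <- if (any(sel)) max(pairTable$maxvi[sel]) else 0
    tmax <- if (any(sel)) max(pairTable$tmax[sel]) else 0
    data.frame(item = lab, mean = means[i], Hi = sc@hItem[i],
               ac = ac, vi = vi, maxvi = maxvi, tmax = tmax,
               nsig = sum(pairTable$nsig[sel]),
               crit = critComposite(sc@hItem[i], ac, vi, maxvi, tmax),
               stringsAsFactors = FALSE)
  }))
  rownames(itemSummary) <- NULL
  ht <- tryCatch(suppressMessages(coefficientHt(m)),
                 error = function(e) NA_real_)
  new("IIOReport", itemOrder = labs[ord], itemMeans = means,
      pairTable = pairTable, itemSummary = itemSummary,
      removedItems = character(0), ht = ht,
      htClass = if (is.finite(ht)) classifyItemOrdering(ht) else "undefined",
      minvi = minvi, minsize = as.integer(minsize), alpha = alpha)
}

setMethod("show", "IIOReport", function(object) {
  cat(sprintf("Manifest invariant item ordering (minvi = %.3f)\n",
              object@minvi))
  cat("  order (easiest first):", paste(object@itemOrder, collapse = " > "),
      "\n")
  cat(sprintf("  HT = %.3f [%s]\n", object@ht, object@htClass))
  print(object@itemSummary[, c("item", "mean", "ac", "vi", "maxvi", "crit")],
        digits = 3)
  if (length(object@removedItems))
    cat("  removed by backward selection:",
        paste(object@removedItems, collapse = ", "), "\n")
})

#' Backward item selection against ordering violations
#'
#' Iteratively removes the item with the most significant ordering reversals
#' (ties broken by the larger composite `crit`, then by the lower item
#' index), recomputes the MIIO check on the survivors, and stops when no
#' violations remain. Removal stops at 3 items (the smallest set for which
#' the pair rest score exists); if violations persist there, a warning is
#' issued. After termination, re-running [checkMiio()] on the surviving items
#' reproduces zero violations.
#'
#' @param m a [ResponseMatrix-class].
#' @param report an initial [IIOReport-class] (computed if `NULL`).
#' @inheritParams checkMiio
#' @return the final [IIOReport-class] with `removedItems` recording the
#'   removal order.
#' @export
backwardSelection <- function(m, report = NULL, minvi = NULL,
                              minsize = defaultMinsize(nPersons(m)),
                              alpha = 0.05) {
  if (is.null(report))
    report <- checkMiio(m, minvi = minvi, minsize = minsize, alpha = alpha)
  removed <- character(0)
  current <- m
  while (sum(report@itemSummary$vi) > 0L) {
    if (nItems(current) <= 3L) {
      warning("ordering violations remain but only 3 items are left; stopping")
      break
    }
    s <- report@itemSummary
    ord <- order(-s$nsig, -s$crit, seq_len(nrow(s)))
    worst <- s$item[ord[1L]]
    removed <- c(removed, worst)
    current <- dropItems(current, worst)
    report <- checkMiio(current, minvi = minvi, minsize = minsize,
                        alpha = alpha)
  }
  report@removedItems <- removed
  report
}

#' Coefficient HT: item-ordering accuracy
#'
#' The scale scalability coefficient computed on the transposed data matrix
#' (persons play the role of items): high values mean the persons agree on
#' one item ordering. Persons with zero response variance carry no ordering
#' information and are removed first (count reported via `message()`).
#' Computed by a closed-form aggregation over response-pattern classes that
#' is algebraically identical to `hScale(computeHScale(transposeResponses(m)))`
#' but linear in N.
#'
#' @param m a [ResponseMatrix-class].
#' @return scalar HT (`NA` if fewer than two non-constant persons exist).
#' @export
coefficientHt <- function(m) {
  v <- responseValues(m)
  storage.mode(v) <- "double"
  keep <- matrixStatsRowVar(v) > 0
  if (any(!keep))
    message(sum(!keep), " constant-pattern person(s) removed before HT")
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) {
    warning("fewer than 2 non-constant persons: HT undefined")
    return(NA_real_)
  }
  j <- ncol(v)
  mP <- rowMeans(v)
  sq <- rowMeans(v * v)
  diagVar <- sum(sq - mP^2)
  num <- 0.5 * (sum(colSums(v)^2) / j - sum(mP)^2 - diagVar)
  w <- t(apply(v, 1L, sort))
  den <- 0.5 * (sum(colSums(w)^2) / j - sum(mP)^2 - diagVar)
  if (den <= 0) {
    warning("degenerate transposed covariance surface: HT undefined")
    return(NA_real_)
  }
  num / den
}

matrixStatsRowVar <- function(v) rowMeans(v * v) - rowMeans(v)^2

#' Paired item response functions
#'
#' Conditional means of two items over their shared rest score (computed
#' from the other J - 2 items) — the plotting surface for paired-IRF
#' figures. For a pair satisfying invariant ordering the easier item's curve
#' lies on or above the harder item's in every group; crossing curves signal
#' an ordering violation.
#'
#' @param m a [ResponseMatrix-class] with at least 3 items.
#' @param itemA,itemB item labels or indices.
#' @param minsize minimum rest-score group size.
#' @return `data.frame` with columns `group`, `restMin`, `restMax`,
#'   `restMid`, `n`, `meanA`, `meanB`.
#' @export
pairedIrf <- function(m, itemA, itemB,
                      minsize = defaultMinsize(nPersons(m))) {
  if (nItems(m) < 3L) stop("paired IRFs need at least 3 items")
  a <- resolveItems(m, itemA); b <- resolveItems(m, itemB)
  if (length(a) != 1L || length(b) != 1L || a == b)
    stop("need two distinct single items")
  x <- responseValues(m)
  rest <- rowSums(x) - x[, a] - x[, b]
  grouping <- makeRestGroups(rest, minsize)
  gid <- assignGroups(grouping, rest)
  nG <- nGroups(grouping)
  gv <- grouping@valueGroup
  data.frame(
    group = seq_len(nG),
    restMin = vapply(seq_len(nG), function(g)
      min(gv$value[gv$group == g]), integer(1L)),
    restMax = vapply(seq_len(nG), function(g)
      max(gv$value[gv$group == g]), integer(1L)),
    restMid = vapply(seq_len(nG), function(g)
      mean(range(gv$value[gv$group == g])), numeric(1L)),
    n = grouping@counts,
    meanA = vapply(seq_len(nG), function(g) mean(x[gid == g, a]), numeric(1L)),
    meanB = vapply(seq_len(nG), function(g) mean(x[gid == g, b]), numeric(1L)))
}
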