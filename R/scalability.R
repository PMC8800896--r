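#' Maximum covariance given two ordinal marginals
#'
#' The normalizer of the Loevinger H coefficient: the covariance of the
#' comonotonic (Frechet-upper-bound) coupling of the two marginal level
#' distributions, obtained by pairing the sorted cumulative frequencies
#' (northwest-corner walk). It dominates the covariance of every joint
#' distribution with these marginals.
#'
#' @param freqI,freqJ integer level-frequency vectors with equal totals, one
#'   count per level in `levels`.
#' @param levels the level values (default `seq_along(freqI)`).
#' @return the maximal covariance (population convention).
#' @examples
#' maxCovariance(c(2, 2), c(2, 2), levels = 1:2)  # 0.25
#' maxCovariance(c(1, 1, 1), c(1, 1, 1), levels = 1:3)  # 2/3
#' @export
maxCovariance <- function(freqI, freqJ, levels = seq_along(freqI)) {
  if (length(freqI) != length(levels) || length(freqJ) != length(levels))
    stop("frequency vectors must have one entry per level")
  if (any(freqI < 0) || any(freqJ < 0)) stop("negative frequencies")
  if (sum(freqI) != sum(freqJ))
    stop("marginal totals differ (", sum(freqI), " vs ", sum(freqJ), ")")
  if (sum(freqI) == 0) stop("empty marginals")
  covmaxFromFreq(freqI, freqJ, levels)
}

#' Pairwise scalability coefficient Hij
#'
#' The observed covariance of two items normalized by its maximum given the
#' marginals; equals 1 exactly when the observed joint distribution is
#' comonotonic, and is negative when the items associate against the scale
#' direction (a monotone-homogeneity violation).
#'
#' @param m a [ResponseMatrix-class].
#' @param i,j item labels or indices.
#' @return scalar Hij (`NA` with a warning if either item has zero variance).
#' @export
computeHPair <- function(m, i, j) {
  i <- resolveItems(m, i); j <- resolveItems(m, j)
  if (length(i) != 1L || length(j) != 1L || i == j)
    stop("need two distinct single items")
  r <- computeHScale(m)
  if (r@undefinedItems[i] || r@undefinedItems[j]) {
    warning("zero-variance item: Hij undefined")
    return(NA_real_)
  }
  r@hPair[i, j]
}

#' Item scalability coefficient Hi
#'
#' Ratio-of-sums convention: `Hi = sum_{j != i} Cov(Xi, Xj) / sum_{j != i}
#' Covmax(Xi, Xj)` — algebraically the normed covariance between the item
#' and its rest score. `Hi > 0.3` is the conventional sufficiency bound.
#'
#' @inheritParams computeHPair
#' @param i item label or index.
#' @return scalar Hi.
#' @export
computeHItem <- function(m, i) {
  i <- resolveItems(m, i)
  if (length(i) != 1L) stop("need a single item")
  computeHScale(m)@hItem[[i]]
}

#' Scalability coefficients of an item set
#'
#' Computes all pairwise Hij, the item Hi and the scale Hs coefficients,
#' together with positivity-test z statistics per pair. Hs is the ratio of
#' the summed observed pairwise covariances to the summed maxima — a weighted
#' mean of the Hi, so `min(Hi) <= Hs <= max(Hi)`. Zero-variance items are
#' flagged as undefined and their pairs excluded from the sums, never
#' silently dropped from the result.
#'
#' @param m a [ResponseMatrix-class].
#' @return a [ScalabilityResult-class] (standard errors unfilled; see
#'   [scalabilitySE()]).
#' @export
computeHScale <- function(m) {
  x <- responseValues(m)
  ps <- pairStatistics(x, m@levelMin, m@levelMax)
  scalabilityFromStats(ps, nrow(x))
}

## Assemble a ScalabilityResult from precomputed pair statistics.
scalabilityFromStats <- function(ps, n) {
  j <- ncol(ps$cov)
  labs <- colnames(ps$cov)
  undef <- ps$var <= 0
  h <- matrix(NA_real_, j, j, dimnames = dimnames(ps$cov))
  ok <- ps$covmax > 0
  h[ok] <- ps$cov[ok] / ps$covmax[ok]
  diag(h) <- NA_real_
  hi <- rep(NA_real_, j); names(hi) <- labs
  for (i in seq_len(j)) {
    den <- sum(ps$covmax[i, -i])
    if (!undef[i] && den > 0) hi[i] <- sum(ps$cov[i, -i][ok[i, -i]]) / den
  }
  upper <- upper.tri(ps$cov)
  denS <- sum(ps$covmax[upper])
  hs <- if (denS > 0) sum(ps$cov[upper & ok]) / denS else NA_real_
  new("ScalabilityResult",
      covPair = ps$cov, covmaxPair = ps$covmax, hPair = h, hItem = hi,
      hScale = hs,
      sePair = matrix(NA_real_, j, j, dimnames = dimnames(ps$cov)),
      seItem = stats::setNames(rep(NA_real_, j), labs), seScale = NA_real_,
      zPair = ps$z, undefinedItems = stats::setNames(undef, labs),
      nPersons = as.integer(n), nBoot = 0L)
}

#' Bootstrap standard errors for scalability coefficients
#'
#' Nonparametric person-resampling bootstrap: persons are resampled with
#' replacement `B` times and the standard deviation of each coefficient over
#' replicates is reported. Seeded and reproducible; the caller's RNG state is
#' left untouched. Coefficients that are undefined on the original data keep
#' an SE of 0 together with their undefined flag.
#'
#' @param m a [ResponseMatrix-class].
#' @param method only `"bootstrap"` is implemented (analytic delta-method
#'   errors are an extension point).
#' @param B number of bootstrap replicates (default 1000, minimum 2).
#' @param seed integer seed.
#' @return a [ScalabilityResult-class] with `sePair`, `seItem`, `seScale`
#'   filled.
#' @export
scalabilitySE <- function(m, method = "bootstrap", B = 1000L, seed = 1L) {
  method <- match.arg(method, "bootstrap")
  B <- as.integer(B)
  if (B < 2L) stop("B must be at least 2")
  base <- computeHScale(m)
  x <- responseValues(m)
  n <- nrow(x); j <- ncol(x)
  hp <- array(NA_real_, c(j, j, B))
  hi <- matrix(NA_real_, j, B)
  hs <- rep(NA_real_, B)
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      ps <- pairStatistics(x[idx, , drop = FALSE], m@levelMin, m@levelMax)
      r <- scalabilityFromStats(ps, n)
      hp[, , b] <- r@hPair
      hi[, b] <- r@hItem
      hs[b] <- r@hScale
    }
  })
  sdNA0 <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) 0 else stats::sd(v)
  }
  sePair <- apply(hp, c(1L, 2L), sdNA0)
  dimnames(sePair) <- dimnames(base@hPair)
  diag(sePair) <- NA_real_
  sePair[is.na(base@hPair) & !upper.tri(base@hPair) & !lower.tri(base@hPair)] <- NA_real_
  seItem <- apply(hi, 1L, sdNA0)
  names(seItem) <- names(base@hItem)
  seItem[base@undefinedItems] <- 0
  base@sePair <- sePair
  base@seItem <- seItem
  base@seScale <- if (is.na(base@hScale)) 0 else sdNA0(hs)
  base@nBoot <- B
  base
}

#' Classify a scale scalability coefficient
#'
#' Conventional rules of thumb: `Hs < 0.3` unscalable, `[0.3, 0.4)` weak,
#' `[0.4, 0.5)` moderate, `>= 0.5` strong (left-closed boundaries).
#'
#' @param hs finite scalar Hs.
#' @return one of `"unscalable"`, `"weak"`, `"moderate"`, `"strong"`.
#' @examples
#' classifyScale(0.559)  # "strong"
#' classifyScale(0.299)  # "unscalable"
#' @export
classifyScale <- function(hs) {
  if (!is.finite(hs)) stop("Hs must be finite")
  if (hs < 0.3) "unscalable"
  else if (hs < 0.4) "weak"
  else if (hs < 0.5) "moderate"
  else "strong"
}

#' Classify an HT item-ordering coefficient
#'
#' `HT < 0.3`: ordering accuracy too low; `[0.3, 0.4)` low; `[0.4, 0.5)`
#' moderate; `>= 0.5` high.
#'
#' @param ht finite scalar HT.
#' @return accuracy label.
#' @export
classifyItemOrdering <- function(ht) {
  if (!is.finite(ht)) stop("HT must be finite")
  if (ht < 0.3) "too low"
  else if (ht < 0.4) "low"
  else if (ht < 0.5) "moderate"
  else "high"
}

#' @rdname hAccessors
#' @export
setMethod("hPair", "ScalabilityResult", function(object) object@hPair)

#' @rdname hAccessors
#' @export
setMethod("hItem", "ScalabilityResult", function(object) object@hItem)

#' @rdname hAccessors
#' @export
setMethod("hScale", "ScalabilityResult", function(object) object@hScale)

#' @rdname hAccessors
#' @export
setMethod("seItem", "ScalabilityResult", function(object) object@seItem)

#' @rdname hAccessors
#' @export
setMethod("seScale", "ScalabilityResult", function(object) object@seScale)

setMethod("show", "ScalabilityResult", function(object) {
  cat(sprintf("ScalabilityResult (N = %d)\n", object@nPersons))
  cat(sprintf("  Hs = %.3f%s  [%s]\n", object@hScale,
              if (is.finite(object@seScale))
                sprintf(" (SE %.3f)", object@seScale) else "",
              tryCatch(classifyScale(object@hScale), error = function(e) "undefined")))
  hi <- sprintf("%.3f", object@hItem)
  hi[object@undefinedItems] <- "undef"
  cat("  Hi:", paste(sprintf("%s=%s", names(object@hItem), hi),
                     collapse = "  "), "\n")
  neg <- which(object@hPair < 0, arr.ind = TRUE)
  neg <- neg[neg[, 1L] < neg[, 2L], , drop = FALSE]
  if (nrow(neg))
    cat("  warning:", nrow(neg),
        "negative Hij pair(s) - monotone homogeneity violation\n")
  if (object@nBoot > 0L)
    cat(sprintf("  bootstrap SEs from %d replicates\n", object@nBoot))
})

#' Long-format scalability table
#'
#' Pair-, item- and scale-level coefficients with standard errors and
#' positivity z statistics as one tidy `data.frame` (the Table 2/3 style
#' report surface).
#'
#' @param object a [ScalabilityResult-class].
#' @return `data.frame` with columns `level`, `itemA`, `itemB`, `estimate`,
#'   `se`, `z`.
#' @export
scalabilityTable <- function(object) {
  labs <- names(object@hItem)
  j <- length(labs)
  rows <- list()
  for (a in seq_len(j - 1L)) for (b in (a + 1L):j)
    rows[[length(rows) + 1L]] <- data.frame(
      level = "pair", itemA = labs[a], itemB = labs[b],
      estimate = object@hPair[a, b], se = object@sePair[a, b],
      z = object@zPair[a, b])
  for (a in seq_len(j))
    rows[[length(rows) + 1L]] <- data.frame(
      level = "item", itemA = labs[a], itemB = NA_character_,
      estimate = object@hItem[a], se = object@seItem[a], z = NA_real_)
  rows[[length(rows) + 1L]] <- data.frame(
    level = "scale", itemA = NA_character_, itemB = NA_character_,
    estimate = object@hScale, se = object@seScale, z = NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
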