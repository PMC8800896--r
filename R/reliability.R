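#' Guttman's lambda-2
#'
#' `lambda2 = (S_T - sum_j s_j^2 + sqrt(J/(J-1) * sum_{i != j} s_ij^2)) /
#' S_T`, with `S_T` the total-score variance, `s_j^2` the item variances and
#' `s_ij` the inter-item covariances. A lower bound to reliability that
#' dominates Cronbach's alpha on every dataset.
#'
#' @param m a [ResponseMatrix-class].
#' @return scalar lambda-2 (unclipped; `NA` when the total-score variance is
#'   zero). Invariant under item relabeling and level shifts.
#' @export
guttmanLambda2 <- function(m) {
  C <- stats::cov(responseValues(m))
  sT <- sum(C)
  if (sT <= 0) {
    warning("zero total-score variance: lambda-2 undefined")
    return(NA_real_)
  }
  j <- ncol(C)
  off <- C; diag(off) <- 0
  (sT - sum(diag(C)) + sqrt(j / (j - 1) * sum(off^2))) / sT
}

#' Cronbach's alpha
#'
#' Internal cross-check companion to [guttmanLambda2()] (Guttman's
#' inequality guarantees `lambda2 >= alpha`).
#'
#' @param m a [ResponseMatrix-class].
#' @return scalar alpha.
#' @export
cronbachAlpha <- function(m) {
  C <- stats::cov(responseValues(m))
  sT <- sum(C)
  if (sT <= 0) return(NA_real_)
  j <- ncol(C)
  j / (j - 1) * (1 - sum(diag(C)) / sT)
}

#' Molenaar-Sijtsma reliability (rho)
#'
#' Total-score reliability for polytomous items in the Mokken tradition. The
#' items are decomposed into cumulative step indicators `Y_ik = (X_i >= k)`;
#' the unobservable within-item parallel joint probabilities
#' `P(Y_ik = 1, Y'_il = 1)` (a hypothetical independent replicate of item i)
#' are approximated from the observed between-item step probability matrix
#' by ordering all steps by their popularity and interpolating linearly in
#' popularity between the nearest steps of *other* items (ratio
#' extrapolation at the ends; estimates are clipped to the Frechet bounds).
#' The estimates are plugged into the standard total-score reliability
#' decomposition `rho = 1 - sum_i (sigma_i^2 - sigma_tilde_ii) / S_T`.
#'
#' @param m a [ResponseMatrix-class] with at least 3 items.
#' @return scalar rho (`NA` with a warning for degenerate inputs).
#' @export
msRho <- function(m) {
  if (nItems(m) < 3L) stop("Molenaar-Sijtsma rho needs at least 3 items")
  x <- responseValues(m)
  n <- nrow(x)
  steps <- list()
  for (i in seq_len(ncol(x)))
    for (k in (m@levelMin + 1L):m@levelMax) {
      pik <- mean(x[, i] >= k)
      if (pik > 0 && pik < 1)  # degenerate steps carry no variance
        steps[[length(steps) + 1L]] <- list(item = i, k = k, pi = pik)
    }
  if (length(steps) < 2L) {
    warning("degenerate step probabilities: rho undefined")
    return(NA_real_)
  }
  nS <- length(steps)
  item <- vapply(steps, `[[`, integer(1L), "item")
  kOf <- vapply(steps, `[[`, integer(1L), "k")
  piS <- vapply(steps, `[[`, numeric(1L), "pi")
  Y <- vapply(seq_len(nS), function(s) as.numeric(x[, item[s]] >= kOf[s]),
              numeric(n))
  P <- crossprod(Y) / n
  if (!all(vapply(seq_len(ncol(x)), function(i)
    any(item != i), logical(1L)))) {
    warning("no between-item information: rho undefined")
    return(NA_real_)
  }
  ## estimate the within-item parallel joint for a (row g, column h) entry
  estimateEntry <- function(g, h) {
    cand <- which(item != item[h] & item != item[g])
    if (!length(cand)) return(NA_real_)
    exact <- cand[abs(piS[cand] - piS[h]) < 1e-12]
    if (length(exact)) return(P[g, exact[1L]])
    lower <- cand[piS[cand] < piS[h]]
    upper <- cand[piS[cand] > piS[h]]
    est <- if (length(lower) && length(upper)) {
      lo <- lower[which.max(piS[lower])]
      hi <- upper[which.min(piS[upper])]
      P[g, lo] + (piS[h] - piS[lo]) / (piS[hi] - piS[lo]) *
        (P[g, hi] - P[g, lo])
    } else if (length(upper)) {
      hi <- upper[which.min(piS[upper])]
      P[g, hi] * piS[h] / piS[hi]
    } else {
      lo <- lower[which.max(piS[lower])]
      P[g, lo] * piS[h] / piS[lo]
    }
    max(max(0, piS[g] + piS[h] - 1), min(est, min(piS[g], piS[h])))
  }
  sigmaObs <- 0; sigmaPar <- 0
  defined <- TRUE
  for (i in unique(item)) {
    si <- which(item == i)
    for (g in si) for (h in si) {
      sigmaObs <- sigmaObs + (piS[if (kOf[g] >= kOf[h]) g else h] -
                              piS[g] * piS[h])
      e1 <- estimateEntry(g, h)
      e2 <- estimateEntry(h, g)
      if (is.na(e1) || is.na(e2)) defined <- FALSE
      sigmaPar <- sigmaPar + (e1 + e2) / 2 - piS[g] * piS[h]
    }
  }
  if (!defined) {
    warning("parallel step probabilities not estimable: rho undefined")
    return(NA_real_)
  }
  sT <- popVar(rowSums(Y))
  if (sT <= 0) {
    warning("zero total-score variance: rho undefined")
    return(NA_real_)
  }
  1 - (sigmaObs - sigmaPar) / sT
}

#' Scale reliability report
#'
#' Computes Guttman's lambda-2, the Molenaar-Sijtsma rho and Cronbach's
#' alpha in one pass. lambda-2 is reported unclipped with a `[0, 1]` clipped
#' companion.
#'
#' @param m a [ResponseMatrix-class].
#' @return a [ReliabilityReport-class].
#' @export
scaleReliability <- function(m) {
  l2 <- suppressWarnings(guttmanLambda2(m))
  rho <- if (nItems(m) >= 3L) suppressWarnings(msRho(m)) else NA_real_
  al <- cronbachAlpha(m)
  new("ReliabilityReport",
      lambda2 = l2,
      lambda2Clipped = if (is.na(l2)) NA_real_ else min(max(l2, 0), 1),
      msRho = rho, alpha = if (is.null(al)) NA_real_ else al,
      nPersons = nPersons(m), defined = !is.na(l2))
}

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("Reliability (N = %d): rho = %.3f, lambda-2 = %.3f (alpha = %.3f)\n",
              object@nPersons, object@msRho, object@lambda2, object@alpha))
  if (!object@defined) cat("  undefined: zero total-score variance\n")
})
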