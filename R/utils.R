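## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's .Random.seed is restored afterwards so analysis steps that seed
## internally never perturb an enclosing simulation.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Population (1/N) covariance and variance. All scalability coefficients are
## ratios of covariances, so the denominator convention cancels; the
## population form is used consistently in numerator and normalizer.
popCov <- function(x, y) mean(x * y) - mean(x) * mean(y)
popVar <- function(x) popCov(x, x)

## Maximum covariance attainable between two ordinal marginals with equal
## totals: the comonotonic (Frechet upper bound) coupling, built by the
## northwest-corner walk over the two cumulative frequency vectors.
## `freqI`, `freqJ`: counts per level; `levels`: the common level values.
covmaxFromFreq <- function(freqI, freqJ, levels) {
  n <- sum(freqI)
  if (sum(freqJ) != n) stop("marginal totals differ: ", n, " vs ", sum(freqJ))
  if (n < 1L) stop("empty marginals")
  i <- 1L; j <- 1L
  ri <- freqI[1L]; rj <- freqJ[1L]
  s <- 0
  repeat {
    if (ri == 0) { i <- i + 1L; if (i > length(freqI)) break; ri <- freqI[i]; next }
    if (rj == 0) { j <- j + 1L; if (j > length(freqJ)) break; rj <- freqJ[j]; next }
    t <- min(ri, rj)
    s <- s + t * levels[i] * levels[j]
    ri <- ri - t; rj <- rj - t
  }
  mi <- sum(freqI * levels) / n
  mj <- sum(freqJ * levels) / n
  s / n - mi * mj
}

## One-sided positivity test for an inter-item association: Fisher
## z-transform of the Pearson correlation, N(0,1) under independence.
positivityZ <- function(r, n) {
  if (!is.finite(r) || n < 4L) return(NA_real_)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  atanh(r) * sqrt(n - 3)
}

## Pairwise covariance / max-covariance / positivity-z matrices for a
## response matrix; computed once and reused by the scalability, AISP and
## report code paths.
pairStatistics <- function(x, levelMin, levelMax) {
  n <- nrow(x); j <- ncol(x)
  levels <- levelMin:levelMax
  freq <- vapply(seq_len(j), function(i) tabulate(x[, i] - levelMin + 1L,
                                                  nbins = length(levels)),
                 integer(length(levels)))
  covP <- stats::cov(x) * (n - 1) / n
  cmax <- matrix(0, j, j, dimnames = dimnames(covP))
  zP <- matrix(NA_real_, j, j, dimnames = dimnames(covP))
  v <- diag(covP)
  for (a in seq_len(j - 1L)) for (b in (a + 1L):j) {
    cmax[a, b] <- cmax[b, a] <- covmaxFromFreq(freq[, a], freq[, b], levels)
    if (v[a] > 0 && v[b] > 0) {
      r <- covP[a, b] / sqrt(v[a] * v[b])
      zP[a, b] <- zP[b, a] <- positivityZ(r, n)
    }
  }
  list(cov = covP, covmax = cmax, z = zP, var = v, freq = freq)
}

## Deterministic integer sub-seed derivation (keeps values < 2^31).
deriveSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + as.integer(k) * 1013) %% 2147480951L
}

roundHalfUp <- function(x) floor(x + 0.5)
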