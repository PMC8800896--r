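#' Construct a graded response model specification
#'
#' @param a positive per-item discriminations.
#' @param b matrix of strictly increasing step locations, one row per item
#'   and `levelMax - levelMin` columns.
#' @param traitLoading per-item loading on the dominant latent factor in
#'   `[0, 1]` (default 1: unidimensional).
#' @param itemLabels item names (default `item1..itemJ`).
#' @param levelMin,levelMax response level bounds.
#' @return a [GrmSpec-class].
#' @export
grmSpec <- function(a, b, traitLoading = rep(1, length(a)),
                    itemLabels = paste0("item", seq_along(a)),
                    levelMin = 1L, levelMax = NULL) {
  b <- as.matrix(b)
  if (is.null(levelMax)) levelMax <- levelMin + ncol(b)
  new("GrmSpec", a = as.numeric(a), b = b,
      traitLoading = as.numeric(traitLoading),
      itemLabels = as.character(itemLabels),
      levelMin = as.integer(levelMin), levelMax = as.integer(levelMax),
      violations = list())
}

#' Evenly spaced step locations
#'
#' Convenience builder: item step locations equally spaced within
#' `[lo, hi]`, identical across items unless per-item centers are given.
#'
#' @param j number of items.
#' @param nSteps steps per item (levels - 1).
#' @param lo,hi range of the step locations.
#' @param centers optional per-item location shifts.
#' @return a J x nSteps matrix.
#' @export
equallySpacedThresholds <- function(j, nSteps = 4L, lo = -1.5, hi = 1.5,
                                    centers = rep(0, j)) {
  base <- seq(lo, hi, length.out = nSteps)
  t(vapply(seq_len(j), function(i) base + centers[i], numeric(nSteps)))
}

#' Simulate responses from a graded response model
#'
#' Step k of item i is endorsed with probability
#' `plogis(a_i * (t_i - b_ik))` where the item trait mixes the dominant
#' standard-normal factor theta with item-specific noise according to
#' `traitLoading`. By construction the data satisfy unidimensionality (at
#' loading 1), local independence and latent monotonicity — the monotone
#' homogeneity model. Attached violation descriptors (see
#' [injectViolation()]) deform the response process as documented there.
#' Fully reproducible from `(spec, N, seed)`.
#'
#' @param spec a [GrmSpec-class].
#' @param n number of persons.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param theta optional fixed latent trait vector (overrides the N(0,1)
#'   draw; useful with per-group shifts).
#' @param groupInfo optional `data.frame` attached to the result.
#' @return a [ResponseMatrix-class].
#' @export
simulateGrm <- function(spec, n, seed = NULL, theta = NULL,
                        groupInfo = NULL) {
  stopifnot(is(spec, "GrmSpec"))
  validObject(spec)
  j <- length(spec@a)
  nSteps <- ncol(spec@b)
  withSeed(seed, {
    th <- if (is.null(theta)) stats::rnorm(n) else rep_len(theta, n)
    x <- matrix(spec@levelMin, n, j)
    for (i in seq_len(j)) {
      lam <- spec@traitLoading[i]
      ti <- lam * th + sqrt(1 - lam^2) * stats::rnorm(n)
      u <- stats::runif(n)
      pPrev <- rep(1, n)
      for (k in seq_len(nSteps)) {
        p <- stats::plogis(spec@a[i] * (ti - spec@b[i, k]))
        p <- applyStepViolations(p, spec@violations, i, k, ti)
        p <- pmin(p, pPrev)  # cumulative coherence across steps
        x[, i] <- x[, i] + (u < p)
        pPrev <- p
      }
    }
    colnames(x) <- spec@itemLabels
    ResponseMatrix(x, levelMin = spec@levelMin, levelMax = spec@levelMax,
                   groupInfo = groupInfo)
  })
}

applyStepViolations <- function(p, violations, item, k, trait) {
  for (v in violations) {
    if (v$kind == "nonmonotone_step" && v$item == item && v$step == k) {
      inWin <- trait > v$window[1L] & trait < v$window[2L]
      p[inWin] <- pmin(p[inWin], v$floor)
    }
  }
  p
}

#' Closed-form marginal step endorsement probability
#'
#' `P(X_i >= k) = integral plogis(a (t - b)) dPhi(t)` by adaptive
#' quadrature; the oracle against which simulated marginals are checked, and
#' the engine of [calibrateGrmThresholds()].
#'
#' @param a discrimination. @param b step location.
#' @return scalar probability.
#' @export
grmMarginalStep <- function(a, b) {
  stats::integrate(function(t) stats::plogis(a * (t - b)) * stats::dnorm(t),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

#' Solve step locations for target marginal endorsement rates
#'
#' Deterministic quadrature plus root-finding: for each target cumulative
#' rate `P(X >= k)` the step location `b` solving
#' [grmMarginalStep()]`(a, b) = p` is found by bisection.
#'
#' @param targets numeric vector (or list of vectors, one per item) of
#'   strictly decreasing cumulative endorsement probabilities in (0, 1).
#' @param a discrimination(s).
#' @return matrix of step locations, one row per item.
#' @export
calibrateGrmThresholds <- function(targets, a) {
  if (!is.list(targets)) targets <- list(targets)
  a <- rep_len(a, length(targets))
  out <- t(mapply(function(tg, ai) {
    vapply(tg, function(p) {
      if (p <= 0 || p >= 1) stop("targets must lie strictly in (0, 1)")
      stats::uniroot(function(b) grmMarginalStep(ai, b) - p,
                     c(-20, 20), tol = 1e-10)$root
    }, numeric(1L))
  }, targets, a))
  rownames(out) <- names(targets)
  out
}

## EQ-5D-5L preset constants. Cumulative endorsement targets P(X >= k) are
## the published MIC sample shares (mobility and usual activities share one
## row as printed there; see the vignette for the caveat). The step
## locations below solve grmMarginalStep(3.5, b) = target; the committed
## values are verified against calibrateGrmThresholds() in the test suite.
.eq5dTargets <- list(
  MO = c(0.3492, 0.1341, 0.0369, 0.0061),
  SC = c(0.1196, 0.0409, 0.0084, 0.0010),
  UA = c(0.3492, 0.1341, 0.0369, 0.0061),
  PD = c(0.7062, 0.3011, 0.1000, 0.0139),
  AD = c(0.4980, 0.2057, 0.0686, 0.0203))

.eq5dPreset <- list(
  a = c(MO = 3.5, SC = 3.5, UA = 3.5, PD = 3.5, AD = 3.5),
  loading = c(MO = 1, SC = 1, UA = 1, PD = 1, AD = 0.53),
  b = matrix(c(0.433999, 1.242503, 2.013806, 2.841655,
               1.321182, 1.959637, 2.707538, 3.532054,
               0.433999, 1.242503, 2.013806, 2.841655,
               -0.607574, 0.583938, 1.439234, 2.486548,
               0.005614, 0.920890, 1.670944, 2.311034),
             nrow = 5, byrow = TRUE,
             dimnames = list(c("MO", "SC", "UA", "PD", "AD"), NULL)))

#' EQ-5D-5L preset specification
#'
#' The committed generator parameters behind [eq5d5lPreset()]: five items
#' (MO, SC, UA, PD, AD) with five levels, common discrimination 3.5, step
#' locations calibrated by quadrature so the marginal severity shares match
#' the published MIC sample table, and the anxiety/depression item loading
#' 0.53 on the dominant health factor (the rest of its variance comes from a
#' second, mental-health factor), which depresses its pairwise scalability
#' with the four physical items.
#'
#' @return a [GrmSpec-class].
#' @export
eq5d5lSpec <- function() {
  grmSpec(a = .eq5dPreset$a, b = .eq5dPreset$b,
          traitLoading = .eq5dPreset$loading,
          itemLabels = rownames(.eq5dPreset$b),
          levelMin = 1L, levelMax = 5L)
}

#' Marginal targets of the EQ-5D-5L preset
#'
#' Cumulative endorsement targets `P(X >= k)`, k = 2..5, per item.
#' @return named list of numeric vectors.
#' @export
eq5d5lTargets <- function() .eq5dTargets

#' Simulate an EQ-5D-5L style sample
#'
#' Draws `n` persons from the calibrated preset ([eq5d5lSpec()]). Optional
#' subgroups introduce real heterogeneity for stratified runs: each group is
#' given a share of the sample, a shift of the dominant health factor
#' (negative = healthier) and a shift of the anxiety/depression trait
#' (positive = AD easier to endorse, as in a depression-like subgroup).
#'
#' @param n sample size (>= 100).
#' @param seed integer seed.
#' @param groups optional named list; each element is
#'   `list(prop =, thetaShift = 0, adShift = 0)`. Proportions must sum to 1.
#' @return a [ResponseMatrix-class]; with `groups`, `groupInfo` holds a
#'   `group` column.
#' @examples
#' m <- eq5d5lPreset(2000, seed = 1)
#' colMeans(responseValues(m) == 1)  # "no problems" shares
#' @export
eq5d5lPreset <- function(n, seed = 1L, groups = NULL) {
  if (n < 100L) stop("preset samples need n >= 100")
  spec <- eq5d5lSpec()
  if (is.null(groups)) return(simulateGrm(spec, n, seed = seed))
  props <- vapply(groups, function(g) g$prop, numeric(1L))
  if (abs(sum(props) - 1) > 1e-8) stop("group proportions must sum to 1")
  withSeed(seed, {
    gid <- sample(rep(seq_along(groups),
                      times = diff(c(0, round(cumsum(props) * n)))))
    th <- stats::rnorm(n)
    adNoise <- stats::rnorm(n)
    for (g in seq_along(groups)) {
      sel <- gid == g
      th[sel] <- th[sel] + (groups[[g]]$thetaShift %||% 0)
    }
    lam <- spec@traitLoading
    x <- matrix(1L, n, 5L)
    for (i in 1:5) {
      ti <- lam[i] * th + sqrt(1 - lam[i]^2) *
        (if (i == 5L) adNoise else stats::rnorm(n))
      if (i == 5L) for (g in seq_along(groups))
        ti[gid == g] <- ti[gid == g] + (groups[[g]]$adShift %||% 0)
      u <- stats::runif(n)
      pPrev <- rep(1, n)
      for (k in 1:4) {
        p <- pmin(stats::plogis(spec@a[i] * (ti - spec@b[i, k])), pPrev)
        x[, i] <- x[, i] + (u < p)
        pPrev <- p
      }
    }
    colnames(x) <- spec@itemLabels
    ResponseMatrix(x, levelMin = 1L, levelMax = 5L,
                   groupInfo = data.frame(group = names(groups)[gid]))
  })
}

#' Attach a model violation to a generator specification
#'
#' Three controlled departures from the monotone homogeneity / double
#' monotonicity structure:
#' \describe{
#'   \item{`nonmonotone_step`}{over a latent window (default
#'     `b_k + c(-0.5, 2.5)`) the middle step's response function of the
#'     target item is held down to its value at the window entry minus
#'     `magnitude` (a probability in `[0, 1)`, floored at 0) — a flat dip of
#'     depth `magnitude` relative to the entry point; steps above are
#'     clipped to keep cumulative coherence.}
#'   \item{`crossing_irf`}{the target item's discrimination is multiplied by
#'     `magnitude` (>= 1; 1 = no change) and its step locations are
#'     recentred to the mid-range of the other items, so its item response
#'     function crosses theirs.}
#'   \item{`second_dimension`}{the target item's responses are driven by a
#'     second factor with loading `magnitude` in `[0, 1]` (its loading on
#'     the dominant factor becomes `sqrt(1 - magnitude^2)`).}
#' }
#' A magnitude of 0 (1 for `crossing_irf`) leaves the generator
#' distributionally identical.
#'
#' @param spec a [GrmSpec-class].
#' @param kind violation kind (above).
#' @param item target item label or index.
#' @param magnitude violation size, bounds per kind.
#' @param window latent window for `nonmonotone_step` (`NULL` for the
#'   default).
#' @return the modified [GrmSpec-class].
#' @export
injectViolation <- function(spec, kind = c("nonmonotone_step", "crossing_irf",
                                           "second_dimension"),
                            item, magnitude, window = NULL) {
  kind <- match.arg(kind)
  stopifnot(is(spec, "GrmSpec"))
  idx <- if (is.character(item)) match(item, spec@itemLabels) else
    as.integer(item)
  if (is.na(idx) || idx < 1L || idx > length(spec@a))
    stop("unknown target item")
  if (kind == "nonmonotone_step") {
    if (magnitude < 0 || magnitude >= 1)
      stop("nonmonotone_step magnitude must lie in [0, 1)")
    step <- ceiling(ncol(spec@b) / 2)
    if (is.null(window)) window <- spec@b[idx, step] + c(-0.5, 2.5)
    if (magnitude > 0) {
      floorVal <- max(0, stats::plogis(
        spec@a[idx] * (window[1L] - spec@b[idx, step])) - magnitude)
      spec@violations <- c(spec@violations,
                           list(list(kind = kind, item = idx, step = step,
                                     magnitude = magnitude, window = window,
                                     floor = floorVal)))
    }
  } else if (kind == "crossing_irf") {
    if (magnitude < 1) stop("crossing_irf magnitude is a multiplier >= 1")
    if (magnitude > 1) {
      spec@a[idx] <- spec@a[idx] * magnitude
      others <- setdiff(seq_along(spec@a), idx)
      spec@b[idx, ] <- spec@b[idx, ] - mean(spec@b[idx, ]) +
        mean(spec@b[others, ])
    }
  } else {
    if (magnitude < 0 || magnitude > 1)
      stop("second_dimension magnitude (loading) must lie in [0, 1]")
    if (magnitude > 0)
      spec@traitLoading[idx] <- sqrt(1 - magnitude^2)
  }
  spec
}

setMethod("show", "GrmSpec", function(object) {
  cat(sprintf("GrmSpec: %d items, levels %d-%d\n", length(object@a),
              object@levelMin, object@levelMax))
  cat("  a:", paste(sprintf("%s=%.2f", object@itemLabels, object@a),
                    collapse = "  "), "\n")
  if (any(object@traitLoading < 1))
    cat("  loadings < 1:",
        paste(sprintf("%s=%.2f",
                      object@itemLabels[object@traitLoading < 1],
                      object@traitLoading[object@traitLoading < 1]),
              collapse = "  "), "\n")
  if (length(object@violations))
    cat("  violations:", length(object@violations), "attached\n")
})
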