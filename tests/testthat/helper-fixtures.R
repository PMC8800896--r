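## Fixtures built in code at test time.

## Perfect Guttman data: all items are identical copies of one ordinal
## column, so every pair is comonotonic (H = 1 everywhere).
guttmanFixture <- function(n = 200L, j = 5L, seed = 11L) {
  base <- withr::with_seed(seed, sample(1:5, n, replace = TRUE))
  ResponseMatrix(matrix(base, n, j), itemLabels = paste0("it", 1:j))
}

## Independent uniform items.
independentFixture <- function(n, j = 5L, seed = 12L) {
  vals <- withr::with_seed(seed,
    matrix(sample(1:5, n * j, replace = TRUE), n, j))
  ResponseMatrix(vals, itemLabels = paste0("it", 1:j))
}

## Unidimensional 5-item graded response spec (a = 2, equal spacing).
uniSpec <- function(j = 5L, a = 2) {
  grmSpec(a = rep(a, j),
          b = equallySpacedThresholds(j, centers = seq(-0.6, 0.6,
                                                       length.out = j)),
          itemLabels = paste0("it", 1:j))
}

## Two independent 3-item blocks: simulated separately and bound together.
twoBlockFixture <- function(n, seed) {
  sA <- grmSpec(a = rep(2, 3), b = equallySpacedThresholds(3),
                itemLabels = paste0("A", 1:3))
  sB <- grmSpec(a = rep(2, 3), b = equallySpacedThresholds(3),
                itemLabels = paste0("B", 1:3))
  mA <- simulateGrm(sA, n, seed = seed)
  mB <- simulateGrm(sB, n, seed = seed + 7919L)
  ResponseMatrix(cbind(responseValues(mA), responseValues(mB)))
}

## Equal-discrimination, well-separated item locations: invariant item
## ordering holds by construction (nonintersecting response functions).
iioTrueSpec <- function(j = 5L) {
  grmSpec(a = rep(2, j),
          b = equallySpacedThresholds(j, lo = -1, hi = 1,
                                      centers = seq(-1.2, 1.2,
                                                    length.out = j)),
          itemLabels = paste0("it", 1:j))
}
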