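# npirt — nonparametric IRT scaling for ordinal questionnaires

`npirt` implements polytomous Mokken scale analysis for ordinal
questionnaire data, built around the use case of the EQ-5D-5L health
profile: five items (mobility MO, self-care SC, usual activities UA,
pain/discomfort PD, anxiety/depression AD), each answered on five ordered
severity levels. When preference-based utility weights are unavailable or
unsuitable, the natural summary is the **level sum score (LSS)** — the plain
sum of the five levels, ranging 5 (`11111`, no problems) to 25 (`55555`,
extreme problems everywhere). Whether that score may be used to *order
persons* (and whether the items keep one fixed ordering along the score) is
exactly what the nonparametric IRT models of Mokken scaling test.

## What it computes

For an N×J matrix of integer responses the package provides:

- **Scalability coefficients** `H_ij`, `H_i`, `H_s` — observed covariances
  normalized by their maximum given the item marginals (the comonotonic /
  Fréchet-upper-bound coupling), with seeded person-bootstrap standard
  errors and positivity tests. Rules of thumb: `H_s < 0.3` unscalable,
  0.3–0.4 weak, 0.4–0.5 moderate, ≥ 0.5 strong.
- **Automated item selection (AISP)** — hierarchical partitioning of items
  into Mokken scales at a lower bound `c` on `H_i`, plus a two-stage sweep
  (`sweepLbound()`, `refineExclusionThreshold()`) that pinpoints, to 0.001,
  the bound at which each item leaves the scale.
- **Manifest monotonicity** — item step response functions
  `P(X_i ≥ k | rest-score group)` with violation counts against `minvi`
  (0.03), z tests and a composite `crit` severity index.
- **Manifest invariant item ordering (MIIO)** — pairwise conditional-mean
  checks over joint rest-score groups (threshold `0.03 × #steps = 0.12` for
  five levels), backward item removal, and the ordering-accuracy
  coefficient `H^T` (scale scalability of the transposed matrix, computed
  by a closed form linear in N).
- **Reliability** — Guttman's λ₂ and the Molenaar–Sijtsma ρ.
- **Synthetic data** — a graded-response-model generator
  (`simulateGrm()`) satisfying the monotone homogeneity model by
  construction, an EQ-5D-5L preset calibrated by quadrature to published
  MIC-sample severity shares (`eq5d5lPreset()`), and controllable
  violations (`injectViolation()`): non-monotone steps, crossing response
  functions, a second latent dimension.
- **Pipeline** — `runFullAnalysis()` executes the whole battery for the
  pooled sample and every stratum of the grouping columns, with generic
  item-exclusion comparison and TSV/JSON report writers.

## Worked example

```r
library(npirt)

m  <- eq5d5lPreset(20000, seed = 7)   # synthetic EQ-5D-5L style sample
sc <- computeHScale(m)
round(hItem(sc), 3)
#>    MO    SC    UA    PD    AD
#> 0.628 0.630 0.623 0.657 0.378
round(hScale(sc), 3)
#> [1] 0.576                          # a strong scale, but AD is weak

checkMiio(m)@pairTable[c(5, 6), c("itemA", "itemB", "vi")]
#>   itemA itemB vi
#> 5    AD    MO  1
#> 6    AD    UA  1                   # AD's IRF crosses MO and UA

m4 <- dropItems(m, "AD")
round(c(Hs = hScale(computeHScale(m4)), HT = coefficientHt(m4)), 3)
#>    Hs    HT
#> 0.745 0.753                        # without AD both orderings strengthen
```

The anxiety/depression item is flagged exactly as in real EQ-5D-5L data:
its `H_i` sits near the 0.3 acceptability bound, it is the first item
excluded as the AISP lower bound rises (`refineExclusionThreshold(m, "AD")`
→ ≈ 0.38), and the MIIO check pins its ordering violations against MO and
UA. The four physical items alone form a very strong, accurately ordered
scale.

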