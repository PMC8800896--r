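---
title: "Mokken scaling for ordinal health questionnaires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mokken scaling for ordinal health questionnaires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npirt)
```

## The measurement problem

A short ordinal questionnaire such as the EQ-5D-5L asks respondents to
grade themselves on a handful of items (mobility, self-care, usual
activities, pain/discomfort, anxiety/depression), each on the same ordered
levels (1 = no problems … 5 = extreme problems). The *level sum score*
(LSS) adds the five levels into a single number between 5 and 25, higher
meaning worse health. Using that sum as a measure of an underlying health
variable $\theta$ is only justified if the data fit a model under which the
total score stochastically orders persons along $\theta$.

Mokken scaling tests two nested nonparametric IRT models:

* the **monotone homogeneity model (MHM)** — unidimensionality, local
  independence, and monotone item step response functions
  $P(X_i \ge k \mid \theta)$. Under the MHM the total score orders persons.
* the **double monotonicity model (DMM)** — MHM plus nonintersecting
  response functions, which adds an *invariant item ordering*: the items
  keep one difficulty order everywhere along $\theta$, giving the score
  range an interpretation in terms of which problems appear first.

Nothing parametric is estimated; all checks are manifest (observable)
statistics.

## Scalability coefficients

For items $i,j$ the pairwise coefficient is
$H_{ij} = \mathrm{Cov}(X_i, X_j) / \mathrm{Cov}^{\max}(X_i, X_j)$, where
the normalizer is the covariance of the *comonotonic coupling* of the two
marginal level distributions — the Fréchet upper bound, computed by the
northwest-corner walk over the cumulative marginal frequencies
(`maxCovariance()`). $H_{ij} = 1$ exactly for comonotonic data; negative
values flag an association against the scale direction and hence an MHM
violation. Item and scale coefficients are ratios of sums,
$H_i = \sum_{j \ne i} \mathrm{Cov}_{ij} / \sum_{j \ne i}
\mathrm{Cov}^{\max}_{ij}$ and $H_s$ analogously over all pairs, which makes
$H_s$ a weighted mean of the $H_i$ (so $\min H_i \le H_s \le \max H_i$).

Two numerical conventions are fixed package-wide and matter only for
internal consistency, never for the coefficients themselves:

* covariances use the population ($1/N$) denominator in numerator and
  normalizer alike — the ratio is invariant to this choice, and the
  population form is what a direct enumeration of couplings yields;
* zero-variance items get flagged `NA` coefficients rather than being
  dropped, and their pairs are excluded from the ratio sums.

Standard errors come from a seeded nonparametric person bootstrap
(`scalabilitySE()`, default $B = 1000$). A delta-method alternative would
have identical asymptotics; the bootstrap was chosen because it is simple
to verify and applies unchanged to every coefficient. Positivity of a pair
($H_{ij} > 0$) is tested with a one-sided Fisher-$z$ statistic
$\operatorname{atanh}(r)\sqrt{N-3}$.

## Automated item selection

`runAisp()` implements the hierarchical bottom-up procedure: seed with the
largest significantly positive $H_{ij} \ge c$, then repeatedly add the
candidate item that maximizes the scale's $H$ among those with
$H_i(\text{candidate; selection}) \ge c$ and significantly positive
associations with every selected item; start further scales on the
leftovers. Choices the procedure's description leaves open are fixed as:

* significance: Fisher-$z$ positivity tests at $\alpha = 0.05$ with a
  Bonferroni correction over the item pairs active at seeding;
* ties on any $H$ comparison break to the lowest item index, making runs
  bit-for-bit reproducible.

The two-stage threshold search mirrors practice: `sweepLbound()` re-runs
the selection on a coarse grid (default $0, 0.05, \dots, 0.55$ — twelve
values; the endpoints are configurable because "up to 0.5" and "twelve
runs" disagree by one grid point), then `refineExclusionThreshold()` walks
down from the coarsest bound at which an item is unscalable in steps of
0.001 and reports the smallest bound at which it stays excluded. Since an
item is retained while $c \le H_i$, the threshold lands one resolution step
above the item's $H_i$ — on EQ-5D-5L style data the anxiety/depression item
leaves the scale just above its $H_i \approx 0.38$ while the physical items
survive past 0.6.

## Manifest monotonicity

For each item, persons are grouped by the item's rest score (LSS minus the
item). Groups are built deterministically: adjacent rest-score values merge
left to right until each group reaches `minsize`, and an undersized last
group merges backwards. The default `minsize` is $\lfloor N/10 \rfloor$ for
$N \ge 500$, otherwise $\lfloor N/5 \rfloor$ with a floor of 50 — a
documented rule pinned by tests, since automatic group sizing has no single
canonical definition.

Within each group the step response functions $\hat P(X_i \ge k \mid g)$
are estimated; a comparison of groups $g < g'$ at step $k$ is a violation
when $\hat P_g - \hat P_{g'} > \texttt{minvi}$ (default 0.03), and each
flagged comparison gets a one-sided two-proportion $z$ test. The summary
per item reports active comparisons, violations, `maxvi`, `zmax` and a
composite severity index

`crit = round(50·max(0, 0.3 − H_i) + √vi + 100·vi/ac + 100·maxvi + 10·√zmax)`,

zero exactly when nothing was flagged. The weights follow the MSP-manual
tradition but are a convention, exposed as an argument of
`critComposite()`; no acceptance check depends on their exact values.

## Invariant item ordering

`checkMiio()` orders items by their overall means. The package's easiness
convention — stated explicitly because both exist in the literature — is
*higher mean = easier to endorse*, i.e. problems reported more readily;
reports list the easiest item first (for the EQ-5D-5L typically PD first,
SC last). Every ordered pair is checked over the rest score of the other
$J-2$ items: a group where the harder item's conditional mean exceeds the
easier item's by more than `minvi` (default $0.03 \times$ number of steps
$= 0.12$ for five levels) is a violation, tested with a one-sided paired
$t$ test (uncorrected by default; a Bonferroni variant is a flag). Tied
item means make invariant ordering ill-defined; ties are broken by item
index and reported.

`backwardSelection()` removes the item with the most *significant*
reversals (ties: larger `crit`, then lower index), recomputes, and stops at
zero violations or at three items (below which the pair rest score would
not exist). The surviving set re-checks clean by construction, which the
tests assert as a fixed point.

The ordering-accuracy coefficient $H^T$ is the scale scalability of the
*transposed* matrix — persons as items. Persons with constant response
patterns carry no ordering information and are removed (with a reported
count). Because all "marginals" in the transposed problem share the same
$J$ observations, the comonotonic normalizer reduces to sorting each
person's responses, and both numerator and denominator collapse to
closed-form column sums; `coefficientHt()` is therefore linear in $N$ and
exactly equal to `hScale(computeHScale(transposeResponses(m)))`, which the
tests verify. Accuracy labels: $<0.3$ too low, 0.3–0.4 low, 0.4–0.5
moderate, $>0.5$ high.

## Reliability

Guttman's $\lambda_2$ uses its closed form; Cronbach's $\alpha$ is
computed as an internal cross-check, and $\lambda_2 \ge \alpha$ holds on
every dataset by the Cauchy–Schwarz step of Guttman's argument (this is a
standing property test). The Molenaar–Sijtsma statistic $\rho$ decomposes
the items into cumulative step indicators $Y_{ik} = (X_i \ge k)$; the
unobservable *parallel* within-item joint probabilities (what a
hypothetical independent replicate of the same item would give) are
approximated from the between-item step probability matrix: all steps are
ordered by popularity and the missing entry is interpolated linearly in
popularity between the nearest steps of other items, with ratio
extrapolation at the extremes and clipping to the Fréchet bounds. This
interpolation variant (1988-style construction) is the documented choice;
duplicated items recover $\rho = 1$ exactly because the twin provides the
parallel joint, and independent items give $\rho \approx 0$. Steps with
popularity 0 or 1 carry no variance and are dropped before interpolation.
$\lambda_2$ is reported unclipped alongside a $[0,1]$-clipped companion.

## The synthetic-data generator

The test bed is the logistic graded response model:
$P(X_i \ge k \mid \theta) = \operatorname{logistic}(a_i(\theta - b_{ik}))$
with $\theta \sim N(0,1)$ and, optionally, an item trait that mixes
$\theta$ with item-specific noise through a loading
($t_i = \lambda_i\theta + \sqrt{1-\lambda_i^2}\,\varepsilon_i$). Logistic
step functions are monotone, so the generator satisfies the MHM by
construction; equal discriminations with separated locations additionally
give nonintersecting response functions (an ordering-true fixture). One
uniform draw per person–item converts the cumulative step probabilities
into a level, so a simulated dataset is byte-reproducible from
`(spec, n, seed)`, and the simulation restores the caller's RNG state.

**EQ-5D-5L preset.** `eq5d5lPreset()` emulates the response structure of a
large multi-country general/chronic-condition sample (the MIC study — the
original data are permission-gated, so the preset stands in for them and is
synthetic by design):

* step locations were calibrated offline by quadrature root-finding
  (`calibrateGrmThresholds()`, committed to six decimals and re-verified in
  the tests) so the marginal severity shares match the published MIC
  distributions — e.g. 65.1 % "no problems" on mobility, 88.0 % on
  self-care, 29.4 % on pain/discomfort. The published table prints
  identical frequency rows for mobility and usual activities (5163 / 1707 /
  771 / 244 / 48), very likely a typesetting duplication; the preset uses
  the values as printed, so those two items share thresholds.
* a common discrimination of 3.5 reproduces the strong scalability of the
  four physical items ($H_i \approx 0.6$–0.66, $H_s \approx 0.57$);
* the anxiety/depression item loads 0.53 on the dominant health factor,
  the remainder of its variance coming from a second (mental-health)
  factor. This single number was calibrated so that AD's $H_i$ sits near
  0.38 — just above the 0.3 acceptability bound — which reproduces the
  qualitative signature of real EQ-5D-5L data: AD is the weakest item,
  the first excluded in lower-bound sweeps, the source of the ordering
  violations against MO and UA, and its removal lifts both $H_s$
  (≈ 0.57 → 0.74) and $H^T$ (≈ 0.46 → 0.74).

What the preset does *not* emulate: the joint dependence structure beyond
one-and-a-half factors, the observed profile counts of any real sample,
country-level covariance differences, or response styles. A passing test
battery on the preset therefore shows that the *methods* behave correctly
under a realistic marginal/loading structure, not that any particular real
dataset fits the MHM. Subgroup heterogeneity for stratified runs is
injected through per-group shifts of the health factor and of the AD trait
(a "depression-like" group with a positive AD shift endorses AD more
readily than mobility at every rest score, reversing the pooled ordering —
real heterogeneity, not relabeled copies).

**Violation injectors.** `injectViolation()` produces data that *should*
fail each check:

* `nonmonotone_step` — within a latent window (default
  $b_k + [-0.5, 2.5]$) the middle step's response function is capped at
  its window-entry value minus the magnitude (floored at 0): a flat dip.
  The flat shape is deliberate: rest-score groups mix a range of $\theta$,
  and a narrow subtractive dip of 0.2 averages out to manifest differences
  below `minvi`. Even with the flat dip, a latent magnitude of 0.2
  manifests as rest-score-group differences of only ≈ 0.05 — the
  pre-window step probability bounds the observable contrast — so the
  detection contract is on *flagging* (violations found in ≥ 95 % of
  replications at $N = 5000$, which holds with margin), not on the
  manifest `maxvi` reaching the latent magnitude.
* `crossing_irf` — multiplies the target discrimination (neutral value 1)
  and recenters its steps to the other items' mid-range, making its IRF
  cross theirs; detected by the pairwise ordering check. Power fixtures
  use shallow base items ($a = 1$) so the conditional-mean reversals
  comfortably exceed the 0.12 threshold.
* `second_dimension` — re-drives the item from a second factor with the
  stated loading; depresses the item's $H_i$ without breaking latent
  monotonicity.

Magnitude 0 (multiplier 1) leaves the generator byte-identical under the
same seed.

## Missing data

`readResponses()` deletes persons with missing item responses listwise
(with a warning carrying the count) or fails fast, by policy. Pairwise
deletion was considered and rejected: with per-pair sample sizes the
ratio-of-sums identities behind $H_i$ and $H_s$ (and the guarantee
$\mathrm{Cov} \le \mathrm{Cov}^{\max}$ within one coupling) no longer refer
to a single population, so the coefficients would lose their weighted-mean
interpretation.

## Problem sizes and determinism

The test suite simulates its own data throughout: structure-recovery runs
use 100 replications at $N = 5000$, violation-power runs 200 replications
at $N = 5000$, limit cases up to $N = 20{,}000$, and the preset battery
$N = 50{,}000$ — sizes at which the checked properties are stable while the
whole suite stays quick. Every stochastic step takes an explicit seed, and
the pipeline logs it; identical configuration and seed reproduce every
report file byte for byte.

## Known limitations

* Analytic (delta-method) standard errors are an extension point; only the
  bootstrap is implemented.
* The `crit` composite's weights are a convention; compare `crit` values
  only within one convention.
* Rest-score group boundaries depend on the `minsize` rule; statistics can
  shift slightly at group-boundary ties compared to other implementations
  with different automatic grouping.
* The genetic-algorithm variant of item selection is out of scope; only
  the hierarchical procedure is provided.
* No kernel-smoothed response functions — grouped empirical estimates only.
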