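---
title: "Species versus functional-trait stability: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species versus functional-trait stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Repeatedly surveyed communities can be described two ways: by *which
species* are present and how abundant they are, or by the *functional
traits* those individuals carry (feeding morphology, locomotion, nutrient
excretion). When several species carry similar trait values — functional
redundancy — species turnover need not translate into trait turnover, so a
community can look unstable through a species lens and stable through a
trait lens. `traitstab` quantifies that contrast for multi-pond,
multi-year fish survey data and for synthetic data with the same
statistical structure.

The pipeline is: impute traits for every surveyed individual from a
measured reference sample; aggregate to pond-by-year species-abundance and
community-weighted-trait matrices; compute Bray–Curtis dissimilarities;
measure stability in ordination space; test differences with a two-way
ANOVA, PERMANOVA, SIMPER, and vector fitting; and control for dimensional
reduction with mock communities of matched dimensionality.

## Trait imputation

Each of 13 traits is modeled as

$$y_{ij} = \alpha_{t(i)} + s(L_{ij}) + \varepsilon_{ij},$$

a taxon intercept plus a penalized thin-plate spline of fork length $L$,
with the smoothing parameter $\lambda$ chosen by REML (via `mgcv::gam`,
the standard engine for this model class — we deliberately use it rather
than re-deriving spline penalties, and verify the REML optimum by a
$\lambda$-grid local-optimality test). Morphometric traits are fitted at
species level; the three nutrient-recycling traits (NH4, PO4, N:P) at
family level, because excretion is measured per family, and surveyed
species inherit their family's model.

Choices a user should know about:

* **Shared smooth by default.** `trait ~ taxon + s(length)` rather than
  per-taxon smooths: with roughly 20 measured fish per species, per-taxon
  smooths are weakly identified. `smooth = "by_taxon"` is available.
* **Basis dimension** defaults to `k = 10`, reduced automatically when a
  trait has few distinct lengths.
* **Extrapolation is clamped.** Surveyed fish outside the measured length
  range are predicted at the nearest range boundary; splines extrapolate
  wildly and the survey contains sizes never measured in hand. Clamp
  counts are logged.
* **Unmeasured individuals** (cell count minus measured rows) enter as one
  pseudo-individual at the species' survey-wide mean length, weighted by
  the number of fish it represents. The source data do not say how
  unlengthed fish were handled; this is our choice and it is logged.
* Taxa with a single record cannot inform the length effect; they are
  imputed as their taxon mean, with a warning.

## Community matrices

Abundance cells are a two-stage average: counts are averaged across
stations within each month, then across months, with absent species
counting as zero and denominators taken from the station-months actually
sampled. A one-stage grand mean is available (`average = "grand"`) since
the averaging order is not fully pinned down by the source description.

The trait matrix holds community-weighted means: the weighted average of
predicted individual trait values per pond-year. Negative cells (possible
for excretion differences) are clamped to zero by default with a logged
count, because Bray–Curtis assumes non-negative data; `clamp_negative =
FALSE` and `rescale_minmax()` expose the alternatives.

## Distances, ordination, stability

`bray_curtis()`, `pcoa()` and `nmds()` are implemented from scratch (they
are the analytical core, and tests compare them against vegan as an
independent oracle). nMDS minimizes Kruskal stress-1 by alternating
isotonic regression (pool-adjacent-violators, primary/weak ties) with a
Guttman update, backtracking the step so stress is non-increasing within a
start; 20 random starts plus a principal-coordinates start. No
Wisconsin/square-root pre-transformations are applied by default — the
source analysis does not mention them — but scaling options are exposed.

`year_to_centroid()` measures, per pond, how far each yearly community
sits from the pond's multi-year average. The default mode works in PCoA
space exactly as `vegan::betadisper`: squared distances are (positive-axis
part) − (negative-axis part), floored at zero (the floor count is
reported). The verbal definition — Bray–Curtis between each year and the
time-mean composition row — is implemented as `mode = "raw_to_mean"`;
both are first-class because the source is ambiguous about which was used.
The centroid is the group mean by default (matching the description
"average (or centroid)"); a spatial-median option exists but note it is a
joint numerical optimization in the signed PCoA geometry and does *not*
reproduce vegan's `type = "median"` algorithm numerically.

`year_to_year()` takes Bray–Curtis between consecutive observed years;
gaps in the year sequence are logged, never bridged. Relative stability
divides every distance by the maximum across all ponds and units within
its composition type, so values live in [0, 1] and the least stable
pond-year scores 1. The crossed two-way ANOVA
(`pond * composition_type`, years or transitions as replicates) uses Type
I sums of squares on the balanced design — all SS types coincide there —
and falls back to Type II with a warning when unbalanced.

## Inference

PERMANOVA partitions the Gower-centered inner-product matrix by the
sequential model `pond + year + pond:year` with **year as a numeric
covariate** (1 df) — the degrees-of-freedom pattern of the reference
results (5, 1, 5, 24 for 6 ponds × 6 years) forces this reading —
with free row permutation and the `+1` p-value convention. SIMPER is
computed only over the comparisons the analysis actually uses (each year
versus the pond's time-mean; consecutive year pairs), not the classic
all-pairs between-group average; contributions sum exactly to the pair's
Bray–Curtis value, percents to 100. `envfit()` regresses each
species/feeding-mode abundance on the trait-ordination scores, reporting
unit direction cosines, $R^2$, and a permutation p value.

## The synthetic world

The generator mirrors the study design: 6 ponds × 6 years × 6 months × 2
stations, 27 species in four feeding modes split 3/6/9/9 (detritivore /
planktivore / hunting-meiofauna / hunting-macrofauna). Counts are Poisson
with a lognormal mean,

$$\log \mathbb{E}[N_{spy}] = \log b_s + \pi_{sp} + \eta_{sy},$$

where the pond offsets $\pi_{sp} \sim N(0, \sigma_{\text{space}}^2)$ are
fixed across years (persistent spatial filtering — pond characteristics
stay put through time), and the year shocks $\eta_{sy}$ have SD
$\sqrt{\log(1 + \mathrm{CV}^2)}$ with the within-feeding-mode mean removed
in proportion to the `compensation` parameter, so at compensation 1 the
mode-level log-fluctuations sum to zero (compensatory dynamics).
Trait means mix a feeding-mode archetype with an independent draw using
convex weight `redundancy`; because the random draws do not depend on the
weight, pools at different redundancy but the same seed are exact convex
mixtures of one another — which is how the tests verify the mixture
formula "by hand".

Defaults chosen where no value was stated, fixed once: measurement noise
SD 0.05 on traits whose scales are O(0.1–10); interannual CV 0.5 and
spatial filter SD 0.5 on the log scale (substantial year-to-year
reassembly and persistent pond differences, as described for these
coastal ponds); base abundances lognormal around 5 fish per station
visit; fork lengths truncated-normal with SD 18% of the species mean.
What the generator does **not** emulate: mechanistic dispersal or food-web
dynamics, observation-process detectability, month effects, and
trait–abundance feedbacks. A green end-to-end test therefore establishes
that the *statistical* mechanism (redundancy + compensation → trait
stability) is recovered, not that any field system behaves this way.

## Mock-community control

Comparing a 27-column species matrix against a 13-column trait matrix
confounds stability with dimensionality. `run_mock_experiment()` draws
column subsets of equal size (independently for species and traits,
uniformly without replacement), recomputes the whole stability comparison
per replicate, and reports the per-replicate trait-minus-species gap in
mean relative distance, on both the relative and raw scales (the
max-normalization is per composition type, so both are informative). With
traits built as a column permutation of species abundances the gap is
identically zero — Bray–Curtis is column-order-free — which the tests
assert as a structural identity.

## Numerical notes and limitations

* Negative squared distances from negative PCoA eigenvalues are floored at
  zero and counted, as in common betadisper practice.
* All randomness is funneled through per-stage seeds derived from one run
  seed; identical configurations give byte-identical CSV outputs.
* p-value resolution is $1/(n_{\text{perm}}+1)$; permutations are free
  (unrestricted), matching the common adonis default — restricted schemes
  are out of scope.
* nMDS with few points and many ties can stop at local optima; increase
  `n_starts`.
* No uncertainty from trait imputation is propagated into downstream
  statistics; imputed values are treated as known.
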