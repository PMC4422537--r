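---
title: "Core and mini core collection methods in germcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core and mini core collection methods in germcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcore)
```

## The problem

Large ex situ germplasm collections hold thousands of accessions; screening
all of them for breeding traits is impractical. The standard remedy is a
*core collection* — a subset of roughly 20% chosen to represent the whole
collection's diversity — and, for very large collections, a *mini core* of
about 20% of the core that concentrates the marker-level diversity.
`germcore` implements both constructions together with the statistics used
to certify them, for panels described by three tables: passport data (id,
country, region), quantitative trait descriptors, and dominant-scored SSR
bands (0/1 per band, bands grouped by locus, each band treated as one
allele of its locus).

## Core selection

`build_core()` follows the classical stratified recipe:

1. stratify accessions by geographic region;
2. within each region, compute the standardized Euclidean distance over
   the quantitative descriptors (each descriptor z-scored over the
   analyzed set) and cluster by UPGMA;
3. cut the dendrogram into flat clusters — by height, or into
   `max(2, ceiling(region_size / 50))` clusters by default;
4. from each cluster draw `round(fraction × size)` accessions uniformly
   without replacement, with a minimum of one per nonempty cluster.

The minimum-one rule guarantees that small, distinct clusters (the
"outlier" accessions genebank curators care about) survive into the core;
its price is a slight oversampling of extremes, which grows with cluster
granularity. A region with a single accession has no distance structure;
that accession enters with probability `fraction`.

The number of clusters per region is genuinely underdetermined in
practice; the `region_size / 50` default keeps clusters large enough that
proportional quotas are meaningful, and both `target_clusters` and
`cut_height` are exposed.

## Distances

* **Standardized Euclidean** (traits): z-scores use the sample SD
  (`n − 1`); descriptors missing in either member of a pair are excluded
  and the squared sum is rescaled by `K/K_obs`, which keeps distances
  comparable across pairs with unequal trait coverage. A descriptor that
  is constant over the analyzed set contributes zero.
* **Jaccard** (bands): distance `1 − a/(a + b + c)` over band columns,
  computed only over loci scored in both accessions.
* **Modified Rogers** (bands):
  `MR(i,j) = sqrt(Σ(xᵢ−xⱼ)²/(2m))` over the `m` co-scored loci, with `x`
  the per-locus band indicator vectors. With one band per locus each
  differing locus contributes 2 to the sum, so MR² is simply the fraction
  of differing loci and accessions differing everywhere are at distance 1.
* **Group dissimilarity**: groups (origins, trait classes) are pooled into
  per-locus frequency tables and compared with the same MR formula — the
  between-group measure is an explicit package choice, since published
  group-level dissimilarities rarely state theirs.

Missing marker data are treated at the locus level: a locus with any
unscored band cell for an accession is excluded for that accession from
frequencies, distances and genotype tallies. Band absence (a scored 0) and
missingness are never conflated, because dominant scoring cannot
distinguish allele absence from amplification failure.

## UPGMA

`upgma()` is a direct implementation of average linkage with one
deliberate addition: ties in the minimum inter-cluster distance are broken
by the lexicographically smallest pair of cluster labels (each cluster
labeled by its smallest member). Published dendrograms from legacy
packages are not reproducible at tie level; a fixed rule at least makes
*this* package's trees order-independent and reproducible. The result is a
standard `hclust` object (cophenetic distance between two leaves equals
the merge height of their lowest common ancestor), and the test suite
checks it against both `stats::hclust(..., "average")` on tie-free input
and an independently coded direct-averaging implementation on exhaustive
small instances. Newick export writes branch lengths as differences of
merge heights, so a two-leaf tree merged at height 0.5 reads
`(A:0.5,B:0.5);`.

## Marker and trait diversity

Per locus, with band frequencies `p`: Shannon information index
`I = −Σ p ln p` (natural logs throughout, following population-genetics
convention), Nei expected heterozygosity `H = 1 − Σ p²`, and
`PIC = 1 − Σ p² − Σᵢ<ⱼ 2 pᵢ² pⱼ²`. Genotypes are exact per-locus band
patterns; multilocus genotypes are counted over fully scored accessions.

The trait Shannon–Weaver index bins values into `n_classes` equal-width
classes over the *reference* collection's range and normalizes by
`ln(n_classes)`, so indices of collections with different class counts are
comparable and lie in [0, 1]. Two choices here are documented assumptions
rather than published fact: published trait-diversity tables in this
domain do not state their binning, and the normalization is inferred from
the narrow [0.6, 0.9] range such tables report across descriptors with 10
to 15 classes, which an unnormalized index could not produce. Bin edges
always come from the reference panel so that whole, core and mini core are
binned on one shared class system.

## Mini-core optimization

`build_minicore()` maximizes, over subsets of fixed size
`round(target_fraction · n)`,

```
objective = w_MR · mean pairwise MR  +  w_SH · Shannon term,
```

with default weights 0.7/0.3. The Shannon term is the subset's per-locus
Shannon information index averaged over loci and normalized by the log of
the panel's total declared band count, which puts it on [0, 1] (a subset
of identical accessions scores exactly 0) and makes the weighting
meaningful across panels. The optimizer is a deliberately simple
mixed-replica scheme: independent stochastic searches from random subsets,
one-accession swap proposals accepted when the objective does not
decrease, and periodic replica restarts from the global best. It is a
reimplementation of the *idea* of mixed-replica subset search, not a port
of any specific optimizer's internals; its contract — finding near-optimal
subsets — is verified against exhaustive enumeration on all subsets of
small panels, and against random-subset baselines on larger ones. The
best-so-far objective is monotone in the step budget by construction.

Two baseline strategies mirror the validation designs used for published
mini cores: proportional sampling within marker-UPGMA clusters, and
proportional sampling within geographic regions. `compare_minicores()`
tabulates per-locus allele and genotype retention for any set of
selections.

## Validation statistics

* **Equality test**: the published comparison tables report a χ²-based
  "equality test of two samples" without naming it; the package implements
  the Brown–Mood median test (2×2 table of counts above/below the pooled
  median, 1 df, no continuity correction) — the classical nonparametric
  two-sample χ² reported by the major statistical suites. This
  identification is the package's single largest interpretive assumption
  and is stated here deliberately.
* **Homogeneity test**: χ² on the 2×k table of class counts over the
  reference class system; classes with expected count below 1 are pooled
  into their right neighbor (last into the previous) and the degrees of
  freedom are reduced accordingly. Fewer than two occupied classes is
  reported as degenerate with p = 1 rather than an error.
* **Q-Q / KL**: empirical quantiles of both samples on the 0.5% grid (199
  interior points, linear interpolation); the two quantile vectors are
  discretized into 20 shared equal-width bins and the plugin estimator
  `KL(p‖q) = Σ p ln(p/q)` is computed with add-one smoothing of the counts
  on both sides — the estimator is undefined on empty q-bins and no
  published smoothing rule exists, so a symmetric, simple rule was chosen.
  The statistic is invariant under a common affine transform of both
  samples and zero exactly when the binned distributions coincide.
* **Mantel test**: Pearson correlation of the off-diagonal triangles with
  simultaneous row/column permutations of the second matrix;
  `p = (1 + #{r_perm ≥ r_obs})/(1 + n_perm)`, one-sided by default as the
  population-genetics tools report it, with a two-sided option. p-values
  therefore live on a grid and are never zero.
* **Correlation comparison**: Fisher z on each subset's Pearson
  correlation per trait pair; `|r| = 1` is flagged with infinite z rather
  than silently propagated.

`compare_collections()` assembles all of the above into one report whose
CSV layout mirrors the published whole/core/mini comparison tables. For
large subsets the Mantel test runs on a seeded subsample (default cap 300
accessions) because the distance matrices grow quadratically.

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure of a large
Asian-centred mungbean collection:

* **Regions** are drawn from a weight vector (South and Southeast Asia
  dominant) and decorated with plausible countries; region and
  subpopulation are sampled independently, since population structure in
  such collections is not geographically clean.
* **Traits**: eight descriptors with the collection's published means and
  variances. Within each subpopulation traits are correlated multivariate
  normal (leaf dimensions 0.75, plant heights 0.85, height–flowering
  0.4–0.5, pod–seed relations, a slight seed-number/seed-weight trade-off)
  and clipped at zero. The two subpopulations' means are split
  `trait_divergence` SDs apart (default 0.6) with the within-subpopulation
  SD shrunk so the whole-panel mean and variance equal their configured
  values exactly. This reproduces the two overlapping phenotypic
  mega-clusters that UPGMA reveals in real collections of this kind; a
  single unimodal cloud would misrepresent the data the method is designed
  for.
* **Markers**: 20 loci with 3–13 bands each; per locus a base frequency
  vector is drawn from a symmetric Dirichlet, and each subpopulation's
  frequencies from a Dirichlet centered on the base with concentration
  `(1 − d)/d` — the hierarchical (Balding–Nichols-type) model in which
  `d` is the Fst-like divergence. A linear mixture of Dirichlet draws was
  tried first and discarded: its between-subpopulation distance gap is
  bounded by `d²` times a small factor, which no clustering can recover at
  realistic `d`, whereas the hierarchical model separates cleanly
  (top-split recovery ≥ 99% at `d = 0.3`, `n = 400`).
* **Bands**: exactly one band per locus per accession (homozygote model —
  mungbean is predominantly selfing; heterozygous multi-band patterns are
  out of scope). A consequence worth knowing: per-locus genotype counts
  equal allele counts in synthetic panels, whereas real dominant data show
  more genotypes than alleles.
* **Missingness**: `simulate_band_noise()` masks accession×locus cells
  independently (MCAR) to exercise the missing-data contracts.

What the generator does **not** emulate: linkage between loci,
trait–marker association (so phenotypic and genotypic dendrograms agree
only through shared subpopulation structure), informative missingness,
measurement rounding, and the near-duplicate "entry" structure of real
genebanks (variants of one accession sorted by seed characters). Passing
tests on synthetic panels therefore certify the algorithms, not the
biology of any particular collection.

## Numerical choices

* Per-cluster quotas round half up (`floor(x + 0.5)`), so a quota of 0.5
  never silently drops a cluster below the minimum-one rule.
* All stochastic entry points take explicit integer seeds; pipeline stages
  derive their seeds from the global seed plus the stage name, so adding a
  stage never shifts existing random streams. Seeded code saves and
  restores the caller's RNG state.
* Frequency vectors are validated to sum to 1 within 1e-8; empty loci are
  flagged and excluded rather than propagating NaN.
* Degenerate statistics (all values equal, zero-variance triangles,
  single-class tables) are flagged explicitly with conventional values
  (p = 1, KL = 0) instead of erroring mid-report.

## Problem sizes used by the test and acceptance suites

The suites are sized to certify behavior, not to benchmark: exhaustive
oracles run on panels of up to 12 accessions and distance matrices up to
7×7; calibration checks use 1000 replicates of two 500-value samples;
representativeness runs five stratified core draws on 2000-accession
panels; structure recovery uses five 400-accession panels.

## Known limitations

* The representativeness of a stratified-cluster core is bounded by
  sampling theory: with a core of `n_c` accessions the relative error of a
  trait mean scales as `cv · sqrt((1 − f) · w / n_c)`, where `w` is the
  within-cluster variance share left after stratification. UPGMA chains on
  weakly structured trait clouds (one cluster can absorb most of a
  region), so `w` stays high and the worst-descriptor deviation of a
  ~400-accession core from a 2000-accession panel is typically 1–2%, an
  order of magnitude above the per-descriptor agreement achievable for
  cores of 1500+ accessions drawn from full-size collections. The
  acceptance script reports this quantity as computed, whatever it is.
* The optimizer is greedy per replica; diversification comes only from
  replicas and restarts. For panels far larger than those tested, a tabu
  or simulated-annealing acceptance rule may be worth adding.
* The equality-test identification (Brown–Mood) and the KL smoothing rule
  are documented assumptions; swap in another two-sample test if your
  reporting tradition differs.
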