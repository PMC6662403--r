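---
title: "Quantifying multidimensional specialization and its phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multidimensional specialization and its phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecospec)
```

## The measurement problem

How specialized is a species? A bird that eats one kind of food, forages one
way, and nests in one kind of site occupies a narrower niche than one that
spreads its activity across many categories. `ecospec` quantifies this from a
binary species-by-trait table: traits are grouped into named *bundles* (diet
categories, foraging behaviors, foraging substrates, habitats, nesting
sites, ...), each scored 0/1 for each species, and within each bundle a
species receives one specialization index. A second question follows
immediately in any comparative setting: do related species share similar
specialization levels? The package answers it with Blomberg's K and K*
statistics and Moran's I phylogenetic correlograms on a consensus phylogeny.

## The Gini coefficient as a specialization index

For a trait vector $x_1, \dots, x_n$ within one bundle, the index is the Gini
inequality coefficient

$$G = \frac{\sum_{i=1}^n \sum_{j=1}^n |x_i - x_j|}{2 n^2 \bar{x}},$$

optionally multiplied by the small-sample correction $n/(n-1)$. On binary
data the two anchors are interpretable directly: a species using every
category alike ($x$ constant) has $G = 0$, maximal generalism; a species
using a single category (one-hot $x$) has corrected $G = 1$, perfect
specialization. The uncorrected statistic tops out at $(n-1)/n$, which is why
the corrected form is the default: it is the variant whose maximum is exactly
1, and the variant computed by the widely used `DescTools::Gini` with
`unbiased = TRUE`. Gini is scale-free and permutation-invariant in the trait
columns, so bundles of different sizes (9 diet categories vs. 18 nesting
sites) yield comparable indices.

A species with an all-zero row in some bundle has an undefined index (the
denominator vanishes). `validate_trait_table()` reports such rows as hard
errors rather than silently emitting `NaN`: an all-zero row is a data
problem, not a biological statement.

```{r gini}
gini(c(1, 0, 0, 0, 0, 0, 0, 0, 0))   # one diet category only
gini(rep(1, 9))                      # all nine categories
```

## From bundles to an overall index

`bundle_indices()` applies the Gini to every species and bundle.
`overall_index()` then aggregates each species' bundle indices with the mean
(default; maximum and minimum are available) and min–max standardizes the
aggregate across species, so the observed range maps onto $[0, 1]$ with the
most generalist species at 0 and the most specialist at 1. Two points were
genuinely open and are resolved as follows:

* Each aggregator is standardized separately across species (standardize
  after aggregating, not before). Ranks are unaffected either way; the
  choice only fixes the scale on which the index is reported.
* Which bundles enter the overall index is an explicit argument. Strongly
  correlated bundles (e.g. a year-round and a breeding-season diet index,
  which in real bird data correlate at $\rho > 0.8$) can double-weight one
  dimension; the caller decides what to drop, the package does not guess.

`classify()` labels species specialist/generalist at a user-supplied cutoff.
There is deliberately no default threshold: any cutoff on a continuous index
is a study-level decision, and published specialist counts are not
reproducible without knowing it.

`index_correlations()` reports Shapiro–Wilk normality per index and Spearman
rank correlations between indices (trait-derived indices are rarely normal,
so a rank method is the default and only option). Spearman p-values use the
exact small-sample distribution for $n \le 10$ and the t-approximation
otherwise.

## Consensus trees

Posterior samples of phylogenies (e.g. 1,000 trees drawn from a tree
repository) are condensed with `majority_consensus()`: the consensus
contains exactly the clades whose frequency across the sample *strictly
exceeds* the threshold (default 0.5). The strict inequality matters — at
exactly 50% two incompatible clades could both qualify, while any two clades
above 50% are automatically compatible. Branch lengths on retained clades
are the mean of the subtending edge over the trees containing that clade;
pendant edges average over all trees. Trees are treated as rooted as
written; nothing is midpoint-rooted behind the caller's back, because the K
statistic depends on the root. Consensus polytomies are kept as polytomies —
the covariance matrix is well defined on them — rather than resolved with
zero-length edges, which would make the matrix singular.

## Blomberg's K and K*

Let $C$ be the phylogenetic variance–covariance matrix ($C_{ij}$ = shared
root-to-tip path length, from `vcv_matrix()`). With the GLS phylogenetic
mean $\hat{a} = (\mathbf{1}'C^{-1}\mathbf{1})^{-1}\mathbf{1}'C^{-1}x$,

$$\mathrm{MSE} = \frac{(x-\hat{a})'C^{-1}(x-\hat{a})}{n-1}, \qquad
  \mathrm{MSE}_0 = \frac{(x-\hat{a})'(x-\hat{a})}{n-1},$$

and the Brownian-motion expectation of their ratio
$\left[\operatorname{tr}(C) - n/(\mathbf{1}'C^{-1}\mathbf{1})\right]/(n-1)$,
the statistic is
$K = (\mathrm{MSE}_0/\mathrm{MSE}) \big/ E_{BM}[\mathrm{MSE}_0/\mathrm{MSE}]$.
$K \approx 1$ is consistent with Brownian evolution; $K$ near 0 means no
signal; $K > 1$ means relatives resemble each other more than Brownian
motion predicts. K* is the companion statistic that centers the numerator on
the arithmetic mean $\bar{x}$ instead of $\hat{a}$; the two coincide on an
ultrametric star tree and differ little on real trees. The literature names
both without always giving formulas; this pairing (K = GLS-centered,
K* = arithmetic-centered) is the package's explicit definition, and the two
are reported side by side so the choice is auditable.

On a star tree $C = tI$ and every correction vanishes, so $K = K^* = 1$
exactly for any non-constant trait — a useful analytic identity that the
test suite asserts to $10^{-10}$. $K$ is invariant to affine trait
transforms and to rescaling all branch lengths, so index units and tree
depth units do not matter.

Significance comes from `k_permutation_test()`: trait values are shuffled
across tips, and the GLS MSE is compared with its permutation distribution —
real signal makes the observed MSE small. The p-value uses the add-one
estimator $(1 + \#\{\mathrm{MSE}_{perm} \le \mathrm{MSE}_{obs}\})/(n_{perm}+1)$,
which never returns 0. The default is 999 permutations; all permutation
draws flow from an explicit seed recorded in the result.

## Moran's I correlograms

`phylo_correlogram()` resolves the signal by distance: the range of
patristic distances is cut into equal-width classes, and within each class
Moran's I is computed with binary weights (1 if the pair's distance falls in
the class). Under the permutation null $E[I] = -1/(n-1)$. Confidence
intervals come from bootstrap resampling of tips (default 100 replicates,
the convention for this kind of correlogram); resampled indices are applied
to the trait vector and both margins of the distance matrix, and pairs
formed by two copies of the same tip are dropped from the weights. A class
is called significantly positive when its 95% bootstrap interval lies
entirely above $-1/(n-1)$. Brownian-like traits show positive I in the
smallest-distance classes — signal concentrated near the tips — decaying and
often turning negative at the largest distances. Equal-width binning is the
testable contract here; smooth-curve correlograms are presentation, not
inference, and are out of scope.

## Synthetic data as the validation instrument

Because every statistic above has a known behavior under a known generative
model, the package ships its own generators rather than depending on
external downloads:

* `simulate_yule_tree()` — pure-birth trees: exponential waiting times with
  rate $k\lambda$ while $k$ lineages are alive, including the final waiting
  time at $n$ lineages, so the expected root-to-tip depth is
  $\sum_{k=2}^{n} 1/(k\lambda)$. Yule suffices as a plausible ultrametric
  test phylogeny; birth–death models and posterior samples of real trees
  add realism the statistics do not need for validation.
* `simulate_bm_traits()` — Brownian traits by preorder accumulation of
  Normal(0, $\sigma^2 \cdot$ edge length) increments; the tip covariance is
  $\sigma^2 C$ by construction.
* `simulate_trait_table()` — binary bundles with a specialization dial: the
  number of used categories is $1 + \mathrm{Binomial}(n_{traits}-1,
  1-s)$, placed uniformly. At $s = 1$ every row is one-hot (corrected Gini
  exactly 1), at $s = 0$ all-ones (Gini 0), and the expected Gini increases
  monotonically in between. Rows always keep at least one 1, so generated
  tables always validate.

What the generators deliberately do not emulate: correlated evolution
between bundles, discrete trait evolution on the tree (trait rows are drawn
independently of the phylogeny), rate heterogeneity, and observational error
in trait scoring. Passing tests therefore demonstrate that the statistics
behave correctly under their own model assumptions — calibrated type-I
error, parameter recovery, correct nulls — not that any particular empirical
dataset satisfies those assumptions.

## Validation sizes and numerical choices

The test suite fixes its problem sizes as a compromise between statistical
resolution and a test run measured in seconds: K recovery uses 200 Brownian
replicates on a 128-tip Yule tree (mean K within $[0.9, 1.1]$; tip-shuffled
traits fall below 0.5); permutation-test calibration uses 1,000 null
replicates at 32 tips with 199 permutations (rejection rate $0.05 \pm
0.02$); power uses 200 Brownian replicates at 64 tips (≥ 0.9); correlogram
behavior uses 100 replicates at 64 tips with 100 bootstraps each. Exact
identities (Gini double-sum oracle, star-tree K, Moran's I double loop) are
asserted to $10^{-10}$–$10^{-12}$.

Degenerate inputs fail loudly and early: zero-mean Gini rows, constant trait
vectors (K reported as 0 and flagged; permutation p forced to 1 with a
warning), singular covariance matrices (no automatic jitter — zero-length
branches are the caller's to resolve), empty distance classes (NA with a
warning). Stochastic functions take explicit integer seeds and record them
in their outputs; the pipeline writes a manifest with input hashes, package
version and seed, and its outputs are byte-identical across reruns.

## A worked run

```{r pipeline, eval = FALSE}
spec <- list(diet = list(n_traits = 9, specialization = 0.6),
             habitat = list(n_traits = 15, specialization = 0.4))
tab <- simulate_trait_table(64, spec, seed = 1)
trees <- structure(lapply(1:25, function(i) {
  tr <- simulate_yule_tree(64, 1, seed = 1000 + i)
  tr$tip.label <- rownames(tab)
  tr
}), class = "multiPhylo")
res <- run_pipeline(tab, NULL, trees, out_dir = "run1",
                    n_perm = 999, n_classes = 8, n_boot = 100, seed = 42)
res$signal$overall_mean
```

Note the simulated trait table is independent of the simulated trees, so K
for these indices hovers near 0 with non-significant p-values — the correct
answer for phylogeny-free traits, and a useful negative control to contrast
with `simulate_bm_traits()`, where K near 1 is recovered.

## Known limitations

* Binary traits only. The Gini coefficient itself handles continuous
  weights (e.g. percentage diet composition), and the core `gini()` accepts
  them, but the table container enforces 0/1 in this version because mixed
  scales across a bundle would make indices incomparable.
* Thresholds for specialist/generalist classification are never invented;
  counts depend entirely on the caller's cutoff.
* K and K* are the only signal statistics (no Pagel's lambda, no
  Abouheif's test); Moran's I correlograms use equal-width distance bins.
* The consensus is a clade (rooted) consensus; unrooted split semantics
  coincide for these inputs but are not separately implemented.
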