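# ecospec

Multidimensional ecological specialization indices and their phylogenetic
signal.

## The problem

Whether a species is a specialist or a generalist is rarely a property of a
single niche axis. A bird may eat only one kind of food yet nest almost
anywhere; collapsing its ecology into one number hides that structure.
`ecospec` is for comparative ecologists who have (a) a table of binary
(0/1) species traits grouped into named *bundles* — e.g. 9 diet categories,
9 foraging behaviors, 9 foraging substrates, 15 habitats, 18 nesting sites —
and (b) a sample of phylogenetic trees over those species, and who want:

1. one specialization index per species per bundle,
2. an overall specialization index on a common 0–1 scale,
3. an answer to whether related species show similar specialization
   (phylogenetic signal), and at which phylogenetic distances.

## The statistics

**Specialization** is measured per bundle with the Gini inequality
coefficient of the species' trait vector,

    G = Σᵢ Σⱼ |xᵢ − xⱼ| / (2 n² x̄),

by default multiplied by the bias correction n/(n−1) so that a species
using a single category scores exactly 1 (perfect specialist) and a species
using every category alike scores 0 (perfect generalist). Per-species
bundle indices are aggregated (mean by default) and min–max standardized
across species into an overall index on [0, 1].

**Phylogenetic signal** of each index is quantified with Blomberg's K and
K*: the ratio of the trait's mean squared error ignoring phylogeny to its
GLS error under the phylogenetic covariance matrix C, scaled by the
expectation of that ratio under Brownian motion. K ≈ 1 is consistent with
Brownian evolution, K ≈ 0 with no signal. Significance comes from a
one-tailed tip-permutation test. Moran's I computed within equal-width
patristic-distance classes (with 100-bootstrap confidence bands) resolves
where on the tree the autocorrelation lives. Tree samples are condensed
with a strict 50% majority-rule consensus whose branch lengths average the
source trees.

Yule tree, Brownian-motion trait, and binary trait-table simulators with
known ground truth back the test suite and provide negative/positive
controls for real analyses.

## A worked example

```r
library(ecospec)

# six species, two bundles with different specialization targets
tab <- simulate_trait_table(6, list(
  diet    = list(n_traits = 9,  specialization = 0.7),
  habitat = list(n_traits = 15, specialization = 0.3)), seed = 7)
prof <- overall_index(bundle_indices(tab), aggregator = "mean")
print(prof, digits = 3)
#>   species  diet habitat overall_mean
#> 1     sp1 0.250   0.429        0.000
#> 2     sp2 0.750   0.429        0.800
#> 3     sp3 0.875   0.286        0.771
#> 4     sp4 0.875   0.429        1.000
#> 5     sp5 0.875   0.286        0.771
#> 6     sp6 0.625   0.357        0.486
```

`diet` rows were simulated more specialized than `habitat` rows, and their
Gini indices sit correspondingly higher; `overall_mean` rescales the
per-species mean of the two so the extremes hit 0 and 1 exactly.

```r
# signal of a Brownian trait on a 64-tip Yule tree: K should be near 1
tr <- simulate_yule_tree(64, 1, seed = 11, tip_prefix = "sp")
x  <- simulate_bm_traits(tr, sigma2 = 1, seed = 12)
k_permutation_test(x, vcv_matrix(tr), n_perm = 999, seed = 13)
#> Blomberg's K = 1.0699, K* = 1.0435 (n = 64 tips)
#>   permutation p = 0.001 (999 permutations, seed 13)

phylo_correlogram(x, patristic_distances(tr), n_classes = 5,
                  n_boot = 100, seed = 14)
#>   class_low class_high class_mid n_pairs     I ci_low ci_high significance
#> 1     0.026        1.6      0.81     120  0.87  0.480    1.23     positive
#> 2     1.602        3.2      2.39     244  0.32  0.160    0.56     positive
#> 3     3.179        4.8      3.97     384  0.57  0.018    0.99     positive
#> 4     4.755        6.3      5.54     572  0.41  0.120    1.14     positive
#> 5     6.331        7.9      7.12    2712 -0.26 -0.389   -0.16     negative
```

The Brownian trait shows K near 1 with p = 0.001, strong positive
autocorrelation among close relatives (smallest distance classes) decaying
to significant negative autocorrelation between the most distant tips —
the classic correlogram shape of phylogenetically conserved traits.

`run_pipeline()` chains the whole analysis (traits → indices →
correlations → consensus → K/K* → correlograms) and writes `indices.csv`,
`correlations.csv`, `consensus.nwk`, `signal.json`, `correlogram.tsv` and a
seed-carrying `manifest.json`. A thin command-line front-end with the same
coverage lives at `inst/cli/ecospec.R`
(`Rscript inst/cli/ecospec.R run --traits ... --bundles ... --trees ...
--out-dir out`); a demo bundle configuration is in
`inst/extdata/bundles_demo.yaml`.

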