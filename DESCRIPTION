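Package: ecospec
Title: Multidimensional Ecological Specialization Indices and Their Phylogenetic Signal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-species ecological specialization indices as Gini
    inequality coefficients over named bundles of binary traits (diet, foraging
    behavior, foraging substrate, habitat, nesting site, or any user-defined
    grouping), aggregates them into an overall specialization index standardized
    to [0, 1], and quantifies the phylogenetic signal of each index with
    Blomberg's K and K* statistics (permutation tests) and Moran's I
    phylogenetic correlograms with bootstrap confidence intervals. Includes a
    50% majority-rule consensus builder with averaged branch lengths for tree
    samples, Yule tree and Brownian-motion trait simulators for validation, and
    an end-to-end pipeline with reproducible seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
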