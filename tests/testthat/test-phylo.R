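write_newick <- function(lines) {
  path <- tempfile(fileext = ".nwk")
  writeLines(lines, path)
  path
}

test_that("read_trees parses multi-tree Newick and enforces one tip set", {
  path <- write_newick(rep("((A:1,B:1):1,(C:1,D:1):1);", 3))
  trees <- read_trees(path)
  expect_s3_class(trees, "multiPhylo")
  expect_length(trees, 3)
  expect_setequal(trees[[1]]$tip.label, c("A", "B", "C", "D"))
  bad <- write_newick(c("((A:1,B:1):1,(C:1,D:1):1);",
                        "((A:1,B:1):1,(C:1,E:1):1);"))
  expect_error(read_trees(bad), "different tip set.*E")
})

test_that("space- and underscore-form species names are interconverted", {
  # trait data keyed by "Genus species", tree tips by "Genus_species"
  expect_identical(normalize_species_labels(c("  Parus major ", "Sitta_europaea")),
                   c("Parus_major", "Sitta_europaea"))
  tr <- ape::read.tree(
    text = "((Parus_major:1,Parus_ater:1):2,(Sitta_europaea:1.5,Certhia_brachydactyla:1.5):1.5);")
  C <- vcv_matrix(tr)
  x <- setNames(c(0.1, 0.9, 0.4, 0.6),
                c("Parus major", "Parus ater", "Sitta europaea",
                  "Certhia brachydactyla"))
  expect_s3_class(blomberg_k(x, C), "signal_result")
})

test_that("consensus of identical trees is that tree with its branch lengths", {
  path <- write_newick(rep("((A:1,B:1):1,(C:1,D:1):1);", 3))
  trees <- read_trees(path)
  cons <- majority_consensus(trees)
  ref <- trees[[1]]
  expect_true(ape::all.equal.phylo(cons, ref, use.edge.length = FALSE))
  # branch lengths survive averaging over identical copies
  expect_equal(sort(cons$edge.length), sort(ref$edge.length))
})

test_that("2/3 majority keeps AB|CD and drops AC|BD; lengths are means over holders", {
  trees <- c(quartet("AB", bl = 1), quartet("AB", bl = 2), quartet("AC", bl = 3))
  cons <- majority_consensus(trees)
  expect_true(ape::all.equal.phylo(cons, quartet("AB"),
                                   use.edge.length = FALSE))
  # clade (A,B) occurs in trees 1 and 2 with stem lengths 1 and 2 -> mean 1.5
  m <- ape::mrca(cons)
  ab_node <- m["A", "B"]
  stem <- cons$edge.length[cons$edge[, 2] == ab_node]
  expect_equal(stem, 1.5)
  # tip edges average over all 3 trees: (1 + 2 + 3) / 3
  a_edge <- cons$edge.length[cons$edge[, 2] == which(cons$tip.label == "A")]
  expect_equal(a_edge, 2)
})

test_that("a split in exactly half the trees is excluded (strict majority)", {
  trees <- c(quartet("AB"), quartet("AB"), quartet("AC"), quartet("AC"))
  cons <- majority_consensus(trees)  # each split at 2/4 = 0.5, not > 0.5
  expect_identical(cons$Nnode, 1L)   # star: no internal clade survives
})

test_that("every retained clade recounts above threshold; order does not matter", {
  set.seed(31)
  base <- simulate_yule_tree(12, 1, seed = 40)
  sample <- structure(lapply(1:9, function(i) {
    tr <- base
    if (i > 6) tr <- simulate_yule_tree(12, 1, seed = 40 + i)  # minority noise
    tr
  }), class = "multiPhylo")
  cons <- majority_consensus(sample, threshold = 0.5)
  # recount every consensus clade's frequency in the input sample
  cons_parts <- ape::prop.part(cons)
  labs <- attr(cons_parts, "labels")
  for (cl in cons_parts) {
    clade <- sort(labs[cl])
    if (length(clade) %in% c(1L, 12L)) next
    hits <- vapply(sample, function(tr) {
      pp <- ape::prop.part(tr)
      any(vapply(pp, function(p)
        identical(sort(attr(pp, "labels")[p]), clade), logical(1)))
    }, logical(1))
    expect_gt(mean(hits), 0.5)
  }
  shuffled <- structure(sample[c(4, 9, 1, 7, 2, 6, 3, 8, 5)],
                        class = "multiPhylo")
  cons2 <- majority_consensus(shuffled, threshold = 0.5)
  expect_true(ape::all.equal.phylo(cons, cons2))
})

test_that("consensus topology agrees with the ape reference implementation", {
  set.seed(77)
  sample <- structure(lapply(1:7, function(i)
    simulate_yule_tree(10, 1, seed = 200 + (i %% 4))), class = "multiPhylo")
  cons <- majority_consensus(sample, threshold = 0.5)
  ref <- ape::consensus(sample, p = 0.5, rooted = TRUE)
  expect_true(ape::all.equal.phylo(cons, ref, use.edge.length = FALSE))
})

test_that("consensus rejects empty samples and bad thresholds", {
  expect_error(majority_consensus(structure(list(), class = "multiPhylo")),
               "empty")
  expect_error(majority_consensus(c(quartet("AB")), threshold = 0.3),
               "0.5")
})

test_that("VCV matrix matches hand computation and star/ultrametric identities", {
  C <- vcv_matrix(tree_abc())
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  Cs <- vcv_matrix(tree_star(6, len = 2.5))
  expect_equal(unname(Cs), diag(2.5, 6))
  tr <- simulate_yule_tree(16, 1, seed = 4)
  expect_equal(unname(diag(vcv_matrix(tr))), rep(max(ape::node.depth.edgelength(tr)), 16),
               tolerance = 1e-10)
  expect_error(vcv_matrix(ape::rtree(4, br = NULL)), "branch lengths")
})

test_that("patristic distances match hand computation and the VCV identity", {
  D <- patristic_distances(tree_abc())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(unname(diag(D)), rep(0, 3))
  for (seed in 1:5) {
    tr <- simulate_yule_tree(12, 1, seed = seed)
    C <- vcv_matrix(tr)
    D <- patristic_distances(tr)
    expect_equal(D, outer(diag(C), diag(C), "+") - 2 * C, tolerance = 1e-10)
  }
  # collapsing a zero-length internal edge leaves distances unchanged
  t1 <- ape::read.tree(text = "(((A:1,B:1):0,C:1):1,D:2);")
  t2 <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_equal(patristic_distances(t1)[c("A", "B", "C", "D"), c("A", "B", "C", "D")],
               patristic_distances(t2)[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
})
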