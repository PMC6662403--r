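#' Simulate a Yule (pure-birth) tree
#'
#' Grows a tree from a root with two lineages: while `k` lineages are alive
#' the next speciation occurs after an Exponential(k * birth_rate) waiting
#' time on a uniformly chosen lineage. Growth stops with `n_tips` lineages
#' after one further Exponential(n_tips * birth_rate) waiting time (the tree
#' is sampled just before the next speciation), so the expected root-to-tip
#' depth is \eqn{\sum_{k=2}^{n} 1/(k\lambda)}. The result is ultrametric and
#' binary, with `n_tips - 1` internal nodes.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate lambda (> 0; default 1).
#' @param seed integer seed; the tree is deterministic given it.
#' @param tip_prefix prefix for tip labels (default `"t"`, giving
#'   `t1 ... tn`).
#' @return a rooted, ultrametric, binary `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_prefix = "t") {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  # node ids: tips 1..n, internals n+1 (root) .. 2n-1, allocated in order
  # of speciation; edge length = child node time - parent node time
  max_nodes <- 2L * n - 1L
  parent <- integer(max_nodes)
  node_time <- numeric(max_nodes)
  root <- n + 1L
  next_internal <- n + 2L
  next_tip <- 3L  # tips 1 and 2 are the root's initial lineages
  alive <- c(1L, 2L)
  parent[1L] <- parent[2L] <- root
  node_time[root] <- 0
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
    split_i <- alive[sample.int(k, 1L)]
    # a new internal node replaces the split lineage at time t_now; the
    # lineage's tip id is reused for one child, one fresh tip id appears
    nd <- next_internal; next_internal <- next_internal + 1L
    tip_new <- next_tip; next_tip <- next_tip + 1L
    parent[nd] <- parent[split_i]
    node_time[nd] <- t_now
    parent[split_i] <- nd
    parent[tip_new] <- nd
    alive <- c(alive[alive != split_i], split_i, tip_new)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1L, rate = n * birth_rate)
  node_time[seq_len(n)] <- t_end
  child_ids <- setdiff(seq_len(max_nodes), root)
  edge <- cbind(parent[child_ids], child_ids)
  edge_len <- node_time[child_ids] - node_time[parent[child_ids]]
  tr <- structure(list(
    edge = edge, edge.length = edge_len, Nnode = n - 1L,
    tip.label = paste0(tip_prefix, seq_len(n))), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a trait under Brownian motion on a tree
#'
#' Starting from value 0 at the root, each node's value is its parent's
#' value plus a Normal(0, sigma2 * edge_length) increment, so the tip vector
#' has covariance `sigma2 * C` with `C` the phylogenetic VCV matrix.
#'
#' @param tree a rooted `phylo` with non-negative branch lengths.
#' @param sigma2 Brownian rate: trait variance accrued per unit branch
#'   length (> 0; default 1).
#' @param seed integer seed; deterministic given it.
#' @return named numeric vector of tip values in `tree$tip.label` order.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  val <- numeric(n + tr$Nnode)
  inc <- stats::rnorm(nrow(tr$edge), mean = 0,
                      sd = sqrt(sigma2 * tr$edge.length))
  for (k in seq_len(nrow(tr$edge))) {
    val[tr$edge[k, 2L]] <- val[tr$edge[k, 1L]] + inc[k]
  }
  stats::setNames(val[seq_len(n)], tr$tip.label)
}

#' Simulate a binary species-by-trait table with a specialization gradient
#'
#' For each species and bundle, the number of used categories `m` is drawn
#' as `1 + Binomial(n_traits - 1, 1 - specialization)` and the `m` ones are
#' placed uniformly at random among the bundle's columns. The two anchors
#' are exact: `specialization = 1` gives one-hot rows (corrected Gini 1 for
#' every species) and `specialization = 0` gives all-ones rows (Gini 0);
#' between them the expected Gini increases monotonically with the target
#' level. Rows always contain at least one 1, so generated tables pass
#' [validate_trait_table()].
#'
#' @param n_species number of species (>= 4).
#' @param bundle_spec named list: bundle name -> list(n_traits, specialization)
#'   with `n_traits >= 2` and `specialization` in `[0, 1]`.
#' @param seed integer seed; deterministic given it.
#' @param species_prefix prefix for species ids (default `"sp"`).
#' @return a [trait_table()].
#' @export
simulate_trait_table <- function(n_species, bundle_spec, seed = NULL,
                                 species_prefix = "sp") {
  if (n_species < 4L) stop("need at least 4 species", call. = FALSE)
  if (!length(bundle_spec) || is.null(names(bundle_spec))) {
    stop("bundle_spec must be a named list", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  species <- paste0(species_prefix, seq_len(n_species))
  blocks <- list()
  cfg <- list()
  for (bn in names(bundle_spec)) {
    sp <- bundle_spec[[bn]]
    nt <- as.integer(sp$n_traits)
    s <- sp$specialization
    if (is.null(nt) || nt < 2L) stop("bundle '", bn, "': n_traits >= 2 required",
                                     call. = FALSE)
    if (is.null(s) || s < 0 || s > 1) stop("bundle '", bn,
                                           "': specialization in [0, 1] required",
                                           call. = FALSE)
    cols <- paste0(bn, "_", seq_len(nt))
    m <- matrix(0L, n_species, nt, dimnames = list(species, cols))
    n_ones <- 1L + stats::rbinom(n_species, nt - 1L, 1 - s)
    for (i in seq_len(n_species)) {
      m[i, sample.int(nt, n_ones[i])] <- 1L
    }
    blocks[[bn]] <- m
    cfg[[bn]] <- cols
  }
  trait_table(do.call(cbind, blocks), bundle_config(cfg))
}
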