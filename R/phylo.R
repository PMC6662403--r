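#' Read a sample of phylogenetic trees
#'
#' Reads one or more trees from a Newick file (one tree per line or
#' semicolon-separated) or a Nexus file with a TREES block, normalizes tip
#' labels (whitespace trimmed, spaces converted to underscores), and checks
#' that all trees share one tip set. Trees are taken as rooted as written;
#' no rerooting is performed.
#'
#' @param path path to the tree file.
#' @return a `multiPhylo` object (ape); length >= 1.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(trees)) stop("could not parse any tree from ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- normalize_species_labels(tr$tip.label)
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicated tip labels in a tree in ", path, call. = FALSE)
    }
    tr
  })
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      extra <- setdiff(tips, ref)
      missing <- setdiff(ref, tips)
      stop(sprintf(
        "tree %d has a different tip set (only in tree %d: %s; missing: %s)",
        i, i,
        if (length(extra)) paste(extra, collapse = ", ") else "-",
        if (length(missing)) paste(missing, collapse = ", ") else "-"),
        call. = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  trees
}

# Clade table of one rooted tree: for every internal node except the root,
# the sorted tip-label key of its descendant clade and the length of the
# edge above it. Pendant edge lengths are returned per tip label.
tree_clades <- function(tr) {
  n <- length(tr$tip.label)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  root <- n + 1L
  # descendant tips of every node by postorder accumulation
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  edge_above <- integer(n + tr$Nnode)
  edge_above[tr$edge[, 2L]] <- seq_len(nrow(tr$edge))
  internal <- setdiff(seq.int(n + 1L, n + tr$Nnode), root)
  keys <- vapply(internal, function(nd) {
    paste(sort(tr$tip.label[desc[[nd]]]), collapse = "\r")
  }, character(1))
  lens <- tr$edge.length[edge_above[internal]]
  tip_len <- tr$edge.length[edge_above[seq_len(n)]]
  names(tip_len) <- tr$tip.label
  list(keys = keys, lens = lens, tip_len = tip_len)
}

#' Majority-rule consensus of a tree sample
#'
#' Builds the consensus tree containing exactly the clades whose frequency
#' across the sample strictly exceeds `threshold` (plus all tips). With the
#' default 50% rule the retained clades are guaranteed mutually compatible.
#' The branch length of a retained clade is the mean length of its
#' subtending edge over the trees that contain that clade; pendant (tip)
#' edges get the mean pendant length over all trees. Trees are treated as
#' rooted, so "splits" are clades (descendant tip sets).
#'
#' @param sample a `multiPhylo` from [read_trees()] (or any list of `phylo`
#'   over one tip set).
#' @param threshold clade frequency that must be strictly exceeded; in
#'   `[0.5, 1]` (default 0.5, the 50% majority rule).
#' @return a `phylo` consensus tree with branch lengths; internal nodes get
#'   `node.label` giving the clade's support frequency.
#' @export
majority_consensus <- function(sample, threshold = 0.5) {
  if (inherits(sample, "phylo")) sample <- c(sample)
  n_trees <- length(sample)
  if (n_trees < 1L) stop("empty tree sample", call. = FALSE)
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]", call. = FALSE)
  }
  tips <- sort(sample[[1L]]$tip.label)
  n <- length(tips)

  count <- new.env(parent = emptyenv())
  lensum <- new.env(parent = emptyenv())
  tip_sum <- stats::setNames(numeric(n), tips)
  for (tr in sample) {
    if (!setequal(tr$tip.label, tips)) {
      stop("trees in sample do not share one tip set", call. = FALSE)
    }
    cl <- tree_clades(tr)
    for (k in seq_along(cl$keys)) {
      key <- cl$keys[k]
      count[[key]] <- (if (is.null(count[[key]])) 0L else count[[key]]) + 1L
      lensum[[key]] <- (if (is.null(lensum[[key]])) 0 else lensum[[key]]) +
        cl$lens[k]
    }
    tip_sum <- tip_sum + cl$tip_len[tips]
  }

  keys <- ls(count)
  freq <- vapply(keys, function(k) count[[k]], integer(1)) / n_trees
  keep <- keys[freq > threshold]
  clade_tips <- lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  clade_len <- vapply(keep, function(k) lensum[[k]] / count[[k]], numeric(1))
  clade_freq <- freq[keep]
  # order retained clades by decreasing size; parents precede children
  ord <- order(-lengths(clade_tips))
  clade_tips <- clade_tips[ord]
  clade_len <- clade_len[ord]
  clade_freq <- clade_freq[ord]
  m <- length(clade_tips)

  # node ids: tips 1..n, root n+1, retained clades n+2 .. n+1+m
  clade_sets <- lapply(clade_tips, function(ct) match(ct, tips))
  parent_of <- integer(n + 1L + m)  # 0 = none (root)
  find_parent <- function(member_set) {
    # smallest retained clade strictly containing member_set; clades are
    # sorted by decreasing size so the last hit is the smallest
    best <- n + 1L
    for (j in seq_len(m)) {
      if (length(clade_sets[[j]]) > length(member_set) &&
          all(member_set %in% clade_sets[[j]])) best <- n + 1L + j
    }
    best
  }
  for (i in seq_len(n)) parent_of[i] <- find_parent(i)
  if (m) for (j in seq_len(m)) {
    parent_of[n + 1L + j] <- find_parent(clade_sets[[j]])
  }

  children <- split(seq_len(n + 1L + m)[-(n + 1L)],
                    parent_of[-(n + 1L)])
  edge <- matrix(0L, n + m, 2L)
  edge_len <- numeric(n + m)
  row <- 0L
  stack <- n + 1L
  while (length(stack)) {  # preorder
    nd <- stack[1L]; stack <- stack[-1L]
    ch <- children[[as.character(nd)]]
    for (c_ in ch) {
      row <- row + 1L
      edge[row, ] <- c(nd, c_)
      edge_len[row] <- if (c_ <= n) tip_sum[c_] / n_trees else
        clade_len[c_ - n - 1L]
      if (c_ > n) stack <- c(c_, stack)
    }
  }
  cons <- structure(list(
    edge = edge, edge.length = edge_len, Nnode = m + 1L, tip.label = tips,
    node.label = c("", formatC(clade_freq, digits = 3, format = "f"))),
    class = "phylo")
  cons <- ape::reorder.phylo(cons, "cladewise")
  cons
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry `C[i, j]` is the shared root-to-tip path length of tips i and j
#' (the depth of their most recent common ancestor); the diagonal holds
#' root-to-tip depths. Under Brownian motion with rate `sigma2` the trait
#' covariance across tips is `sigma2 * C`. Polytomies are handled as-is.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric positive-semidefinite matrix with tip labels as
#'   dimnames, rows/columns in `tree$tip.label` order.
#' @export
vcv_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Patristic distance matrix
#'
#' `D[i, j]` is the sum of branch lengths on the path between tips i and j.
#' For a rooted tree with VCV matrix `C`, `D = diag(C) 1' + 1 diag(C)' - 2C`.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}
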