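# Independent brute-force oracles and small fixture builders, kept free of
# the package's own shortcuts so they can arbitrate its output.

# Gini by the literal double sum G = sum_ij |x_i - x_j| / (2 n^2 mean(x))
gini_bruteforce <- function(x, corrected = FALSE) {
  n <- length(x)
  g <- sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  if (corrected) g * n / (n - 1) else g
}

# Moran's I by explicit double loop
morans_i_bruteforce <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# fixed small trees used across tests
tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree_star <- function(n = 8, len = 1) {
  ape::read.tree(text = paste0(
    "(", paste0("s", seq_len(n), ":", len, collapse = ","), ");"))
}

# a quartet tree sample over A-D with controllable topology mix
quartet <- function(split = c("AB", "AC"), bl = 1) {
  txt <- switch(match.arg(split),
    AB = sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);", bl, bl, bl, bl, bl, bl),
    AC = sprintf("((A:%g,C:%g):%g,(B:%g,D:%g):%g);", bl, bl, bl, bl, bl, bl))
  ape::read.tree(text = txt)
}

# binary trait matrix with named species rows; columns named after the
# bundle config's trait list, in order
binary_table <- function(rows, bundles) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("sp", seq_len(nrow(m)))
  colnames(m) <- unlist(bundles, use.names = FALSE)
  trait_table(m, bundles)
}
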