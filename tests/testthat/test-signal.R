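test_that("K and K* equal exactly 1 on a star tree (C = I) for any trait", {
  star <- tree_star(10, len = 1)
  C <- vcv_matrix(star)
  set.seed(1)
  for (i in 1:10) {
    x <- setNames(rnorm(10), star$tip.label)
    res <- blomberg_k(x, C)
    expect_equal(res$K, 1, tolerance = 1e-10)
    expect_equal(res$K_star, 1, tolerance = 1e-10)
    expect_equal(res$expected_ratio, 1, tolerance = 1e-12)
  }
})

test_that("K agrees with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(8)
  for (i in 1:8) {
    tr <- simulate_yule_tree(20, 1, seed = 300 + i)
    x <- simulate_bm_traits(tr, 1, seed = 400 + i)
    C <- vcv_matrix(tr)
    expect_equal(blomberg_k(x, C)$K,
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant to affine trait transforms and branch rescaling", {
  tr <- simulate_yule_tree(24, 1, seed = 15)
  x <- simulate_bm_traits(tr, 1, seed = 16)
  C <- vcv_matrix(tr)
  base <- blomberg_k(x, C)
  shifted <- blomberg_k(-2.5 * x + 7, C)
  expect_equal(shifted$K, base$K, tolerance = 1e-10)
  expect_equal(shifted$K_star, base$K_star, tolerance = 1e-10)
  rescaled <- blomberg_k(x, 13 * C)
  expect_equal(rescaled$K, base$K, tolerance = 1e-10)
  expect_equal(rescaled$K_star, base$K_star, tolerance = 1e-10)
})

test_that("constant traits are flagged degenerate; mismatched labels error", {
  tr <- simulate_yule_tree(8, 1, seed = 2)
  C <- vcv_matrix(tr)
  res <- blomberg_k(setNames(rep(1, 8), tr$tip.label), C)
  expect_true(res$degenerate)
  expect_identical(res$K, 0)
  expect_warning(
    p <- k_permutation_test(setNames(rep(1, 8), tr$tip.label), C, 99, 1),
    "constant")
  expect_identical(p$p_K, 1)
  x_bad <- setNames(rnorm(8), paste0("z", 1:8))
  expect_error(blomberg_k(x_bad, C), "mismatch")
})

test_that("permutation test is deterministic given a seed", {
  tr <- simulate_yule_tree(16, 1, seed = 5)
  x <- simulate_bm_traits(tr, 1, seed = 6)
  C <- vcv_matrix(tr)
  a <- k_permutation_test(x, C, n_perm = 99, seed = 123)
  b <- k_permutation_test(x, C, n_perm = 99, seed = 123)
  expect_identical(a, b)
  expect_gte(a$p_K, 1 / 100)
  expect_error(k_permutation_test(x, C, n_perm = 10, seed = 1), "99")
})

test_that("Moran's I matches hand computations and the brute-force oracle", {
  x <- c(1, 1, -1, -1)
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
  expect_equal(morans_i(x, W), 1)
  W2 <- matrix(0, 4, 4); W2[1, 3] <- W2[3, 1] <- W2[2, 4] <- W2[4, 2] <- 1
  expect_equal(morans_i(x, W2), -1)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    xr <- rnorm(n)
    Wr <- matrix(runif(n * n), n, n); diag(Wr) <- 0
    expect_equal(morans_i(xr, Wr), morans_i_bruteforce(xr, Wr),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with the ape reference implementation", {
  # ape row-normalizes weights internally, so use a constant-row-sum W
  # (all ones off the diagonal), where row normalization is a pure rescale
  # that leaves Moran's I unchanged
  set.seed(33)
  n <- 15
  x <- rnorm(n)
  W <- matrix(1, n, n); diag(W) <- 0
  expect_equal(morans_i(x, W), ape::Moran.I(x, W)$observed, tolerance = 1e-10)
})

test_that("permutation-null mean of Moran's I is -1/(n-1)", {
  set.seed(55)
  n <- 12
  x <- rnorm(n)
  W <- matrix(rbinom(n * n, 1, 0.4), n, n); diag(W) <- 0
  sims <- replicate(10000, morans_i(sample(x), W))
  expect_lt(abs(mean(sims) - (-1 / (n - 1))), 3 * sd(sims) / sqrt(length(sims)))
})

test_that("Moran's I rejects degenerate input", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  expect_error(morans_i(c(2, 2, 2), W), "constant")
  expect_error(morans_i(c(1, 2, 3), matrix(0, 3, 3)), "all-zero")
  Wd <- W; Wd[1, 1] <- 1
  expect_error(morans_i(c(1, 2, 3), Wd), "diagonal")
})

test_that("correlogram is deterministic, well-shaped, and flags empty bins", {
  tr <- simulate_yule_tree(32, 1, seed = 61)
  x <- simulate_bm_traits(tr, 1, seed = 62)
  D <- patristic_distances(tr)
  a <- phylo_correlogram(x, D, n_classes = 5, n_boot = 50, seed = 9)
  b <- phylo_correlogram(x, D, n_classes = 5, n_boot = 50, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a), 5L)
  expect_true(all(a$ci_low <= a$ci_high, na.rm = TRUE))
  expect_true(all(a$significance %in% c("positive", "negative", "none")))
  expect_equal(sum(a$n_pairs), 32 * 31)
  # two tight clusters far apart leave middle distance classes empty
  tclust <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1):10,(b1:0.1,b2:0.1):10);"))
  Dc <- patristic_distances(tclust)
  xc <- setNames(c(1, 1.2, -1, -0.8), tclust$tip.label)
  expect_warning(cg <- phylo_correlogram(xc, Dc, n_classes = 4, n_boot = 20,
                                         seed = 1),
                 "empty distance class")
  expect_true(anyNA(cg$I))
})
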