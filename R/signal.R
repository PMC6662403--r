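#' Align a named trait vector with a VCV or distance matrix
#'
#' @param x named numeric vector (one value per tip).
#' @param M square matrix with tip labels as dimnames.
#' @return `x` reordered to the row order of `M`.
#' @noRd
align_trait <- function(x, M) {
  if (is.null(names(x))) {
    if (length(x) != nrow(M)) {
      stop("unnamed trait vector of wrong length (", length(x), " vs ",
           nrow(M), " tips)", call. = FALSE)
    }
    return(as.numeric(x))
  }
  nm <- normalize_species_labels(names(x))
  tips <- rownames(M)
  missing <- setdiff(tips, nm)
  extra <- setdiff(nm, tips)
  if (length(missing) || length(extra)) {
    stop("trait/tip label mismatch (missing from traits: ",
         if (length(missing)) paste(missing, collapse = ", ") else "-",
         "; not in tree: ",
         if (length(extra)) paste(extra, collapse = ", ") else "-", ")",
         call. = FALSE)
  }
  as.numeric(x[match(tips, nm)])
}

# Core K computation given x aligned to C. Returns the pieces shared by
# blomberg_k() and the permutation test.
k_stats <- function(x, C, Cinv = NULL) {
  n <- length(x)
  if (is.null(Cinv)) Cinv <- solve(C)
  ones <- rep(1, n)
  c1 <- Cinv %*% ones                    # C^-1 1
  s1 <- sum(c1)                          # 1' C^-1 1
  a_hat <- sum(c1 * x) / s1              # GLS phylogenetic mean
  r <- x - a_hat
  MSE <- drop(crossprod(r, Cinv %*% r)) / (n - 1)
  MSE0 <- sum(r^2) / (n - 1)             # centered on GLS mean (K)
  MSE0_star <- sum((x - mean(x))^2) / (n - 1)  # arithmetic mean (K*)
  expected_ratio <- (sum(diag(C)) - n / s1) / (n - 1)
  list(a_hat = a_hat, MSE = MSE, MSE0 = MSE0, MSE0_star = MSE0_star,
       expected_ratio = expected_ratio, Cinv = Cinv, c1 = c1, s1 = s1)
}

#' Blomberg's K and K* phylogenetic signal statistics
#'
#' K is a mean-square ratio: the numerator `MSE0` is the trait's error
#' ignoring phylogeny, the denominator `MSE` is the generalized
#' least-squares error given the phylogenetic covariance matrix `C`, and the
#' ratio is scaled by its expectation under Brownian motion so that K near 1
#' is consistent with Brownian evolution, K well below 1 indicates weak
#' signal, and K above 1 stronger-than-Brownian resemblance of relatives.
#' K centers the trait on the GLS phylogenetic mean; the companion K*
#' centers on the arithmetic mean. On an ultrametric star tree (`C`
#' proportional to the identity) both equal exactly 1 for any non-constant
#' trait.
#'
#' A constant trait vector has `MSE0 = 0`; K is returned as 0 and flagged
#' degenerate.
#'
#' @param x numeric trait vector, named by tip label (or unnamed, already in
#'   `rownames(C)` order).
#' @param C phylogenetic VCV matrix from [vcv_matrix()].
#' @return a list of class `"signal_result"`: `K`, `K_star`, `MSE0`, `MSE`,
#'   `expected_ratio`, `n`, `degenerate`; p-value fields are filled in by
#'   [k_permutation_test()].
#' @export
blomberg_k <- function(x, C) {
  x <- align_trait(x, C)
  n <- length(x)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips", call. = FALSE)
  Cinv <- tryCatch(solve(C), error = function(e) {
    stop("VCV matrix is singular (zero-length branches can cause this; ",
         "no jitter is applied automatically): ", conditionMessage(e),
         call. = FALSE)
  })
  st <- k_stats(x, C, Cinv)
  degenerate <- st$MSE0 == 0
  res <- list(
    K = if (degenerate) 0 else (st$MSE0 / st$MSE) / st$expected_ratio,
    K_star = if (degenerate) 0 else (st$MSE0_star / st$MSE) / st$expected_ratio,
    MSE0 = st$MSE0, MSE0_star = st$MSE0_star, MSE = st$MSE,
    expected_ratio = st$expected_ratio, n = n,
    degenerate = degenerate,
    p_K = NA_real_, p_K_star = NA_real_, n_permutations = NA_integer_,
    seed = NA_integer_)
  class(res) <- "signal_result"
  res
}

#' Permutation test for phylogenetic signal
#'
#' Randomly permutes trait values across tips and compares the observed GLS
#' mean-squared error with its permutation distribution. Real signal makes
#' the observed MSE small relative to random tip assignments, so the test is
#' one-tailed with p = (1 + #\{permutations with MSE <= observed\}) /
#' (n_perm + 1). The same MSE permutation distribution serves K and K*
#' (their numerators are invariant or near-invariant under permutation), so
#' one p-value is reported for each.
#'
#' @param x named numeric trait vector.
#' @param C phylogenetic VCV matrix.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed; the test is deterministic given it.
#' @return a `"signal_result"` as from [blomberg_k()] with `p_K`,
#'   `p_K_star`, `n_permutations` and `seed` filled in. A constant trait
#'   gives p = 1 with a warning.
#' @export
k_permutation_test <- function(x, C, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("use at least 99 permutations", call. = FALSE)
  res <- blomberg_k(x, C)
  res$n_permutations <- as.integer(n_perm)
  res$seed <- as.integer(seed)
  if (res$degenerate) {
    warning("constant trait vector: no signal testable, p = 1", call. = FALSE)
    res$p_K <- res$p_K_star <- 1
    return(res)
  }
  xa <- align_trait(x, C)
  n <- length(xa)
  Cinv <- solve(C)
  c1 <- Cinv %*% rep(1, n)
  s1 <- sum(c1)
  # MSE(x) = [x' Cinv x - (1' Cinv x)^2 / s1] / (n - 1); evaluate for all
  # permutations at once as matrix products
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(xa), numeric(n))
  Q <- Cinv %*% P
  mse_perm <- (colSums(P * Q) - drop(crossprod(c1, P))^2 / s1) / (n - 1)
  mse_obs <- res$MSE
  p <- (1 + sum(mse_perm <= mse_obs)) / (n_perm + 1)
  res$p_K <- res$p_K_star <- p
  res
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f, K* = %.4f (n = %d tips)\n",
              x$K, x$K_star, x$n))
  if (!is.na(x$p_K)) {
    cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
                x$p_K, x$n_permutations, x$seed))
  }
  if (isTRUE(x$degenerate)) cat("  [degenerate: constant trait]\n")
  invisible(x)
}

#' Moran's I autocorrelation statistic
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij} (x_i - \bar{x})(x_j - \bar{x})}
#'        {\sum_i (x_i - \bar{x})^2}}
#' Under the permutation null its expectation is `-1/(n-1)`.
#'
#' @param x numeric vector, not constant.
#' @param W non-negative weight matrix with zero diagonal, not all zero;
#'   typically an indicator of a patristic-distance class.
#' @return Moran's I (a single number).
#' @export
morans_i <- function(x, W) {
  x <- as.numeric(x)
  n <- length(x)
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n) {
    stop("W must be an n x n matrix", call. = FALSE)
  }
  if (any(W < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  s0 <- sum(W)
  if (s0 == 0) stop("all-zero weight matrix", call. = FALSE)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I undefined for a constant vector", call. = FALSE)
  (n / s0) * drop(crossprod(z, W %*% z)) / denom
}

#' Moran's I phylogenetic correlogram
#'
#' Partitions the range of patristic distances into `n_classes` equal-width
#' bins and computes Moran's I within each bin (weight 1 for tip pairs whose
#' distance falls in the bin, 0 otherwise). A 95% confidence interval per
#' bin comes from bootstrap resampling of tips with replacement (the
#' resampled indices are applied to both the trait vector and the distance
#' matrix; pairs formed by two copies of the same tip are dropped from the
#' weights). A bin is flagged as significant positive autocorrelation if its
#' CI lies entirely above the permutation-null expectation `-1/(n-1)`,
#' significant negative if entirely below, otherwise none.
#'
#' @param x named numeric trait vector.
#' @param D patristic distance matrix from [patristic_distances()].
#' @param n_classes number of distance classes (>= 2; default 10).
#' @param n_boot bootstrap replicates for the CI (default 100).
#' @param seed integer seed; output is deterministic given it.
#' @return a data frame of class `"correlogram"`: `class_low`, `class_high`,
#'   `class_mid`, `n_pairs`, `I`, `ci_low`, `ci_high`, `significance`; the
#'   null expectation and seed are attached as attributes. Empty bins get
#'   `NA` with a warning.
#' @export
phylo_correlogram <- function(x, D, n_classes = 10L, n_boot = 100L,
                              seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 distance classes", call. = FALSE)
  if (n_boot < 2L) stop("need at least 2 bootstrap replicates", call. = FALSE)
  xa <- align_trait(x, D)
  n <- length(xa)
  off <- D[upper.tri(D)]
  breaks <- seq(min(off), max(off), length.out = n_classes + 1L)
  # bin index per pair; values at the global min fall in bin 1
  bin_of <- function(dm) {
    b <- findInterval(dm, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    if (is.matrix(dm)) dim(b) <- dim(dm)
    b
  }
  class_I <- function(xv, dm, keep = NULL) {
    b <- bin_of(dm)
    vapply(seq_len(n_classes), function(k) {
      W <- (b == k) * 1
      diag(W) <- 0
      if (!is.null(keep)) W <- W * keep
      if (sum(W) == 0) return(NA_real_)
      morans_i(xv, W)
    }, numeric(1))
  }
  I_obs <- class_I(xa, D)
  if (anyNA(I_obs)) {
    warning("empty distance class(es): ",
            paste(which(is.na(I_obs)), collapse = ", "),
            "; Moran's I recorded as NA", call. = FALSE)
  }
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, n_classes)
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    keep <- 1 - outer(idx, idx, "==")  # drop duplicate-tip self pairs
    bx <- xa[idx]
    if (length(unique(bx)) == 1L) next  # degenerate resample, skip
    boot[bi, ] <- class_I(bx, D[idx, idx], keep = keep)
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  e_null <- -1 / (n - 1)
  sig <- ifelse(is.na(I_obs), NA_character_,
         ifelse(ci[1L, ] > e_null, "positive",
         ifelse(ci[2L, ] < e_null, "negative", "none")))
  out <- data.frame(
    class_low = breaks[-(n_classes + 1L)],
    class_high = breaks[-1L],
    class_mid = (breaks[-1L] + breaks[-(n_classes + 1L)]) / 2,
    n_pairs = vapply(seq_len(n_classes), function(k) {
      sum(bin_of(off) == k)
    }, numeric(1)) * 2,
    I = I_obs, ci_low = ci[1L, ], ci_high = ci[2L, ],
    significance = sig,
    stringsAsFactors = FALSE)
  structure(out, null_expectation = e_null, n_boot = as.integer(n_boot),
            seed = as.integer(seed),
            class = c("correlogram", "data.frame"))
}
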