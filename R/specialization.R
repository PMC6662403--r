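#' Gini coefficient of a non-negative vector
#'
#' Computes the Gini inequality coefficient
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar{x}}}
#' optionally with the small-sample bias correction `n/(n-1)`. Applied to a
#' binary trait vector within a bundle it measures how unevenly a species
#' uses the bundle's categories: a constant vector (perfectly even use)
#' gives 0, maximal generalism; a single 1 among zeros gives the corrected
#' maximum 1, perfect specialization. The uncorrected statistic is bounded
#' by `(n-1)/n`.
#'
#' Internally the double sum is evaluated through the sorted-vector identity
#' \eqn{\sum_i\sum_j |x_i-x_j| = 2\sum_i (2i - n - 1) x_{(i)}}, which is
#' O(n log n); tests check it against the literal double loop.
#'
#' @param x numeric vector, all values >= 0, at least one positive.
#' @param corrected multiply by `n/(n-1)` so the maximum is exactly 1
#'   (default `TRUE`).
#' @return the Gini coefficient, a number in `[0, 1]`.
#' @export
#' @examples
#' gini(c(1, 0, 0, 0, 0, 0, 0, 0, 0))            # 1: perfect specialist
#' gini(rep(1, 9))                               # 0: perfect generalist
#' gini(c(1, 1, 0, 0), corrected = FALSE)        # 0.5
gini <- function(x, corrected = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("gini needs at least 2 values", call. = FALSE)
  if (anyNA(x)) stop("gini input contains NA", call. = FALSE)
  if (any(x < 0)) stop("gini input must be non-negative", call. = FALSE)
  xbar <- mean(x)
  if (xbar == 0) {
    stop("gini undefined for a zero-mean vector (denominator 2*n^2*mean is 0)",
         call. = FALSE)
  }
  xs <- sort(x)
  g <- 2 * sum((2 * seq_len(n) - n - 1) * xs) / (2 * n^2 * xbar)
  if (corrected) g <- g * n / (n - 1)
  g
}

#' Per-bundle specialization indices for every species
#'
#' Applies [gini()] to each species' trait row within each bundle, yielding
#' one specialization index per species per bundle (e.g. diet specialism,
#' habitat specialism, ...).
#'
#' @param t a [trait_table()]; must pass [validate_trait_table()] (no
#'   all-zero rows within a bundle).
#' @param corrected passed to [gini()] (default `TRUE`).
#' @return a data frame of class `"specialization_profile"`: column
#'   `species`, then one numeric column per bundle.
#' @export
bundle_indices <- function(t, corrected = TRUE) {
  stopifnot(inherits(t, "trait_table"))
  b <- bundles(t)
  out <- data.frame(species = rownames(t), stringsAsFactors = FALSE)
  for (bn in names(b)) {
    sub <- unclass(t)[, b[[bn]], drop = FALSE]
    out[[bn]] <- vapply(seq_len(nrow(sub)), function(i) {
      tryCatch(gini(sub[i, ], corrected = corrected),
               error = function(e) stop(sprintf(
                 "species '%s', bundle '%s': %s",
                 rownames(t)[i], bn, conditionMessage(e)), call. = FALSE))
    }, numeric(1))
  }
  structure(out, bundle_names = names(b),
            class = c("specialization_profile", "data.frame"))
}

bundle_names_of <- function(profiles) {
  bn <- attr(profiles, "bundle_names")
  if (is.null(bn)) {
    bn <- setdiff(names(profiles),
                  c("species", "overall_mean", "overall_max", "overall_min"))
  }
  bn
}

#' Overall specialization index
#'
#' Aggregates the per-bundle indices of each species (mean, max or min) and
#' min-max standardizes the aggregate across species to `[0, 1]`, so the
#' least specialized species scores exactly 0 (generalist) and the most
#' specialized exactly 1 (specialist). Each aggregator is standardized
#' separately across species.
#'
#' @param profiles output of [bundle_indices()].
#' @param bundles bundle names to aggregate over; defaults to all bundles in
#'   `profiles`. Dropping a bundle that duplicates another (e.g. a second,
#'   strongly correlated diet index) is done here.
#' @param aggregator one of `"mean"`, `"max"`, `"min"`.
#' @return `profiles` with an added column `overall_<aggregator>` in `[0, 1]`.
#' @export
overall_index <- function(profiles, bundles = NULL,
                          aggregator = c("mean", "max", "min")) {
  aggregator <- match.arg(aggregator)
  bn <- if (is.null(bundles)) bundle_names_of(profiles) else bundles
  missing <- setdiff(bn, names(profiles))
  if (length(missing)) {
    stop("profiles lack bundle(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) < 2L) {
    stop("overall index needs at least 2 species", call. = FALSE)
  }
  m <- as.matrix(profiles[, bn, drop = FALSE])
  agg <- switch(aggregator,
                mean = rowMeans(m),
                max = apply(m, 1L, max),
                min = apply(m, 1L, min))
  rng <- range(agg)
  if (rng[1] == rng[2]) {
    stop("all per-species aggregates identical; standardization degenerate",
         call. = FALSE)
  }
  profiles[[paste0("overall_", aggregator)]] <- (agg - rng[1]) / (rng[2] - rng[1])
  profiles
}

#' Classify species as specialists or generalists
#'
#' Labels each species `"specialist"` if its index for `bundle` is at least
#' `threshold`, `"generalist"` otherwise. No default threshold is provided:
#' the cutoff is a study-level choice, not a property of the index.
#'
#' @param profiles output of [bundle_indices()] (possibly with overall
#'   columns added).
#' @param bundle name of the index column to classify on (a bundle name or
#'   e.g. `"overall_mean"`).
#' @param threshold number in `(0, 1)`; specialist iff index >= threshold.
#' @return a list with `labels` (named character vector per species) and
#'   `counts` (named integer vector over the two labels).
#' @export
classify <- function(profiles, bundle, threshold) {
  if (!bundle %in% names(profiles)) {
    stop("unknown bundle or index column: ", bundle, call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  idx <- profiles[[bundle]]
  labels <- ifelse(idx >= threshold, "specialist", "generalist")
  names(labels) <- profiles$species
  counts <- c(specialist = sum(labels == "specialist"),
              generalist = sum(labels == "generalist"))
  list(labels = labels, counts = counts)
}

#' Correlations and normality of the specialization indices
#'
#' For each index a Shapiro-Wilk normality test is run; indices in ecological
#' trait data are typically non-normal, so associations between indices are
#' measured with Spearman rank correlations. P-values are two-sided: exact
#' for n <= 10 (the exact null distribution of the rank statistic, equivalent
#' to full permutation when there are no ties), t-approximation otherwise.
#'
#' @param profiles output of [bundle_indices()].
#' @param columns index columns to correlate; defaults to all bundles.
#' @return a list of class `"index_correlations"` with `bundle_names`,
#'   matrices `rho` and `p` (Spearman), and `normality_p` (Shapiro-Wilk per
#'   index). A constant index yields `NA` correlations with a warning.
#' @export
index_correlations <- function(profiles, columns = NULL) {
  bn <- if (is.null(columns)) bundle_names_of(profiles) else columns
  if (nrow(profiles) < 4L) {
    stop("correlation analysis needs at least 4 species", call. = FALSE)
  }
  k <- length(bn)
  rho <- matrix(NA_real_, k, k, dimnames = list(bn, bn))
  p <- matrix(NA_real_, k, k, dimnames = list(bn, bn))
  diag(rho) <- 1; diag(p) <- 0
  exact <- nrow(profiles) <= 10L
  constant <- vapply(bn, function(b) length(unique(profiles[[b]])) == 1L,
                     logical(1))
  if (any(constant)) {
    warning("constant index vector(s): ",
            paste(bn[constant], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    if (constant[i] || constant[j]) next
    ct <- suppressWarnings(
      stats::cor.test(profiles[[bn[i]]], profiles[[bn[j]]],
                      method = "spearman", exact = exact))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  normality_p <- vapply(bn, function(b) {
    x <- profiles[[b]]
    if (length(unique(x)) == 1L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  structure(list(bundle_names = bn, rho = rho, p = p,
                 normality_p = normality_p),
            class = "index_correlations")
}

#' @export
print.index_correlations <- function(x, ...) {
  cat("Spearman correlations among", length(x$bundle_names),
      "specialization indices\n")
  print(round(x$rho, 3))
  cat("Shapiro-Wilk normality p-values:\n")
  print(signif(x$normality_p, 3))
  invisible(x)
}
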