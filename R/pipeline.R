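#' Run the full specialization / phylogenetic-signal pipeline
#'
#' Orchestrates the end-to-end analysis: read and validate the binary trait
#' table, compute per-bundle Gini specialization indices and the overall
#' index, the inter-index correlation matrix, the majority-rule consensus
#' of the tree sample, Blomberg's K / K* with permutation p-values for every
#' index on the consensus tree, and a Moran's I correlogram per index.
#' Species present in the tree sample but absent from the trait table are
#' pruned with a warning (trait coverage defines the study set); species in
#' the traits but missing from the trees abort the run.
#'
#' Outputs written to `out_dir`: `indices.csv`, `correlations.csv`,
#' `consensus.nwk`, `signal.json`, `correlogram.tsv` and `manifest.json`
#' (input hashes, package version, seed, parameters). Given fixed inputs,
#' parameters and seed the outputs are byte-identical across runs.
#'
#' @param traits path to the trait CSV (see [read_trait_table()]).
#' @param bundles_cfg path to the YAML/JSON bundle config, or a
#'   [bundle_config()].
#' @param trees path to the Newick/Nexus tree sample.
#' @param out_dir output directory, created if absent.
#' @param corrected use the bias-corrected Gini (default `TRUE`).
#' @param aggregator aggregator for the overall index (default `"mean"`).
#' @param overall_bundles bundles entering the overall index; default all.
#' @param consensus_threshold majority-rule threshold (default 0.5).
#' @param n_perm permutations for the K test (default 999).
#' @param n_classes correlogram distance classes (default 10).
#' @param n_boot correlogram bootstraps (default 100).
#' @param threshold optional classification cutoff in (0, 1); if given,
#'   specialist/generalist counts per index are added to the manifest.
#' @param seed integer master seed recorded in all stochastic outputs.
#' @return (invisibly) a list with the computed objects and output paths.
#' @export
run_pipeline <- function(traits, bundles_cfg, trees, out_dir,
                         corrected = TRUE, aggregator = "mean",
                         overall_bundles = NULL,
                         consensus_threshold = 0.5,
                         n_perm = 999L, n_classes = 10L, n_boot = 100L,
                         threshold = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- if (inherits(traits, "trait_table")) traits else
    read_trait_table(traits, bundles_cfg)
  rep <- validate_trait_table(tab)
  if (!rep$ok) {
    stop("trait table failed validation:\n  ",
         paste(rep$issues$message[rep$issues$severity == "error"],
               collapse = "\n  "), call. = FALSE)
  }

  sample <- if (inherits(trees, c("multiPhylo", "phylo"))) {
    if (inherits(trees, "phylo")) c(trees) else trees
  } else read_trees(trees)
  tree_tips <- sample[[1L]]$tip.label
  sp <- rownames(tab)
  absent <- setdiff(sp, tree_tips)
  if (length(absent)) {
    stop("species in trait table but not in trees: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  drop <- setdiff(tree_tips, sp)
  if (length(drop)) {
    warning("pruning ", length(drop),
            " tree tip(s) without trait data: ",
            paste(utils::head(drop, 10L), collapse = ", "),
            if (length(drop) > 10L) ", ..." else "", call. = FALSE)
    sample <- structure(lapply(sample, ape::drop.tip, tip = drop),
                        class = "multiPhylo")
  }

  profiles <- bundle_indices(tab, corrected = corrected)
  profiles <- overall_index(profiles, bundles = overall_bundles,
                            aggregator = aggregator)
  idx_cols <- c(bundle_names_of(profiles), paste0("overall_", aggregator))
  corr <- index_correlations(profiles)

  cons <- majority_consensus(sample, threshold = consensus_threshold)
  C <- vcv_matrix(cons)
  D <- patristic_distances(cons)

  signal <- lapply(idx_cols, function(cl) {
    x <- stats::setNames(profiles[[cl]], profiles$species)
    k_permutation_test(x, C, n_perm = n_perm, seed = seed)
  })
  names(signal) <- idx_cols
  correlograms <- lapply(idx_cols, function(cl) {
    x <- stats::setNames(profiles[[cl]], profiles$species)
    phylo_correlogram(x, D, n_classes = n_classes, n_boot = n_boot,
                      seed = seed)
  })
  names(correlograms) <- idx_cols

  # ---- outputs -------------------------------------------------------
  p_indices <- file.path(out_dir, "indices.csv")
  utils::write.csv(profiles, p_indices, row.names = FALSE, quote = FALSE)

  p_corr <- file.path(out_dir, "correlations.csv")
  corr_df <- data.frame(index = rownames(corr$rho), corr$rho,
                        check.names = FALSE, row.names = NULL)
  utils::write.csv(corr_df, p_corr, row.names = FALSE, quote = FALSE)

  p_cons <- file.path(out_dir, "consensus.nwk")
  ape::write.tree(cons, p_cons)

  p_signal <- file.path(out_dir, "signal.json")
  jsonlite::write_json(lapply(signal, function(s) {
    s[c("K", "K_star", "p_K", "p_K_star", "MSE0", "MSE",
        "expected_ratio", "n", "n_permutations", "seed")]
  }), p_signal, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  p_cgram <- file.path(out_dir, "correlogram.tsv")
  cg <- do.call(rbind, lapply(names(correlograms), function(cl) {
    data.frame(index = cl, as.data.frame(correlograms[[cl]]))
  }))
  utils::write.table(cg, p_cgram, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  classification <- NULL
  if (!is.null(threshold)) {
    classification <- lapply(idx_cols, function(cl) {
      as.list(classify(profiles, cl, threshold)$counts)
    })
    names(classification) <- idx_cols
  }

  manifest <- list(
    package = "ecospec",
    version = as.character(utils::packageVersion("ecospec")),
    seed = as.integer(seed),
    parameters = list(corrected = corrected, aggregator = aggregator,
                      consensus_threshold = consensus_threshold,
                      n_perm = as.integer(n_perm),
                      n_classes = as.integer(n_classes),
                      n_boot = as.integer(n_boot),
                      threshold = threshold),
    inputs = list(
      traits = if (is.character(traits))
        list(path = traits, md5 = unname(tools::md5sum(traits))) else "in-memory",
      trees = if (is.character(trees))
        list(path = trees, md5 = unname(tools::md5sum(trees))) else "in-memory"),
    n_species = nrow(tab), n_trees = length(sample),
    indices = idx_cols,
    classification = classification,
    outputs = basename(c(p_indices, p_corr, p_cons, p_signal, p_cgram)))
  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  invisible(list(profiles = profiles, correlations = corr, consensus = cons,
                 signal = signal, correlograms = correlograms,
                 classification = classification,
                 paths = c(indices = p_indices, correlations = p_corr,
                           consensus = p_cons, signal = p_signal,
                           correlogram = p_cgram, manifest = p_manifest)))
}
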