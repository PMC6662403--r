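#' Normalize species labels for matching against tree tip labels
#'
#' Trims surrounding whitespace and converts internal spaces to underscores,
#' the Newick convention used by most phylogeny repositories. Matching between
#' trait tables and trees is by exact string equality after this normalization,
#' so `"Parus major"` and `"Parus_major"` refer to the same species.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_species_labels(c("  Parus major ", "Sitta_europaea"))
normalize_species_labels <- function(x) {
  x <- trimws(as.character(x))
  gsub(" ", "_", x, fixed = TRUE)
}

#' Read a bundle configuration from YAML or JSON
#'
#' A bundle configuration maps bundle names (e.g. `diet`, `habitat`) to the
#' ordered list of binary trait columns that make up that bundle. One
#' specialization index is later computed per bundle.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top level is a
#'   mapping from bundle name to a list of column names.
#' @return a named list of character vectors, validated as a bundle config.
#' @export
read_bundle_config <- function(path) {
  if (!file.exists(path)) {
    stop("bundle config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported bundle config format '", ext, "' (use YAML or JSON)",
         call. = FALSE)
  )
  cfg <- lapply(cfg, as.character)
  bundle_config(cfg)
}

#' Construct and validate a bundle configuration
#'
#' @param entries named list: bundle name -> character vector of trait columns.
#' @return the validated named list, classed `"bundle_config"`.
#' @export
bundle_config <- function(entries) {
  if (!is.list(entries) || length(entries) == 0L) {
    stop("bundle config must be a non-empty named list", call. = FALSE)
  }
  nm <- names(entries)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every bundle must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicated bundle names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  all_cols <- unlist(entries, use.names = FALSE)
  if (any(!nzchar(all_cols))) {
    stop("empty trait column name in bundle config", call. = FALSE)
  }
  if (anyDuplicated(all_cols)) {
    stop("trait column assigned to more than one bundle: ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(entries)
  if (any(sizes < 2L)) {
    stop("every bundle needs at least 2 traits; too small: ",
         paste(nm[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  structure(entries, class = "bundle_config")
}

#' Construct a species-by-trait table partitioned into bundles
#'
#' @param values numeric matrix of 0/1 values, species in rows, traits in
#'   columns; `rownames` are species ids, `colnames` are trait names.
#' @param bundles a [bundle_config()] (or a plain named list coerced to one)
#'   whose column names all appear in `colnames(values)`.
#' @return an object of class `"trait_table"`: the 0/1 matrix with a
#'   `bundles` attribute.
#' @export
trait_table <- function(values, bundles) {
  if (!inherits(bundles, "bundle_config")) bundles <- bundle_config(bundles)
  values <- as.matrix(values)
  species <- rownames(values)
  if (is.null(species) || any(!nzchar(species))) {
    stop("trait table needs species ids as row names", call. = FALSE)
  }
  species <- normalize_species_labels(species)
  if (anyDuplicated(species)) {
    stop("duplicated species ids: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(values) <- species
  cols <- unlist(bundles, use.names = FALSE)
  missing <- setdiff(cols, colnames(values))
  if (length(missing)) {
    stop("trait columns named in bundle config but absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- values[, cols, drop = FALSE]
  bad <- which(!(values == 0 | values == 1) | is.na(values), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-binary cell at species '%s', column '%s': %s (all traits must be 0 or 1)",
      rownames(values)[i], colnames(values)[j],
      format(values[i, j])), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  structure(values, bundles = bundles, class = c("trait_table", "matrix"))
}

#' Read a binary species-by-trait table from CSV
#'
#' The first column of the CSV is the species identifier; remaining columns
#' are binary (0/1) traits. Columns are restricted to those named in the
#' bundle configuration, in configuration order; row order is preserved.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param config a [bundle_config()] or path to a YAML/JSON bundle file.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, config) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  if (is.character(config) && length(config) == 1L) {
    config <- read_bundle_config(config)
  }
  if (!inherits(config, "bundle_config")) config <- bundle_config(config)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("trait CSV needs a species column plus traits",
                          call. = FALSE)
  species <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- species
  trait_table(m, config)
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_table()]: the species id column is written first,
#' then trait columns in bundle order, so a read/write round trip preserves
#' values exactly.
#'
#' @param t a [trait_table()].
#' @param path output CSV path.
#' @param species_col name for the species id column (default `"species"`).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(t, path, species_col = "species") {
  stopifnot(inherits(t, "trait_table"))
  df <- data.frame(rownames(t), unclass(t), check.names = FALSE,
                   row.names = NULL)
  names(df)[1L] <- species_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundles of a trait table
#' @param t a [trait_table()].
#' @return the `bundle_config` of `t`.
#' @export
bundles <- function(t) attr(t, "bundles")

#' Restrict a trait table to a subset of bundles
#' @param t a [trait_table()].
#' @param keep character vector of bundle names to retain.
#' @return a [trait_table()] over the retained bundles only.
#' @export
subset_bundles <- function(t, keep) {
  b <- bundles(t)
  unknown <- setdiff(keep, names(b))
  if (length(unknown)) {
    stop("unknown bundle(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  trait_table(unclass(t), bundle_config(b[keep]))
}

#' Validate a trait table for index computation
#'
#' A species whose trait row is all zero within a bundle has an undefined
#' Gini coefficient there (the denominator `2 * n^2 * mean(x)` vanishes), so
#' such rows are reported as errors. A trait column that is zero for every
#' species is only a warning: it carries no information but breaks nothing.
#'
#' @param t a [trait_table()].
#' @return a list of class `"validation_report"` with elements `ok` (logical)
#'   and `issues` (data frame: severity, where, message). `ok` is `TRUE` iff
#'   no issue has severity `"error"`.
#' @export
validate_trait_table <- function(t) {
  stopifnot(inherits(t, "trait_table"))
  b <- bundles(t)
  issues <- list()
  for (bn in names(b)) {
    sub <- unclass(t)[, b[[bn]], drop = FALSE]
    zero_rows <- rownames(t)[rowSums(sub) == 0L]
    for (sp in zero_rows) {
      issues[[length(issues) + 1L]] <- data.frame(
        severity = "error", where = sprintf("%s/%s", sp, bn),
        message = sprintf(
          "species '%s' has all-zero traits in bundle '%s'; Gini undefined (zero mean)",
          sp, bn))
    }
    zero_cols <- b[[bn]][colSums(sub) == 0L]
    for (cl in zero_cols) {
      issues[[length(issues) + 1L]] <- data.frame(
        severity = "warning", where = sprintf("column %s", cl),
        message = sprintf("trait '%s' is zero for all species", cl))
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), where = character(),
               message = character())
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "OK" else "INVALID", "-", nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s\n", x$issues$severity[i], x$issues$message[i]))
    }
  }
  invisible(x)
}

#' @export
print.trait_table <- function(x, ...) {
  b <- bundles(x)
  cat(sprintf("trait_table: %d species x %d binary traits in %d bundle(s)\n",
              nrow(x), ncol(x), length(b)))
  cat("  bundles:", paste(sprintf("%s(%d)", names(b), lengths(b)),
                          collapse = ", "), "\n")
  invisible(x)
}
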