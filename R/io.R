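## Readers/writers for connectivity matrices, node tables, cohort manifests
## and result tables. All tables are delimited text (CSV/TSV); matrices are
## written at full double precision so cohorts round-trip bit-identically.

GROUP_LEVELS <- c("LLD-MD", "LLD-IM", "HC")

#' Validate a connectivity matrix
#'
#' A connectivity matrix is a symmetric, zero-diagonal, nonnegative weighted
#' adjacency matrix (connection probabilities from probabilistic
#' tractography, averaged over the two tracking directions).
#'
#' @param w Numeric square matrix.
#' @param tol Asymmetry tolerance; asymmetric input within `tol` is
#'   symmetrized by averaging, beyond it is an error (upstream averaging of
#'   the two tracking directions must already have happened).
#' @return The validated (symmetrized, zero-diagonal) matrix.
#' @export
as_connectivity_matrix <- function(w, tol = 1e-9) {
  if (!is.matrix(w) || !is.numeric(w))
    stopf("connectivity matrix must be a numeric matrix")
  if (nrow(w) != ncol(w))
    stopf("connectivity matrix must be square, got %d x %d", nrow(w), ncol(w))
  if (anyNA(w)) stopf("connectivity matrix contains missing values")
  if (any(w < 0)) stopf("connectivity matrix has %d negative entries", sum(w < 0))
  asym <- max(abs(w - t(w)))
  if (asym > tol)
    stopf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol)
  w <- (w + t(w)) / 2
  if (any(diag(w) != 0)) {
    warning("nonzero diagonal forced to 0", call. = FALSE)
    diag(w) <- 0
  }
  dimnames(w) <- NULL
  w
}

read_delim_auto <- function(path, header = TRUE) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, header = header, sep = sep, check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Read a connectivity matrix from delimited text
#'
#' @param path CSV (comma) or TSV/TXT (tab) file of `n_nodes` rows by
#'   `n_nodes` columns of reals, no header.
#' @param n_nodes Expected matrix dimension (90 for the AAL cerebrum atlas).
#' @param tol Asymmetry tolerance passed to [as_connectivity_matrix()].
#' @return A validated connectivity matrix.
#' @export
read_matrix <- function(path, n_nodes = 90L, tol = 1e-9) {
  df <- read_delim_auto(path, header = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (nrow(m) != n_nodes || ncol(m) != n_nodes)
    stopf("'%s': expected %d x %d matrix, got %d x %d",
          path, n_nodes, n_nodes, nrow(m), ncol(m))
  as_connectivity_matrix(m, tol = tol)
}

#' Write a connectivity matrix at full double precision
#' @param w Connectivity matrix.
#' @param path Output CSV/TSV path (delimiter chosen by extension).
#' @export
write_matrix <- function(w, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  txt <- apply(w, 1, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Construct a node table
#'
#' Per-node atlas metadata: region label, hemisphere and seed-mask voxel
#' count (2 mm isotropic voxels), plus the subject's whole-brain gray-matter
#' voxel total. Drives voxel-count weight normalization and region naming.
#'
#' @param label Character vector of unique region labels (AAL-style).
#' @param hemisphere "left"/"right" per node.
#' @param voxel_count Positive integer voxels per regional seed mask.
#' @param gray_matter_total Whole-brain gray-matter voxel count (scalar).
#' @return A `node_table` data.frame with 0-based `index` column and a
#'   `gray_matter_total` attribute.
#' @export
node_table <- function(label, hemisphere, voxel_count, gray_matter_total) {
  n <- length(label)
  if (anyDuplicated(label)) stopf("node labels must be unique")
  if (length(hemisphere) != n || length(voxel_count) != n)
    stopf("node table columns must have equal length")
  if (any(voxel_count < 1)) stopf("voxel counts must be >= 1")
  if (gray_matter_total < max(voxel_count))
    stopf("gray_matter_total must be >= the largest regional voxel count")
  out <- data.frame(index = seq_len(n) - 1L, label = label,
                    hemisphere = hemisphere,
                    voxel_count = as.integer(voxel_count),
                    stringsAsFactors = FALSE)
  attr(out, "gray_matter_total") <- as.integer(gray_matter_total)
  class(out) <- c("node_table", "data.frame")
  out
}

#' Read a node table from CSV
#' @param path CSV with columns index, label, hemisphere, voxel_count,
#'   gray_matter_total (the total is constant down its column).
#' @return A `node_table`.
#' @export
read_node_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("label", "hemisphere", "voxel_count", "gray_matter_total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("'%s': missing column(s) %s", path, paste(miss, collapse = ", "))
  node_table(df$label, df$hemisphere, df$voxel_count, df$gray_matter_total[1])
}

#' Write a node table to CSV
#' @param nodes A `node_table`.
#' @param path Output CSV path.
#' @export
write_node_table <- function(nodes, path) {
  df <- as.data.frame(nodes)
  df$gray_matter_total <- attr(nodes, "gray_matter_total")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default AAL-style labels for a 90-node cerebrum parcellation
#'
#' Synthetic stand-in labels (`L01_L`, `L01_R`, ...) used by the simulator
#' when no atlas table is supplied; 45 homologous pairs, left/right
#' alternating, mirroring the structure of the 90-region AAL cerebrum atlas.
#' @param n_nodes Number of nodes (must be even).
#' @return Character vector of labels.
#' @export
default_labels <- function(n_nodes = 90L) {
  if (n_nodes %% 2L) stopf("n_nodes must be even for paired hemispheres")
  paste0("R", sprintf("%02d", rep(seq_len(n_nodes / 2), each = 2)),
         c("_L", "_R"))
}

#' Assemble a cohort object
#'
#' @param subjects Data frame with one row per subject: `subject_id`,
#'   `group` (LLD-MD / LLD-IM / HC), `age`, `education`, `gender`, `hrsd`,
#'   optional raw test-score columns prefixed `test_`, and (after
#'   [read_cohort()] / [write_cohort()]) `matrix_ref` / `node_table_ref`.
#' @param matrices List of connectivity matrices, one per subject.
#' @param node_tables List of `node_table`s, one per subject.
#' @param config An [analysis_config()].
#' @return A `cohort` object.
#' @export
cohort <- function(subjects, matrices, node_tables, config = analysis_config()) {
  if (anyDuplicated(subjects$subject_id))
    stopf("duplicate subject_id: %s",
          paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]), collapse = ", "))
  bad <- !subjects$group %in% GROUP_LEVELS
  if (any(bad))
    stopf("unknown group label '%s' in manifest row %d (allowed: %s)",
          subjects$group[which(bad)[1]], which(bad)[1],
          paste(GROUP_LEVELS, collapse = ", "))
  if (length(matrices) != nrow(subjects) || length(node_tables) != nrow(subjects))
    stopf("matrices/node_tables must match the number of subjects")
  dims <- vapply(matrices, nrow, 0L)
  if (length(unique(dims)) > 1) stopf("all matrices must share n_nodes")
  structure(list(subjects = subjects, matrices = matrices,
                 node_tables = node_tables, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d nodes\n",
              nrow(x$subjects), nrow(x$matrices[[1]])))
  print(table(x$subjects$group))
  invisible(x)
}

#' Matrices of the subjects in one group
#' @param ch A `cohort`.
#' @param group Group label ("LLD-MD", "LLD-IM" or "HC"), or a vector of
#'   labels to pool.
#' @return List of connectivity matrices.
#' @export
group_matrices <- function(ch, group) {
  ch$matrices[ch$subjects$group %in% group]
}

#' Read a cohort from a manifest
#'
#' The manifest is a CSV with one row per subject (see [cohort()]); columns
#' `matrix_ref` and `node_table_ref` are paths relative to the manifest's
#' directory. Missing test scores may be empty or NA and are kept as NA.
#'
#' @param manifest_path Path to manifest CSV.
#' @param n_nodes Expected matrix dimension.
#' @param config Optional [analysis_config()] attached to the cohort.
#' @return A validated `cohort` with all matrices loaded.
#' @export
read_cohort <- function(manifest_path, n_nodes = 90L, config = analysis_config()) {
  man <- read_delim_auto(manifest_path)
  base <- dirname(manifest_path)
  need <- c("subject_id", "group", "matrix_ref", "node_table_ref")
  miss <- setdiff(need, names(man))
  if (length(miss)) stopf("manifest missing column(s): %s", paste(miss, collapse = ", "))
  mats <- lapply(file.path(base, man$matrix_ref), read_matrix, n_nodes = n_nodes)
  ntabs <- lapply(file.path(base, man$node_table_ref), read_node_table)
  cohort(man, mats, ntabs, config)
}

#' Write a cohort to a directory
#'
#' Writes one matrix CSV and one node-table CSV per subject plus
#' `manifest.csv`; the cohort can be re-read with [read_cohort()] and
#' round-trips bit-identically on weights.
#'
#' @param ch A `cohort`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ch$subjects
  man$matrix_ref <- paste0(man$subject_id, "_matrix.csv")
  man$node_table_ref <- paste0(man$subject_id, "_nodes.csv")
  for (k in seq_len(nrow(man))) {
    write_matrix(ch$matrices[[k]], file.path(dir, man$matrix_ref[k]))
    write_node_table(ch$node_tables[[k]], file.path(dir, man$node_table_ref[k]))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Dispatches on result type: per-subject metric tables and rich-club curves
#' become delimited tables, NBS results become an edge list with region
#' labels plus the permutation null distribution.
#'
#' @param results A result object (`global_metrics` table, `rich_club_curve`,
#'   `nbs_result`, or a plain data.frame).
#' @param out_dir Output directory (created if absent).
#' @param name Base file name (defaults by type).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir, name = NULL) UseMethod("write_results")

#' @export
write_results.data.frame <- function(results, out_dir, name = "results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.rich_club_curve <- function(results, out_dir, name = "richclub_curve") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".csv"))
  df <- as.data.frame(results)
  txt <- c(paste(names(df), collapse = ","),
           apply(df, 1, function(r) paste(sprintf("%.17g", as.numeric(r)), collapse = ",")))
  writeLines(txt, path)
  invisible(path)
}

#' @export
write_results.nbs_result <- function(results, out_dir, name = "nbs") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- nbs_edge_table(results)
  p1 <- file.path(out_dir, paste0(name, "_edges.csv"))
  write.csv(edges, p1, row.names = FALSE)
  p2 <- file.path(out_dir, paste0(name, "_null_max_sizes.csv"))
  write.csv(data.frame(null_max_size = results$null_max_sizes), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write a JSON run summary (config, seed, package version)
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param extra Optional named list merged into the summary.
#' @return The JSON path, invisibly.
#' @export
write_run_summary <- function(config, out_dir, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "run_summary.json")
  info <- c(list(package = "richclubnet",
                 version = as.character(utils::packageVersion("richclubnet")),
                 seed = config$seed,
                 config = unclass(config)),
            extra)
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
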