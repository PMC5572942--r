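#' Analysis configuration
#'
#' Collects the thresholds, null-model sizes and permutation counts used by
#' the pipeline. Defaults follow the published analysis protocol: group
#' prevalence filter keeping edges present in at least 20% of subjects, an
#' 80% prevalence mask for NBS, rich-club consensus edges present in more
#' than 80% of subjects, richness factors r = k/15, 1,000 weight-reshuffle
#' and rewiring nulls, 10,000-permutation covariate-adjusted group tests,
#' and 5,000-permutation NBS with a one-tailed primary threshold of P < 0.01.
#'
#' @param prevalence_keep_threshold Fraction of group subjects in which an
#'   edge must be present to survive the group prevalence filter (boundary
#'   kept: exactly this fraction is retained).
#' @param nbs_mask_threshold Per-group prevalence an edge needs (in either
#'   group) to enter the NBS mask.
#' @param richclub_edge_threshold Consensus threshold for rich-club edges;
#'   strictly more than this fraction of subjects must carry the edge.
#' @param richness_denominator Denominator of the richness-factor grid
#'   r = k/denominator, k = 1..denominator-1. The default 15 with 90 nodes
#'   yields integer club sizes at all 14 levels.
#' @param n_null_richclub Number of weight-reshuffle null networks.
#' @param n_null_smallworld Number of degree-preserving rewired null networks.
#' @param n_perm_group Permutations for covariate-adjusted group tests.
#' @param n_perm_nbs Permutations for NBS FWER correction.
#' @param nbs_primary_p One-tailed primary p-value defining the
#'   suprathreshold t cutoff.
#' @param alpha Nominal significance level.
#' @param seed Integer base seed; every randomized stage derives its own
#'   deterministic sub-stream from it.
#' @return An object of class `analysis_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config(seed = 42, n_perm_nbs = 500)
analysis_config <- function(prevalence_keep_threshold = 0.20,
                            nbs_mask_threshold = 0.80,
                            richclub_edge_threshold = 0.80,
                            richness_denominator = 15L,
                            n_null_richclub = 1000L,
                            n_null_smallworld = 1000L,
                            n_perm_group = 10000L,
                            n_perm_nbs = 5000L,
                            nbs_primary_p = 0.01,
                            alpha = 0.05,
                            seed = 1L) {
  fracs <- c(prevalence_keep_threshold = prevalence_keep_threshold,
             nbs_mask_threshold = nbs_mask_threshold,
             richclub_edge_threshold = richclub_edge_threshold,
             nbs_primary_p = nbs_primary_p, alpha = alpha)
  for (nm in names(fracs)) {
    if (!is_scalar_number(fracs[[nm]]) || fracs[[nm]] <= 0 || fracs[[nm]] >= 1)
      stopf("'%s' must be a fraction in (0, 1), got %s", nm, fracs[[nm]])
  }
  counts <- c(richness_denominator = richness_denominator,
              n_null_richclub = n_null_richclub,
              n_null_smallworld = n_null_smallworld,
              n_perm_group = n_perm_group, n_perm_nbs = n_perm_nbs)
  for (nm in names(counts)) {
    if (!is_scalar_number(counts[[nm]]) || counts[[nm]] < 1)
      stopf("'%s' must be a count >= 1, got %s", nm, counts[[nm]])
  }
  structure(list(
    prevalence_keep_threshold = prevalence_keep_threshold,
    nbs_mask_threshold = nbs_mask_threshold,
    richclub_edge_threshold = richclub_edge_threshold,
    richness_denominator = as.integer(richness_denominator),
    n_null_richclub = as.integer(n_null_richclub),
    n_null_smallworld = as.integer(n_null_smallworld),
    n_perm_group = as.integer(n_perm_group),
    n_perm_nbs = as.integer(n_perm_nbs),
    nbs_primary_p = nbs_primary_p,
    alpha = alpha,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or key=value text
#'
#' Any field of [analysis_config()] may appear; unknown keys are an error.
#' @param path Path to a YAML file or a flat `key = value` file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(vals) || !is.list(vals)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) as.numeric(trimws(p[2])))
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, x[[nm]]))
  invisible(x)
}
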