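## High-level pipeline stages over a cohort. Each stage works in memory and
## optionally writes delimited tables; the CLI at inst/cli/connectome.R is a
## thin wrapper around these functions.

#' Simulate a cohort and write it to disk
#'
#' Writes the manifest, per-subject matrices and node tables, plus a
#' `ground_truth.json` with the planted hub set, subnetwork edges and
#' multipliers.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory.
#' @return The manifest path, invisibly.
#' @export
simulate_to_dir <- function(cfg, out_dir) {
  gen <- generate_cohort(cfg)
  path <- write_cohort(gen$cohort, out_dir)
  gt <- gen$truth
  gt$group_mean_class_strength <- NULL
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## Prevalence-filtered matrices per group (list of lists), plus masks.
filter_by_group <- function(ch) {
  out <- list()
  for (g in unique(ch$subjects$group)) {
    f <- apply_prevalence_filter(group_matrices(ch, g),
                                 ch$config$prevalence_keep_threshold)
    out[[g]] <- f
  }
  out
}

#' Per-subject global network metrics for a cohort
#'
#' Applies the group prevalence filter, then computes all global metrics
#' per subject.
#'
#' @param ch A [cohort()].
#' @param include_small_world Compute gamma/lambda/sigma (slow)?
#' @param out_dir Optional output directory for the metrics table.
#' @return Data frame: subject_id, group, and one column per metric.
#' @export
run_metrics <- function(ch, include_small_world = FALSE, out_dir = NULL) {
  filt <- filter_by_group(ch)
  rows <- lapply(seq_len(nrow(ch$subjects)), function(s) {
    g <- ch$subjects$group[s]
    pos <- which(ch$subjects$group == g)
    w <- filt[[g]]$matrices[[match(s, pos)]]
    cbind(ch$subjects[s, c("subject_id", "group")],
          compute_global_metrics(w, ch$config,
                                 include_small_world = include_small_world))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) write_results(tab, out_dir, "global_metrics")
  tab
}

#' Rich-club analysis for a cohort
#'
#' Per group: prevalence filter, voxel normalization, per-subject
#' normalized rich-club curves and their AUC. Rich-club regions are defined
#' from the control group's mean normalized matrix at `r_define`; every
#' subject's raw filtered matrix is then partitioned into
#' rich-club/feeder/local classes.
#'
#' @param ch A [cohort()].
#' @param r_define Richness factor defining the club (default 2/15).
#' @param out_dir Optional output directory.
#' @return List with `curves` (long data.frame), `rich_nodes`,
#'   `class_strengths` (per-subject data.frame), `auc` (per subject),
#'   `consensus_edges`.
#' @export
run_richclub <- function(ch, r_define = 2 / 15, out_dir = NULL) {
  filt <- filter_by_group(ch)
  n_subj <- nrow(ch$subjects)
  norm_mats <- vector("list", n_subj)
  raw_mats <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    g <- ch$subjects$group[s]
    pos <- which(ch$subjects$group == g)
    raw_mats[[s]] <- filt[[g]]$matrices[[match(s, pos)]]
    norm_mats[[s]] <- voxel_normalize(raw_mats[[s]], ch$node_tables[[s]])
  }
  hc_idx <- which(ch$subjects$group == "HC")
  rich_nodes <- define_rich_club_nodes(norm_mats[hc_idx],
                                       ch$node_tables[[hc_idx[1]]], r_define)
  curves <- vector("list", n_subj)
  auc <- numeric(n_subj)
  cls <- matrix(NA_real_, n_subj, 3,
                dimnames = list(NULL, c("rich_club", "feeder", "local")))
  for (s in seq_len(n_subj)) {
    cfg_s <- ch$config
    cfg_s$seed <- derive_seed(ch$config$seed, "richclub_subject", s)
    cv <- normalized_curve(norm_mats[[s]], cfg_s)
    auc[s] <- curve_auc(cv)
    curves[[s]] <- cbind(subject_id = ch$subjects$subject_id[s],
                         group = ch$subjects$group[s], as.data.frame(cv))
    part <- partition_and_strengths(raw_mats[[s]], rich_nodes)
    cls[s, ] <- part$class_average_strength[colnames(cls)]
  }
  consensus <- richclub_edge_consensus(raw_mats, rich_nodes,
                                       ch$config$richclub_edge_threshold)
  out <- list(curves = do.call(rbind, curves), rich_nodes = rich_nodes,
              class_strengths = cbind(ch$subjects[, c("subject_id", "group")],
                                      as.data.frame(cls), auc = auc),
              auc = auc, consensus_edges = consensus)
  if (!is.null(out_dir)) {
    write_results(out$curves, out_dir, "richclub_curves")
    write_results(out$class_strengths, out_dir, "class_strengths")
    write_results(data.frame(index = unname(rich_nodes),
                             label = names(rich_nodes)),
                  out_dir, "rich_nodes")
  }
  out
}

#' NBS comparison between the two patient groups
#'
#' One-tailed (LLD-MD < LLD-IM) network-based statistic on the 80%
#' prevalence mask, with max-component permutation FWER correction.
#'
#' @param ch A [cohort()].
#' @param group_a,group_b Group labels compared (A < B alternative).
#' @param out_dir Optional output directory.
#' @return An `nbs_result`.
#' @export
run_nbs <- function(ch, group_a = "LLD-MD", group_b = "LLD-IM", out_dir = NULL) {
  res <- nbs_permutation(group_matrices(ch, group_a),
                         group_matrices(ch, group_b), ch$config)
  if (!is.null(out_dir)) {
    labels <- ch$node_tables[[1]]$label
    write_results(res, out_dir)
    write_results(nbs_edge_table(res, labels), out_dir, "nbs_edges_labeled")
  }
  res
}

#' Group statistics over rich-club and global-topology outputs
#'
#' Covariate-adjusted (age, education, gender) permutation tests on the
#' normalized rich-club coefficient at `r_test`, the curve AUC and the
#' three class average strengths; ANCOVA with LSD post hoc on cognitive
#' composites; HDRS-adjusted partial correlations between composites and
#' class strengths (flagged at p < alpha and at the Bonferroni p <
#' alpha/3); and stepwise regression of each composite on the class
#' strengths with HDRS forced in.
#'
#' @param ch A [cohort()] whose subject table carries `executive`, `speed`,
#'   `memory` composites.
#' @param rc Result of [run_richclub()].
#' @param r_test Richness factor tested (default 2/15).
#' @param out_dir Optional output directory.
#' @return List of result tables.
#' @export
run_stats <- function(ch, rc, r_test = 2 / 15, out_dir = NULL) {
  sub <- ch$subjects
  covs <- sub[, c("age", "education", "gender")]
  cfgn <- ch$config$n_perm_group
  phi_at <- function(df) df$phi_norm[abs(df$r - r_test) < 1e-9]
  phin <- vapply(split(rc$curves, rc$curves$subject_id)[sub$subject_id], phi_at, 0)

  perm_tests <- list(
    phi_norm = adjusted_permutation_test(phin, sub$group, covs, cfgn,
                                         seed = derive_seed(ch$config$seed, "stats_phi")),
    auc = adjusted_permutation_test(rc$auc, sub$group, covs, cfgn,
                                    seed = derive_seed(ch$config$seed, "stats_auc")))
  for (cl in c("rich_club", "feeder", "local")) {
    perm_tests[[paste0(cl, "_strength")]] <-
      adjusted_permutation_test(rc$class_strengths[[cl]], sub$group, covs, cfgn,
                                seed = derive_seed(ch$config$seed, paste0("stats_", cl)))
  }
  composites <- c("executive", "speed", "memory")
  ancova <- lapply(setNames(composites, composites), function(dv)
    ancova_lsd(sub[[dv]], sub$group, covs))

  lld <- sub$group %in% c("LLD-MD", "LLD-IM")
  cors <- do.call(rbind, lapply(composites, function(dv) {
    do.call(rbind, lapply(c("rich_club", "feeder", "local"), function(cl) {
      pc <- partial_correlation(rc$class_strengths[[cl]][lld], sub[[dv]][lld],
                                sub$hrsd[lld])
      data.frame(domain = dv, subnetwork = cl, r = pc$r, p = pc$p,
                 significant = pc$p < ch$config$alpha,
                 significant_bonf = pc$p < ch$config$alpha / 3,
                 tendency = pc$p >= ch$config$alpha / 3 & pc$p < ch$config$alpha)
    }))
  }))
  stepw <- lapply(setNames(composites, composites), function(dv) {
    sr <- stepwise_regression(sub[[dv]][lld],
                              rc$class_strengths[lld, c("rich_club", "feeder", "local")],
                              setNames(data.frame(sub$hrsd[lld]), "hrsd"))
    sr$coefficients
  })
  out <- list(perm_tests = perm_tests, ancova = ancova,
              correlations = cors, stepwise = stepw)
  if (!is.null(out_dir)) {
    ptab <- do.call(rbind, lapply(names(perm_tests), function(nm)
      data.frame(measure = nm, F = perm_tests[[nm]]$statistic,
                 p_perm = perm_tests[[nm]]$p_perm)))
    write_results(ptab, out_dir, "group_permutation_tests")
    write_results(cors, out_dir, "partial_correlations")
    write_results(do.call(rbind, lapply(names(stepw), function(nm)
      cbind(domain = nm, stepw[[nm]]))), out_dir, "stepwise_models")
  }
  out
}

#' Run the full pipeline on a cohort
#'
#' Metrics, rich-club analysis, NBS (LLD-MD vs LLD-IM) and group
#' statistics, optionally writing all tables plus a JSON run summary.
#'
#' @param ch A [cohort()].
#' @param out_dir Optional output directory.
#' @param include_small_world Compute the small-world normalization in the
#'   metrics stage?
#' @return List with `metrics`, `richclub`, `nbs`, `stats`.
#' @export
run_all <- function(ch, out_dir = NULL, include_small_world = FALSE) {
  metrics <- run_metrics(ch, include_small_world, out_dir)
  rc <- run_richclub(ch, out_dir = out_dir)
  nbs <- run_nbs(ch, out_dir = out_dir)
  st <- run_stats(ch, rc, out_dir = out_dir)
  if (!is.null(out_dir)) write_run_summary(ch$config, out_dir)
  list(metrics = metrics, richclub = rc, nbs = nbs, stats = st)
}
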