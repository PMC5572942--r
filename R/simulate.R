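## Synthetic cohort generator: weighted connectomes with planted hub
## structure and group effects, demographic covariates drawn to the study's
## group profiles, and cognitive composites linearly coupled to subnetwork
## strengths. Provides the planted ground truth every downstream stage is
## validated against.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: three groups of 15 (memory
#' deficit), 24 (intact memory) and 30 (control) subjects; 90 nodes with 12
#' planted hub regions (the rich-club size at r = 2/15); edge density 0.64
#' (the density scale of probability-weighted AAL networks); hub-hub edges
#' boosted by `hub_gain` (hub-nonhub edges by its square root, so hub
#' strength clearly dominates); log-normal edge weights with subject-level
#' multiplicative noise; and per-group covariates drawn to the reported
#' demographic profile (age 64.47/66.21/66.23, HRSD 9.13/10.79/1.27, ...).
#'
#' Patient effects are planted as multipliers < 1: `delta_richclub` on
#' hub-hub edges in both patient groups; `delta_feeder`/`delta_local` on
#' feeder/local edges plus a connected 20-edge subnetwork scaled by
#' `nbs_deficit`, all three only in the memory-deficit group. The effect
#' sizes on the weight scale are simulation choices (the study reports
#' none); defaults are picked so group effects are detectable but not
#' trivial at the study's sample sizes.
#'
#' Raw weights additionally scale with the product of the two regions'
#' voxel counts (as tractography streamline counts do), which
#' [voxel_normalize()] is designed to remove.
#'
#' @param n_per_group Integer vector (LLD-MD, LLD-IM, HC).
#' @param n_nodes,n_hubs Network size and planted hub count.
#' @param base_weight_logmean,base_weight_logsd Log-normal edge weight
#'   parameters.
#' @param hub_gain Multiplier on hub-hub edges (> 1).
#' @param edge_density Fraction of node pairs with a nonzero weight.
#' @param delta_richclub,delta_feeder,delta_local Planted group multipliers
#'   (< 1).
#' @param nbs_n_edges,nbs_deficit Size and multiplier of the planted
#'   connected subnetwork deficit.
#' @param noise_sd Subject-level log-scale weight noise SD.
#' @param voxel_count_range Per-region seed-mask voxel counts (2 mm
#'   voxels).
#' @param covariate_means,covariate_sds Per-group age/education/HRSD
#'   parameters (3 x 3, rows = groups LLD-MD/LLD-IM/HC).
#' @param male_counts Males per group (females are the remainder); gender
#'   has no planted effect and exists to exercise covariate adjustment.
#' @param cognition_loadings 3 x 3 matrix mapping z-scored (rich-club,
#'   feeder, local) average strengths to (executive, speed, memory)
#'   composites.
#' @param cognition_noise_sd SD of the Gaussian noise on composites.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = c(15L, 24L, 30L),
                              n_nodes = 90L,
                              n_hubs = 12L,
                              base_weight_logmean = -5.2,
                              base_weight_logsd = 0.6,
                              hub_gain = 3.0,
                              edge_density = 0.64,
                              delta_richclub = 0.8,
                              delta_feeder = 0.85,
                              delta_local = 0.85,
                              nbs_n_edges = 20L,
                              nbs_deficit = 0.6,
                              noise_sd = 0.3,
                              voxel_count_range = c(200L, 4000L),
                              covariate_means = rbind(
                                `LLD-MD` = c(age = 64.47, education = 8.53, hrsd = 9.13),
                                `LLD-IM` = c(age = 66.21, education = 9.71, hrsd = 10.79),
                                HC = c(age = 66.23, education = 10.65, hrsd = 1.27)),
                              covariate_sds = rbind(
                                `LLD-MD` = c(age = 6.87, education = 3.76, hrsd = 7.92),
                                `LLD-IM` = c(age = 5.57, education = 3.82, hrsd = 7.11),
                                HC = c(age = 4.95, education = 3.00, hrsd = 3.04)),
                              male_counts = c(3L, 6L, 6L),
                              cognition_loadings = rbind(
                                executive = c(rich_club = 0, feeder = 0.5, local = 0),
                                speed = c(0.3, 0, 0.5),
                                memory = c(0, 0, 0.5)),
                              cognition_noise_sd = 0.9,
                              seed = 1L) {
  if (n_hubs < 2 || n_hubs >= n_nodes)
    stopf("need 2 <= n_hubs < n_nodes, got n_hubs = %d, n_nodes = %d", n_hubs, n_nodes)
  if (edge_density <= 0 || edge_density > 1) stopf("edge_density must be in (0, 1]")
  mult <- c(hub_gain = hub_gain, delta_richclub = delta_richclub,
            delta_feeder = delta_feeder, delta_local = delta_local,
            nbs_deficit = nbs_deficit)
  if (any(mult <= 0)) stopf("all multipliers must be > 0")
  if (length(n_per_group) != 3 || any(n_per_group < 1))
    stopf("n_per_group must give three positive group sizes")
  structure(list(
    n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
    n_hubs = as.integer(n_hubs),
    base_weight_logmean = base_weight_logmean,
    base_weight_logsd = base_weight_logsd,
    hub_gain = hub_gain, edge_density = edge_density,
    delta_richclub = delta_richclub, delta_feeder = delta_feeder,
    delta_local = delta_local,
    nbs_n_edges = as.integer(nbs_n_edges), nbs_deficit = nbs_deficit,
    noise_sd = noise_sd,
    voxel_count_range = as.integer(voxel_count_range),
    covariate_means = covariate_means, covariate_sds = covariate_sds,
    male_counts = as.integer(male_counts),
    cognition_loadings = cognition_loadings,
    cognition_noise_sd = cognition_noise_sd,
    seed = as.integer(seed)), class = "simulation_config")
}

## Edge-class labels for a skeleton given the hub set.
edge_class_of <- function(ei, ej, hubs) {
  k <- (ei %in% hubs) + (ej %in% hubs)
  c("local", "feeder", "rich_club")[k + 1L]
}

#' Apply planted group effects to a template matrix
#'
#' Control subjects are returned unchanged. In both patient groups hub-hub
#' (rich-club) edges are scaled by `delta_richclub`; only in the
#' memory-deficit group are feeder and local edges additionally scaled by
#' `delta_feeder`/`delta_local` and the planted subnetwork edges by
#' `nbs_deficit`. Symmetry is preserved.
#'
#' @param base_matrix Connectivity matrix (a control-like template).
#' @param group "HC", "LLD-IM" or "LLD-MD".
#' @param cfg A [simulation_config()].
#' @param truth Ground truth list with `hub_nodes` and `planted_nbs_edges`.
#' @return The scaled connectivity matrix.
#' @export
plant_effects <- function(base_matrix, group, cfg, truth) {
  if (group == "HC") return(base_matrix)
  n <- nrow(base_matrix)
  hubs <- truth$hub_nodes
  is_hub <- seq_len(n) %in% hubs
  mult <- matrix(1, n, n)
  rc <- outer(is_hub, is_hub, `&`)
  mult[rc] <- cfg$delta_richclub
  if (group == "LLD-MD") {
    fe <- outer(is_hub, is_hub, xor)
    lo <- outer(!is_hub, !is_hub, `&`)
    mult[fe] <- cfg$delta_feeder
    mult[lo] <- cfg$delta_local
    pe <- truth$planted_nbs_edges
    for (k in seq_len(nrow(pe))) {
      mult[pe$i[k], pe$j[k]] <- mult[pe$i[k], pe$j[k]] * cfg$nbs_deficit
      mult[pe$j[k], pe$i[k]] <- mult[pe$j[k], pe$i[k]] * cfg$nbs_deficit
    }
  }
  diag(mult) <- 1
  base_matrix * mult
}

## Random connected edge subset (a tree grown over the skeleton), biased
## toward non-hub nodes, emulating a mostly feeder/local deficit subnetwork.
grow_planted_subnetwork <- function(ei, ej, n, hubs, n_edges) {
  adj <- vector("list", n)
  for (e in seq_along(ei)) {
    adj[[ei[e]]] <- c(adj[[ei[e]]], e)
    adj[[ej[e]]] <- c(adj[[ej[e]]], e)
  }
  nonhub <- setdiff(seq_len(n), hubs)
  visited <- sample(nonhub, 1)
  picked <- integer()
  while (length(picked) < n_edges) {
    cand <- setdiff(unlist(adj[visited]), picked)
    other <- ifelse(ei[cand] %in% visited & !(ej[cand] %in% visited), ej[cand],
                    ifelse(ej[cand] %in% visited & !(ei[cand] %in% visited),
                           ei[cand], NA))
    cand <- cand[!is.na(other)]; other <- other[!is.na(other)]
    if (length(cand) == 0) stopf("skeleton too sparse for the planted subnetwork")
    pr <- ifelse(other %in% hubs, 0.1, 1)  # mostly local/feeder, as observed
    k <- sample.int(length(cand), 1, prob = pr)
    picked <- c(picked, cand[k])
    visited <- c(visited, other[k])
  }
  picked
}

rnorm_clamped <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(n, mean, sd)))

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws one shared edge skeleton and base weight per cohort (group
#' prevalence filters presuppose largely shared topology), plants hubs and
#' group effects via [plant_effects()], adds subject-level log-normal
#' weight noise and voxel-size scaling, draws covariates to the per-group
#' profiles, and generates cognitive composites as
#' `loadings %*% z(subnetwork strengths) + noise`. Deterministic given the
#' config seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `cohort` (a [cohort()]) and `truth` (hub nodes,
#'   planted subnetwork edges, multipliers, per-group mean class strengths,
#'   loadings as used).
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  n <- cfg$n_nodes
  groups <- rep(c("LLD-MD", "LLD-IM", "HC"), cfg$n_per_group)
  n_subj <- length(groups)

  hubs <- with_seed(derive_seed(cfg$seed, "hubs"), sort(sample.int(n, cfg$n_hubs)))

  ## shared skeleton + base weights
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  present <- with_seed(derive_seed(cfg$seed, "skeleton"),
                       runif(nrow(pairs)) < cfg$edge_density)
  ei <- pairs[present, 1]; ej <- pairs[present, 2]
  m <- length(ei)
  cls <- edge_class_of(ei, ej, hubs)
  ## per-edge gain = mean of endpoint gains (hub endpoint: hub_gain, else 1)
  gain <- c(rich_club = cfg$hub_gain, feeder = (cfg$hub_gain + 1) / 2,
            local = 1)[cls]
  base_w <- with_seed(derive_seed(cfg$seed, "base_weights"),
                      exp(rnorm(m, cfg$base_weight_logmean, cfg$base_weight_logsd))) * gain

  planted_idx <- with_seed(derive_seed(cfg$seed, "planted"),
                           grow_planted_subnetwork(ei, ej, n, hubs, cfg$nbs_n_edges))
  planted <- data.frame(i = ei[planted_idx], j = ej[planted_idx])

  ## region sizes are anatomical: shared across subjects, small subject
  ## jitter from segmentation/registration differences
  vr <- cfg$voxel_count_range
  v_region <- with_seed(derive_seed(cfg$seed, "voxels"),
                        round(runif(n, vr[1], vr[2])))
  labels <- default_labels(n)

  base_mat <- edges_to_matrix(ei, ej, base_w, n)
  truth <- list(hub_nodes = hubs, planted_nbs_edges = planted,
                multipliers = c(delta_richclub = cfg$delta_richclub,
                                delta_feeder = cfg$delta_feeder,
                                delta_local = cfg$delta_local,
                                nbs_deficit = cfg$nbs_deficit),
                cognition_loadings = cfg$cognition_loadings)

  matrices <- vector("list", n_subj)
  node_tables <- vector("list", n_subj)
  class_strength <- matrix(NA_real_, n_subj, 3,
                           dimnames = list(NULL, c("rich_club", "feeder", "local")))
  for (s in seq_len(n_subj)) {
    sseed <- derive_seed(cfg$seed, "subject", s)
    planted_m <- plant_effects(base_mat, groups[s], cfg, truth)
    noise <- with_seed(derive_seed(sseed, "noise"),
                       exp(rnorm(m, 0, cfg$noise_sd)))
    v_s <- with_seed(derive_seed(sseed, "voxel_jitter"),
                     pmax(1, round(v_region * runif(n, 0.9, 1.1))))
    gm <- with_seed(derive_seed(sseed, "gm"),
                    as.integer(round(sum(v_s) * runif(1, 1.05, 1.2))))
    vf <- (v_s / mean(v_s))
    wt <- planted_m[cbind(ei, ej)] * noise * vf[ei] * vf[ej]
    matrices[[s]] <- edges_to_matrix(ei, ej, wt, n)
    node_tables[[s]] <- node_table(labels, rep(c("left", "right"), n / 2), v_s, gm)
    part <- partition_and_strengths(matrices[[s]], hubs)
    class_strength[s, ] <- part$class_average_strength[colnames(class_strength)]
  }

  ## covariates per group
  gidx <- match(groups, rownames(cfg$covariate_means))
  cm <- cfg$covariate_means; cs <- cfg$covariate_sds
  demo <- with_seed(derive_seed(cfg$seed, "covariates"), {
    age <- rnorm_clamped(n_subj, cm[gidx, "age"], cs[gidx, "age"], 55, 90)
    education <- rnorm_clamped(n_subj, cm[gidx, "education"], cs[gidx, "education"], 0, 22)
    hrsd <- round(rnorm_clamped(n_subj, cm[gidx, "hrsd"], cs[gidx, "hrsd"], 0, 52))
    gender <- unlist(lapply(1:3, function(g) {
      ng <- cfg$n_per_group[g]
      nm <- min(cfg$male_counts[g], ng)  # clamp for downsized groups
      sample(rep(c("M", "F"), c(nm, ng - nm)))
    }))
    data.frame(age = round(age, 1), education = round(education, 1),
               gender = gender, hrsd = hrsd)
  })

  ## cognitive composites from z-scored subnetwork strengths
  zs <- scale(class_strength)
  L <- cfg$cognition_loadings
  cog <- with_seed(derive_seed(cfg$seed, "cognition"), {
    signal <- zs %*% t(L)
    signal + matrix(rnorm(length(signal), 0, cfg$cognition_noise_sd),
                    nrow(signal))
  })
  colnames(cog) <- rownames(L)

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subj)),
    group = groups, demo, cog,
    rich_club_strength = class_strength[, "rich_club"],
    feeder_strength = class_strength[, "feeder"],
    local_strength = class_strength[, "local"],
    stringsAsFactors = FALSE)

  truth$group_mean_class_strength <-
    aggregate(class_strength, list(group = groups), mean)

  list(cohort = cohort(subjects, matrices, node_tables,
                       analysis_config(seed = cfg$seed)),
       truth = truth)
}

#' Generate raw neuropsychological test scores
#'
#' A companion generator producing plausible raw battery scores (MMSE, AVLT
#' N1-N5, TMT-A/B and Stroop A/C completion times, DST forward/backward,
#' SDMT, LMT) with group profiles mirroring the study's: severe delayed
#' recall and MMSE deficits in the memory-deficit group, slower times and
#' fewer correct symbols in patients. Feeds the composite-construction
#' tests; the cohort generator produces composites directly.
#'
#' @param groups Character vector of group labels per subject.
#' @param seed Integer seed.
#' @param n_missing_tmt Number of memory-deficit subjects with the TMT
#'   marked missing (the study retained one such subject).
#' @return Data frame of raw scores (one row per subject) suitable for
#'   [cognitive_composites()].
#' @export
generate_raw_scores <- function(groups, seed = 1L, n_missing_tmt = 1L) {
  gi <- match(groups, c("LLD-MD", "LLD-IM", "HC"))
  if (anyNA(gi)) stopf("unknown group label")
  n <- length(groups)
  par <- function(md, im, hc, sdv) list(mean = c(md, im, hc)[gi], sd = sdv)
  specs <- list(
    mmse = par(21.4, 26.5, 27.4, 2.5), tmt_a = par(95, 75, 60, 20),
    tmt_b = par(220, 180, 150, 45), stroop_a = par(38, 32, 27, 8),
    stroop_c = par(95, 78, 62, 18), dst_forward = par(7, 8, 8, 1.5),
    dst_backward = par(3, 4, 5, 1.5), sdmt = par(18, 28, 34, 8),
    lmt = par(4, 8.5, 10, 3),
    avlt_n1 = par(2.5, 4.5, 5, 1.5), avlt_n2 = par(3.5, 6, 6.5, 1.8),
    avlt_n3 = par(4, 7, 7.5, 1.8), avlt_n4 = par(4, 7.5, 8, 2),
    avlt_n5 = par(0.8, 6.71, 7.3, 1.6))
  out <- with_seed(derive_seed(seed, "raw_scores"), {
    df <- as.data.frame(lapply(specs, function(p)
      round(pmax(0, rnorm(n, p$mean, p$sd)), 1)))
    df$avlt_n5 <- pmin(df$avlt_n5, ifelse(gi == 1, 4, 15))  # deficit rule
    miss <- head(which(gi == 1), n_missing_tmt)
    df$tmt_a[miss] <- NA; df$tmt_b[miss] <- NA
    df
  })
  out
}
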