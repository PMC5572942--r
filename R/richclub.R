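## Weighted rich-club analysis: voxel-count normalization, rich-club
## coefficient curves against weight-reshuffle nulls, rich-club node
## definition from the control group, and rich-club/feeder/local edge
## classification with connective average strengths.

#' Voxel-count normalization of a connectivity matrix
#'
#' Probabilistic-tractography weights scale with the seed and target mask
#' sizes (streamlines are seeded per voxel), so raw probabilities are biased
#' toward large regions. The normalized weight
#' \deqn{W^{norm}_{ij} = \frac{W_{ij}}{(v_i/GM)\,(v_j/GM)}}
#' divides out the seed-voxel, target-voxel and whole-brain gray-matter
#' volume effects; the two directed normalizations are averaged (they
#' coincide for a symmetric voxel product). Normalization is used only for
#' rich-club coefficient calculation and rich-club node definition — all
#' other metrics use raw weights, so over-strong central connections do not
#' mask non-central ones.
#'
#' @param w Connectivity matrix.
#' @param nodes A [node_table()] with positive voxel counts and
#'   `gray_matter_total`.
#' @return Normalized connectivity matrix.
#' @export
voxel_normalize <- function(w, nodes) {
  v <- nodes$voxel_count
  gm <- attr(nodes, "gray_matter_total")
  if (any(v <= 0) || is.null(gm) || gm <= 0)
    stopf("voxel counts and gray_matter_total must be positive")
  if (length(v) != nrow(w))
    stopf("node table has %d rows but matrix has %d nodes", length(v), nrow(w))
  f <- v / gm
  out <- w / outer(f, f)
  (out + t(out)) / 2
}

## Strength ranking with ties broken by ascending node index.
strength_ranks <- function(strength) {
  ord <- order(-strength, seq_along(strength))
  rk <- integer(length(strength))
  rk[ord] <- seq_along(strength)
  rk
}

#' Weighted rich-club coefficient at one richness factor
#'
#' Nodes are ranked by connective strength (ties broken by ascending node
#' index); the rich subnetwork at richness factor r is the induced subgraph
#' on the top r*N nodes. With \eqn{E_{>r}} its edge count and
#' \eqn{\omega_{>r}} its total weight,
#' \deqn{\phi^\omega(r) = \omega_{>r} \Big/ \sum_{l=1}^{E_{>r}} \omega_l^{rank},}
#' the denominator being the sum of the \eqn{E_{>r}} strongest edge weights
#' anywhere in the network. Undefined (NA) when the rich subnetwork has no
#' internal edges.
#'
#' @param w Connectivity matrix (typically voxel-normalized).
#' @param r Richness factor; `r * N` must be a positive integer.
#' @return \eqn{\phi^\omega(r)} in \[0, 1\], or NA when undefined.
#' @export
rich_club_coefficient <- function(w, r) {
  n <- nrow(w)
  sz <- r * n
  if (abs(sz - round(sz)) > 1e-9 || round(sz) < 1)
    stopf("r * N must be a positive integer, got r = %g with N = %d", r, n)
  sz <- as.integer(round(sz))
  rk <- strength_ranks(rowSums(w))
  club <- which(rk <= sz)
  sub <- w[club, club, drop = FALSE]
  ww <- sub[upper.tri(sub)]
  ww <- ww[ww > 0]
  e_r <- length(ww)
  if (e_r == 0) return(NA_real_)
  all_w <- w[upper.tri(w)]
  all_w <- sort(all_w[all_w > 0], decreasing = TRUE)
  sum(ww) / sum(all_w[seq_len(e_r)])
}

#' Weight-reshuffle null networks
#'
#' Each null keeps the exact topology (same present edges, hence same degree
#' sequence) and permutes the multiset of edge weights uniformly at random
#' over those edges. Deterministic given `seed`.
#'
#' @param w Connectivity matrix.
#' @param n_null Number of nulls.
#' @param seed Integer seed.
#' @return List of `n_null` connectivity matrices.
#' @export
reshuffled_nulls <- function(w, n_null, seed = 1L) {
  el <- edge_list(w)
  perms <- reshuffle_perms(nrow(el), n_null, seed)
  lapply(seq_len(n_null), function(b)
    edges_to_matrix(el$i, el$j, el$w[perms[, b]], nrow(w)))
}

## One derived RNG stream yields all null permutations, so the matrix-level
## nulls and the batched curve computation see identical reshuffles.
reshuffle_perms <- function(m, n_null, seed) {
  with_seed(derive_seed(seed, "reshuffle"),
            vapply(seq_len(n_null), function(b) sample.int(m), integer(m)))
}

## phi at every level k = 1..n_lev for one weight assignment over a fixed
## edge skeleton. `denom_cum` is the cumulative sum of weights sorted
## descending (identical across reshuffle nulls).
phi_all_levels <- function(wt, ei, ej, strength, step, n_lev, denom_cum) {
  rk <- strength_ranks(strength)
  lev <- ceiling(pmax(rk[ei], rk[ej]) / step)
  ok <- lev <= n_lev
  cnt <- tabulate(lev[ok], n_lev)
  ws <- numeric(n_lev)
  if (any(ok)) {
    tb <- rowsum(wt[ok], lev[ok])
    ws[as.integer(rownames(tb))] <- tb
  }
  cs_e <- cumsum(cnt)
  cs_w <- cumsum(ws)
  phi <- rep(NA_real_, n_lev)
  pos <- cs_e > 0
  phi[pos] <- cs_w[pos] / denom_cum[cs_e[pos]]
  phi
}

#' Normalized rich-club curve
#'
#' Evaluates \eqn{\phi^\omega(r)} and its weight-reshuffle null mean at
#' r = k/denominator for k = 1..denominator-1 (with N = 90 and denominator
#' 15 this is 14 levels, each with an integer club size), and forms
#' \eqn{\phi_{norm}(r) = \phi^\omega(r) / \overline{\phi^\omega_{random}(r)}}.
#' \eqn{\phi_{norm} > 1} indicates rich-club organization. Levels where the
#' rich subnetwork has no internal edges are recorded as undefined, not
#' dropped.
#'
#' The input should be prevalence-filtered and voxel-normalized.
#'
#' @param w Connectivity matrix.
#' @param config An [analysis_config()] supplying `richness_denominator`,
#'   `n_null_richclub` and the seed.
#' @return A `rich_club_curve`: data.frame with columns `level`, `r`,
#'   `club_size`, `phi`, `phi_random_mean`, `phi_norm`; attributes `n_nulls`
#'   and `undefined_levels`.
#' @export
normalized_curve <- function(w, config = analysis_config()) {
  n <- nrow(w)
  D <- config$richness_denominator
  if ((n %% D) != 0)
    stopf("richness denominator %d does not divide N = %d into integer club sizes", D, n)
  step <- n %/% D
  n_lev <- D - 1L
  el <- edge_list(w)
  m <- nrow(el)
  if (m == 0) stopf("matrix has no edges")
  denom_cum <- cumsum(sort(el$w, decreasing = TRUE))
  strength <- rowSums(w)
  phi_obs <- phi_all_levels(el$w, el$i, el$j, strength, step, n_lev, denom_cum)

  n_null <- config$n_null_richclub
  perms <- reshuffle_perms(m, n_null, config$seed)
  P <- matrix(el$w[perms], m, n_null)
  phi_null <- phi_levels_batch(el$i, el$j, P, n, step, n_lev, denom_cum)
  phi_rand <- rowMeans(phi_null, na.rm = TRUE)
  phi_rand[is.nan(phi_rand)] <- NA_real_

  out <- data.frame(level = seq_len(n_lev), r = seq_len(n_lev) / D,
                    club_size = step * seq_len(n_lev),
                    phi = phi_obs, phi_random_mean = phi_rand,
                    phi_norm = phi_obs / phi_rand)
  attr(out, "n_nulls") <- n_null
  attr(out, "undefined_levels") <- out$r[is.na(phi_obs)]
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Define rich-club nodes from the control group
#'
#' Computes the arithmetic mean of the control subjects' (voxel-normalized,
#' prevalence-filtered) matrices, ranks nodes by connective strength and
#' returns the top `r_define * N` most powerful nodes (with 90 nodes and
#' r = 2/15, the 12 strongest regions). Ties are broken by ascending node
#' index.
#'
#' @param hc_matrices List of control-group connectivity matrices.
#' @param nodes A [node_table()] supplying region labels.
#' @param r_define Richness factor defining the club (default 2/15).
#' @return Named integer vector of node indices (names are region labels).
#' @export
define_rich_club_nodes <- function(hc_matrices, nodes, r_define = 2 / 15) {
  if (length(hc_matrices) == 0) stopf("empty control group")
  n <- nrow(hc_matrices[[1]])
  sz <- r_define * n
  if (abs(sz - round(sz)) > 1e-9 || round(sz) < 1)
    stopf("r_define * N must be a positive integer")
  sz <- as.integer(round(sz))
  mean_mat <- Reduce(`+`, hc_matrices) / length(hc_matrices)
  rk <- strength_ranks(rowSums(mean_mat))
  idx <- which(rk <= sz)
  idx <- idx[order(rk[idx])]
  names(idx) <- nodes$label[idx]
  idx
}

#' Partition edges into rich-club, feeder and local classes
#'
#' Rich-club connections join two rich-club regions, feeder connections join
#' a rich-club region to a local (non-rich-club) region, and local
#' connections join two local regions. The connective average strength of a
#' class is its total weight divided by its connection count. Raw
#' (non-voxel-normalized) weights are used: normalization applies only to
#' the rich-club coefficient and node definition.
#'
#' @param w Connectivity matrix (raw weights).
#' @param rich_nodes Integer indices of the rich-club regions (nonempty
#'   proper subset of nodes).
#' @return An `edge_partition`: list with `rich_nodes`, `edges` (data.frame
#'   i, j, w, class), `class_average_strength`, `class_edge_count`,
#'   `class_total_weight` (each named by class; empty classes have NA
#'   average).
#' @export
partition_and_strengths <- function(w, rich_nodes) {
  n <- nrow(w)
  if (length(rich_nodes) == 0 || length(rich_nodes) >= n)
    stopf("rich_nodes must be a nonempty proper subset of the nodes")
  el <- edge_list(w)
  in_rich_i <- el$i %in% rich_nodes
  in_rich_j <- el$j %in% rich_nodes
  k <- in_rich_i + in_rich_j
  el$class <- c("local", "feeder", "rich_club")[k + 1L]
  classes <- c("rich_club", "feeder", "local")
  tot <- vapply(classes, function(cl) sum(el$w[el$class == cl]), 0)
  cnt <- vapply(classes, function(cl) sum(el$class == cl), 0L)
  avg <- ifelse(cnt > 0, tot / cnt, NA_real_)
  names(avg) <- classes
  structure(list(rich_nodes = rich_nodes, edges = el,
                 class_average_strength = avg,
                 class_edge_count = cnt, class_total_weight = tot),
            class = "edge_partition")
}

#' Consensus rich-club edges across subjects
#'
#' Among node pairs internal to the rich-club region, returns those present
#' in strictly more than `threshold` of the subjects ("more than 80%").
#'
#' @param matrices List of connectivity matrices.
#' @param rich_nodes Integer indices of rich-club regions.
#' @param threshold Fraction in (0,1); strict inequality.
#' @return Data frame with columns `i`, `j`, `prevalence`.
#' @export
richclub_edge_consensus <- function(matrices, rich_nodes, threshold = 0.80) {
  if (length(matrices) == 0) stopf("empty matrix list")
  count <- Reduce(`+`, lapply(matrices, function(w) w > 0))
  prev <- count / length(matrices)
  pairs <- t(utils::combn(sort(rich_nodes), 2))
  pv <- prev[pairs]
  keep <- pv > threshold
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2], prevalence = pv[keep])
}

#' Area under the normalized rich-club curve
#'
#' Integrates `phi_norm` over the richness-factor grid across defined
#' levels; undefined levels are excluded (their count is recorded by
#' [normalized_curve()]). Trapezoidal quadrature by default; a rectangle
#' (left Riemann) dialect is provided for sensitivity checks.
#'
#' @param curve A `rich_club_curve`.
#' @param method "trapezoid" (default) or "rectangle".
#' @return The area, a single number.
#' @export
curve_auc <- function(curve, method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  ok <- !is.na(curve$phi_norm)
  x <- curve$r[ok]; y <- curve$phi_norm[ok]
  if (length(x) < 2) stopf("AUC needs at least 2 defined levels")
  if (method == "trapezoid")
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  else
    sum(diff(x) * head(y, -1))
}
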