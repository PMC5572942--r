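## Global weighted-network properties of a single connectome, and the group
## prevalence filter applied before any metric is computed.
##
## Conventions (documented dialects):
##  * path length of an edge is the reciprocal weight 1/w ("reciprocal"
##    mapping used by the GRETNA toolkit for probability-weighted networks);
##  * clustering uses raw weights with the geometric-mean (cube-root) triangle
##    intensity, no max-weight rescaling;
##  * assortativity correlates node *connective strength* (not degree) across
##    linked node pairs.

#' Group prevalence filter
#'
#' Edges present (weight > 0) in fewer than `keep_threshold` of the group's
#' subjects are considered spurious and zeroed in every subject's matrix.
#' The boundary is kept: an edge present in exactly `keep_threshold` of
#' subjects survives ("present in less than the threshold" is removed).
#'
#' @param matrices List of connectivity matrices from one group.
#' @param keep_threshold Fraction in (0,1); default 0.20.
#' @return List with `matrices` (filtered) and `mask` (binary group mask).
#' @export
apply_prevalence_filter <- function(matrices, keep_threshold = 0.20) {
  if (length(matrices) == 0) stopf("empty matrix list")
  count <- Reduce(`+`, lapply(matrices, function(w) w > 0))
  mask <- (count / length(matrices)) >= keep_threshold
  storage.mode(mask) <- "double"
  list(matrices = lapply(matrices, function(w) w * mask), mask = mask)
}

node_degrees <- function(w) colSums(w > 0)

#' Global weighted clustering coefficient
#'
#' Per node i with degree \eqn{k_i \ge 2}, the triangle intensity
#' \eqn{2/(k_i(k_i-1)) \sum_{j<k} (w_{ij} w_{jk} w_{ki})^{1/3}} over neighbor
#' pairs joined by an edge; nodes with fewer than two neighbors contribute 0.
#' Returns the mean over all N nodes, on the raw weight scale.
#'
#' @param w Connectivity matrix.
#' @return Global clustering coefficient Cp.
#' @export
clustering_coefficient <- function(w) {
  n <- nrow(w)
  k <- node_degrees(w)
  w3 <- w^(1/3)
  tri2 <- diag(w3 %*% w3 %*% w3)  # 2 * sum over unordered neighbor pairs
  cp_i <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(cp_i)
}

graph_from_weights <- function(w) {
  el <- edge_list(w)
  igraph::graph_from_data_frame(
    data.frame(from = el$i, to = el$j, weight = 1 / el$w),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(w))))
}

#' Pairwise shortest path lengths
#'
#' Edge length is the reciprocal weight 1/w; \eqn{L_{ij}} is the minimal
#' total length over paths. Errors when the network is disconnected,
#' identifying the components (individual filtered brain networks are
#' expected to be connected).
#'
#' @param w Connectivity matrix.
#' @return N x N matrix of shortest path lengths (0 diagonal).
#' @export
shortest_path_lengths <- function(w) {
  g <- graph_from_weights(w)
  L <- igraph::distances(g, algorithm = "dijkstra")
  if (any(is.infinite(L))) {
    comp <- igraph::components(g)
    stopf("network is disconnected (%d components with sizes %s)",
          comp$no, paste(comp$csize, collapse = ", "))
  }
  L <- L[order(as.integer(rownames(L))), order(as.integer(colnames(L)))]
  dimnames(L) <- NULL
  L
}

#' Global shortest path length Lp
#' @param w Connectivity matrix.
#' @return Mean of \eqn{L_{ij}} over ordered pairs i != j.
#' @export
global_path_length <- function(w) {
  L <- shortest_path_lengths(w)
  n <- nrow(L)
  sum(L) / (n * (n - 1))
}

efficiency_from_weights <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  g <- graph_from_weights(w)
  L <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / L
  diag(inv) <- 0
  inv[is.infinite(L)] <- 0  # disconnected pairs contribute 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' \eqn{E_{glob} = [1/(N(N-1))] \sum_{i \ne j} 1/L_{ij}}, with disconnected
#' pairs contributing 0.
#' @param w Connectivity matrix.
#' @return Global efficiency.
#' @export
global_efficiency <- function(w) efficiency_from_weights(w)

#' Global fault-tolerant (local) efficiency
#'
#' For each node i, the global efficiency of the subgraph induced on i's
#' neighbors (i removed, original weights kept); nodes with fewer than two
#' neighbors contribute 0. Returns the mean over all nodes.
#' @param w Connectivity matrix.
#' @return Eloc.
#' @export
fault_tolerant_efficiency <- function(w) {
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_from_weights(w[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

#' Network connective strength
#'
#' Mean over nodes of the node strength (sum of weights incident to the
#' node); each undirected edge counts once per endpoint.
#' @param w Connectivity matrix.
#' @return S.
#' @export
network_strength <- function(w) mean(rowSums(w))

#' Weighted assortativity of connective strength
#'
#' Weight-weighted Pearson correlation of endpoint connective strengths over
#' the symmetrized ordered-pair expansion of the edges: with \eqn{k_i} the
#' node connective strength and H the total edge weight,
#' \deqn{r_\omega = \frac{H^{-1}\sum_\phi \omega_\phi k_i k_j -
#'   [H^{-1}\sum_\phi \omega_\phi (k_i+k_j)/2]^2}
#'  {H^{-1}\sum_\phi \omega_\phi (k_i^2+k_j^2)/2 -
#'   [H^{-1}\sum_\phi \omega_\phi (k_i+k_j)/2]^2}.}
#' When endpoint strengths carry no (weighted) variance the statistic is
#' undefined: the function warns and returns NA rather than a number.
#'
#' @param w Connectivity matrix with at least 2 edges.
#' @return \eqn{r_\omega} in \[-1, 1\], or NA (degenerate).
#' @export
weighted_assortativity <- function(w) {
  el <- edge_list(w)
  if (nrow(el) < 2) stopf("assortativity needs at least 2 edges")
  k <- rowSums(w)
  ki <- k[el$i]; kj <- k[el$j]; om <- el$w
  H <- sum(om)
  mu <- sum(om * (ki + kj) / 2) / H
  v <- sum(om * (ki^2 + kj^2) / 2) / H - mu^2
  if (v <= .Machine$double.eps * mu^2 * 100 || !is.finite(v) || v <= 0) {
    warning("assortativity undefined: zero weighted variance of endpoint strengths",
            call. = FALSE)
    return(NA_real_)
  }
  (sum(om * ki * kj) / H - mu^2) / v
}

#' Network density
#'
#' Fraction of present connections among the N(N-1)/2 possible ones.
#' @param w Connectivity matrix.
#' @return Density in \[0, 1\].
#' @export
network_density <- function(w) {
  n <- nrow(w)
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

#' Degree-preserving rewired null network
#'
#' Maslov-Sneppen double-edge swaps; each edge carries its weight through
#' the swap, so both the degree sequence and the multiset of edge weights
#' are preserved while the topology (and the pairing of weights with node
#' pairs) is randomized. Swaps creating multi-edges or self-loops are
#' rejected. On graphs admitting no swap (e.g. complete graphs) the input is
#' returned unchanged.
#'
#' @param w Connectivity matrix.
#' @param n_attempts Number of attempted swaps (default 10 per edge).
#' @return Rewired connectivity matrix.
#' @export
rewire_preserving_degree <- function(w, n_attempts = NULL) {
  el <- edge_list(w)
  m <- nrow(el)
  if (m < 2) return(w)
  if (is.null(n_attempts)) n_attempts <- 10L * m
  i <- el$i; j <- el$j; wt <- el$w
  A <- w > 0
  e1s <- sample.int(m, n_attempts, replace = TRUE)
  e2s <- sample.int(m, n_attempts, replace = TRUE)
  ors <- runif(n_attempts) < 0.5
  for (s in seq_len(n_attempts)) {
    e1 <- e1s[s]; e2 <- e2s[s]
    if (e1 == e2) next
    a <- i[e1]; b <- j[e1]; cc <- i[e2]; d <- j[e2]
    if (a == cc || a == d || b == cc || b == d) next
    if (ors[s]) { n1a <- a; n1b <- d; n2a <- cc; n2b <- b }
    else        { n1a <- a; n1b <- cc; n2a <- b;  n2b <- d }
    if (A[n1a, n1b] || A[n2a, n2b]) next
    A[a, b] <- A[b, a] <- FALSE; A[cc, d] <- A[d, cc] <- FALSE
    A[n1a, n1b] <- A[n1b, n1a] <- TRUE; A[n2a, n2b] <- A[n2b, n2a] <- TRUE
    i[e1] <- n1a; j[e1] <- n1b; i[e2] <- n2a; j[e2] <- n2b
  }
  edges_to_matrix(i, j, wt, nrow(w))
}

#' Small-world properties against rewired nulls
#'
#' Generates `n_null` degree-preserving rewired networks (weights carried
#' with edges) and returns \eqn{\gamma = Cp/\overline{Cp}_{rand}},
#' \eqn{\lambda = Lp/\overline{Lp}_{rand}} and \eqn{\sigma = \gamma/\lambda}.
#' For null networks a rewiring may in principle disconnect the graph; null
#' Lp then averages over connected pairs only. Deterministic given `seed`.
#'
#' @param w Connectivity matrix (connected).
#' @param n_null Number of rewired nulls.
#' @param seed Integer seed.
#' @return Named list `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(w, n_null = 1000L, seed = 1L) {
  cp <- clustering_coefficient(w)
  lp <- global_path_length(w)
  null_lp_mean <- function(m) {
    g <- graph_from_weights(m)
    L <- igraph::distances(g, algorithm = "dijkstra")
    fin <- is.finite(L) & row(L) != col(L)
    mean(L[fin])
  }
  cps <- numeric(n_null); lps <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nullm <- with_seed(derive_seed(seed, "small_world", b),
                       rewire_preserving_degree(w))
    cps[b] <- clustering_coefficient(nullm)
    lps[b] <- null_lp_mean(nullm)
  }
  gamma <- cp / mean(cps)
  lambda <- lp / mean(lps)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global network properties of one connectome
#'
#' Bundles Cp, Lp, S, E_glob, Eloc, assortativity, density and (optionally)
#' the small-world normalization into one row. The input is expected to be
#' prevalence-filtered at the group level.
#'
#' @param w Connectivity matrix.
#' @param config An [analysis_config()] supplying `n_null_smallworld` and the
#'   seed.
#' @param include_small_world Logical; compute gamma/lambda/sigma (the
#'   expensive part)?
#' @return One-row data.frame of class `global_metrics`.
#' @export
compute_global_metrics <- function(w, config = analysis_config(),
                                   include_small_world = TRUE) {
  out <- data.frame(
    cp = clustering_coefficient(w),
    lp = global_path_length(w),
    s = network_strength(w),
    e_glob = global_efficiency(w),
    e_loc = fault_tolerant_efficiency(w),
    r_assort = weighted_assortativity(w),
    density = network_density(w),
    gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  if (include_small_world) {
    sw <- small_world(w, n_null = config$n_null_smallworld, seed = config$seed)
    out$gamma <- sw$gamma; out$lambda <- sw$lambda; out$sigma <- sw$sigma
  }
  class(out) <- c("global_metrics", "data.frame")
  out
}
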