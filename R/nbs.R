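## Network-based statistic: edgewise two-sample t-maps on a prevalence
## mask, primary thresholding, connected-component extraction with
## sum-of-t ("intensity") component sizes, and max-component permutation
## FWER correction.

#' NBS prevalence mask
#'
#' An edge enters the mask iff it is present in at least `threshold` of the
#' subjects of either group ("either" is a union: an edge carried by one
#' group alone is still tested).
#'
#' @param group_a,group_b Lists of connectivity matrices.
#' @param threshold Per-group prevalence fraction (default 0.80).
#' @return Binary N x N mask matrix.
#' @export
nbs_mask <- function(group_a, group_b, threshold = 0.80) {
  if (length(group_a) == 0 || length(group_b) == 0) stopf("empty group")
  prev <- function(ms) Reduce(`+`, lapply(ms, function(w) w > 0)) / length(ms)
  mask <- (prev(group_a) >= threshold) | (prev(group_b) >= threshold)
  storage.mode(mask) <- "double"
  diag(mask) <- 0
  mask
}

## Subjects x edges matrix of masked upper-triangle weights.
edge_values <- function(matrices, idx) {
  t(vapply(matrices, function(w) w[idx], numeric(length(idx))))
}

## Vectorized pooled-variance two-sample t for rows of a permutation-
## indicator matrix U (n_perm x n, 1 = group A). X is n x E.
pooled_t_perm <- function(X, X2, U, n_a, n_b, tail) {
  tot <- colSums(X); tot2 <- colSums(X2)
  sa <- U %*% X            # n_perm x E group-A sums
  sa2 <- U %*% X2
  sb <- rep(1, nrow(U)) %o% tot - sa
  sb2 <- rep(1, nrow(U)) %o% tot2 - sa2
  ssa <- sa2 - sa^2 / n_a
  ssb <- sb2 - sb^2 / n_b
  sp2 <- (ssa + ssb) / (n_a + n_b - 2)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tv <- (sb / n_b - sa / n_a) / se
  tv[se <= 0 | !is.finite(tv)] <- NA_real_  # zero-variance: sub-threshold
  if (tail == "two_sided") tv <- abs(tv)
  tv
}

#' Edgewise two-sample t statistics
#'
#' Pooled-variance two-sample t per masked edge, oriented so that positive t
#' supports the one-tailed alternative: with `tail = "a_less_b"` (the
#' default, e.g. LLD-MD < LLD-IM) t is (mean B - mean A)/SE. With
#' `tail = "two_sided"` the absolute t is returned. Zero-variance edges get
#' NA (treated as sub-threshold downstream). A Welch (unequal-variance)
#' dialect is available; the pooled form is the NBS default.
#'
#' @param group_a,group_b Lists of connectivity matrices (>= 2 subjects
#'   each).
#' @param mask Binary mask matrix from [nbs_mask()].
#' @param tail "a_less_b" or "two_sided".
#' @param variance "pooled" (default) or "welch".
#' @return N x N symmetric matrix of t values (NA outside the mask), with
#'   attribute `df`.
#' @export
edgewise_t <- function(group_a, group_b, mask,
                       tail = c("a_less_b", "two_sided"),
                       variance = c("pooled", "welch")) {
  tail <- match.arg(tail); variance <- match.arg(variance)
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stopf("each group needs at least 2 subjects")
  n <- nrow(mask)
  idx <- which(upper.tri(mask) & mask > 0)
  Xa <- edge_values(group_a, idx)
  Xb <- edge_values(group_b, idx)
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- apply(Xa, 2, var); vb <- apply(Xb, 2, var)
  if (variance == "pooled") {
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(va / n_a + vb / n_b)
    df <- (va / n_a + vb / n_b)^2 /
      ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
    df <- mean(df[is.finite(df)])
  }
  tv <- (mb - ma) / se
  tv[se <= 0 | !is.finite(tv)] <- NA_real_
  if (tail == "two_sided") tv <- abs(tv)
  tmap <- matrix(NA_real_, n, n)
  tmap[idx] <- tv
  tmap[lower.tri(tmap)] <- t(tmap)[lower.tri(tmap)]
  attr(tmap, "df") <- df
  attr(tmap, "tail") <- tail
  tmap
}

## Connected components of an edge set by breadth-first search (union-find
## formulation); returns component id per edge.
edge_components <- function(ei, ej, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, 0L)
  match(roots, unique(roots))
}

#' Suprathreshold connected components
#'
#' The primary t threshold is the upper-tail critical value of the t
#' distribution at `primary_p` (one-tailed; for a two-sided map the
#' `primary_p/2` quantile is used on |t|). Edges with t strictly above the
#' threshold form the suprathreshold graph; its connected components are
#' extracted and sized by intensity, \eqn{M = \sum t} over the component's
#' edges (an edge-count "extent" dialect is available).
#'
#' @param t_map Symmetric t matrix from [edgewise_t()].
#' @param primary_p Primary p-value threshold (default 0.01).
#' @param df Degrees of freedom (defaults to the t_map attribute).
#' @param size "intensity" (sum of t, default) or "extent" (edge count).
#' @return List of components, each `list(edges = data.frame(i, j, t),
#'   nodes, size)`, sorted by decreasing size; empty list when no edge
#'   survives.
#' @export
suprathreshold_components <- function(t_map, primary_p = 0.01, df = NULL,
                                      size = c("intensity", "extent")) {
  size <- match.arg(size)
  if (is.null(df)) df <- attr(t_map, "df")
  if (is.null(df) || df < 1) stopf("df must be >= 1")
  tail <- attr(t_map, "tail")
  p_eff <- if (!is.null(tail) && tail == "two_sided") primary_p / 2 else primary_p
  tcrit <- qt(1 - p_eff, df)
  n <- nrow(t_map)
  ut <- upper.tri(t_map)
  sel <- which(ut & !is.na(t_map) & t_map > tcrit)
  if (length(sel) == 0) return(structure(list(), t_threshold = tcrit))
  ei <- row(t_map)[sel]; ej <- col(t_map)[sel]; tv <- t_map[sel]
  comp <- edge_components(ei, ej, n)
  comps <- lapply(seq_len(max(comp)), function(cid) {
    inx <- comp == cid
    list(edges = data.frame(i = ei[inx], j = ej[inx], t = tv[inx]),
         nodes = sort(unique(c(ei[inx], ej[inx]))),
         size = if (size == "intensity") sum(tv[inx]) else sum(inx))
  })
  comps <- comps[order(-vapply(comps, `[[`, 0, "size"))]
  structure(comps, t_threshold = tcrit)
}

#' Network-based statistic with permutation FWER correction
#'
#' Computes the observed edgewise t-map on the NBS prevalence mask,
#' extracts suprathreshold components, then permutes group labels
#' `n_perm_nbs` times; every permutation reuses the same mask and t
#' threshold, and the largest component size M (0 when none) is recorded to
#' form the null distribution. The FWER-corrected p-value of an observed
#' component is \eqn{(1 + \#\{M_{null} \ge M_{obs}\}) / (1 + n_{perm})};
#' the observed labeling is not included as a permutation (the +1 plays
#' that role). Deterministic given the config seed.
#'
#' @param group_a,group_b Lists of connectivity matrices.
#' @param config An [analysis_config()] (`n_perm_nbs`, `nbs_mask_threshold`,
#'   `nbs_primary_p`, `alpha`, seed).
#' @param tail "a_less_b" (positive t means group A < group B) or
#'   "two_sided".
#' @param mask Optional pre-computed mask (defaults to [nbs_mask()]).
#' @param size "intensity" or "extent" component sizing.
#' @return An `nbs_result`: list with `mask`, `t_map`,
#'   `primary_t_threshold`, `components`, `null_max_sizes`, `corrected_p`,
#'   `significant` (indices of components with corrected p < alpha), `df`,
#'   `n_perm`.
#' @export
nbs_permutation <- function(group_a, group_b, config = analysis_config(),
                            tail = c("a_less_b", "two_sided"), mask = NULL,
                            size = c("intensity", "extent")) {
  tail <- match.arg(tail); size <- match.arg(size)
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stopf("each group needs at least 2 subjects")
  if (is.null(mask)) mask <- nbs_mask(group_a, group_b, config$nbs_mask_threshold)
  nn <- nrow(mask)
  t_map <- edgewise_t(group_a, group_b, mask, tail = tail)
  df <- attr(t_map, "df")
  comps <- suprathreshold_components(t_map, config$nbs_primary_p, df, size = size)
  tcrit <- attr(comps, "t_threshold")

  idx <- which(upper.tri(mask) & mask > 0)
  X <- rbind(edge_values(group_a, idx), edge_values(group_b, idx))
  X2 <- X^2
  n <- n_a + n_b
  n_perm <- config$n_perm_nbs
  ei <- row(mask)[idx]; ej <- col(mask)[idx]
  null_max <- numeric(n_perm)
  block <- 500L
  for (start in seq(1L, n_perm, by = block)) {
    ids <- start:min(start + block - 1L, n_perm)
    U <- matrix(0, length(ids), n)
    for (k in seq_along(ids)) {
      pick <- with_seed(derive_seed(config$seed, "nbs_perm", ids[k]),
                        sample.int(n, n_a))
      U[k, pick] <- 1
    }
    TV <- pooled_t_perm(X, X2, U, n_a, n_b, tail)
    for (k in seq_along(ids)) {
      sel <- which(!is.na(TV[k, ]) & TV[k, ] > tcrit)
      if (length(sel) == 0) next
      comp <- edge_components(ei[sel], ej[sel], nn)
      null_max[ids[k]] <- if (size == "intensity")
        max(rowsum(TV[k, sel], comp)) else max(tabulate(comp))
    }
  }
  M_obs <- vapply(comps, `[[`, 0, "size")
  corrected_p <- vapply(M_obs, function(m) (1 + sum(null_max >= m)) / (1 + n_perm), 0)
  structure(list(mask = mask, t_map = t_map, primary_t_threshold = tcrit,
                 components = comps, null_max_sizes = null_max,
                 corrected_p = corrected_p,
                 significant = which(corrected_p < config$alpha),
                 df = df, n_perm = n_perm, tail = tail),
            class = "nbs_result")
}

#' Edge table of an NBS result
#'
#' @param result An `nbs_result`.
#' @param labels Optional character vector of region labels (e.g.
#'   `node_table$label`); bare indices are used otherwise.
#' @return Data frame with node labels, t value, component id and corrected
#'   p per suprathreshold edge (header-only when no component).
#' @export
nbs_edge_table <- function(result, labels = NULL) {
  rows <- lapply(seq_along(result$components), function(cid) {
    e <- result$components[[cid]]$edges
    data.frame(node_i = if (is.null(labels)) as.character(e$i) else labels[e$i],
               node_j = if (is.null(labels)) as.character(e$j) else labels[e$j],
               t = e$t, component = cid,
               corrected_p = result$corrected_p[cid])
  })
  if (length(rows) == 0)
    return(data.frame(node_i = character(), node_j = character(),
                      t = numeric(), component = integer(),
                      corrected_p = numeric()))
  do.call(rbind, rows)
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d masked edges, t* = %.3f (df = %.1f), %d permutations\n",
              sum(x$mask[upper.tri(x$mask)] > 0), x$primary_t_threshold,
              x$df, x$n_perm))
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cmp <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, %d nodes, M = %.2f, corrected p = %.4g%s\n",
                  k, nrow(cmp$edges), length(cmp$nodes), cmp$size,
                  x$corrected_p[k],
                  if (k %in% x$significant) " *" else ""))
    }
  }
  invisible(x)
}
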