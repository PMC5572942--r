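## Independent brute-force oracles for the graph metrics, the rich-club
## coefficient and NBS component sizes. Deliberately naive: exhaustive
## enumeration over nodes, triples and simple paths, usable up to ~8 nodes.

## random symmetric weighted graph (guaranteed connected via a random
## spanning tree), weights distinct with probability 1
rnd_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  perm <- sample(n)
  for (k in 2:n) {  # spanning tree keeps the graph connected
    a <- perm[k]; b <- perm[sample(k - 1, 1)]
    w[a, b] <- w[b, a] <- runif(1, 0.1, 1)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] == 0 && runif(1) < density)
      w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
  }
  w
}

bf_strength <- function(w) {
  n <- nrow(w); tot <- 0
  for (i in 1:n) for (j in 1:n) tot <- tot + w[i, j]
  tot / n
}

bf_density <- function(w) {
  n <- nrow(w); cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (w[i, j] > 0) cnt <- cnt + 1
  cnt / (n * (n - 1) / 2)
}

bf_clustering <- function(w) {
  n <- nrow(w)
  cp <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:n) for (l in 1:n) {
      if (j != l && j != i && l != i && w[i, j] > 0 && w[j, l] > 0 && w[l, i] > 0)
        acc <- acc + (w[i, j] * w[j, l] * w[l, i])^(1 / 3)
    }
    cp[i] <- acc / (k * (k - 1))  # ordered triples counted twice = 2/(k(k-1)) * unordered
  }
  mean(cp)
}

## all-pairs shortest 1/w path lengths by exhaustive simple-path enumeration
bf_shortest_paths <- function(w) {
  n <- nrow(w)
  best <- matrix(Inf, n, n); diag(best) <- 0
  recurse <- function(node, target, visited, len) {
    if (node == target) {
      if (len < best[visited[1], target]) best[visited[1], target] <<- len
      return()
    }
    for (nb in which(w[node, ] > 0)) {
      if (!(nb %in% visited))
        recurse(nb, target, c(visited, nb), len + 1 / w[node, nb])
    }
  }
  for (i in 1:n) for (j in 1:n) if (i != j) recurse(i, j, i, 0)
  best
}

bf_lp <- function(w) {
  L <- bf_shortest_paths(w); n <- nrow(w)
  sum(L[row(L) != col(L)]) / (n * (n - 1))
}

bf_eglob <- function(w) {
  L <- bf_shortest_paths(w); n <- nrow(w)
  inv <- 1 / L; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_eloc <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in 1:n) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- bf_eglob(w[nb, nb, drop = FALSE])
  }
  mean(vals)
}

## weighted Pearson correlation over both ordered endpoint pairs per edge
bf_assort <- function(w) {
  n <- nrow(w)
  k <- rowSums(w)
  x <- c(); y <- c(); om <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (w[i, j] > 0) {
    x <- c(x, k[i], k[j]); y <- c(y, k[j], k[i]); om <- c(om, w[i, j], w[i, j])
  }
  mx <- sum(om * x) / sum(om)
  my <- sum(om * y) / sum(om)
  cov <- sum(om * (x - mx) * (y - my)) / sum(om)
  vx <- sum(om * (x - mx)^2) / sum(om)
  vy <- sum(om * (y - my)^2) / sum(om)
  cov / sqrt(vx * vy)
}

## rich-club coefficient straight from its definition
bf_phi <- function(w, r) {
  n <- nrow(w)
  sz <- round(r * n)
  s <- rowSums(w)
  ord <- order(-s, seq_len(n))
  club <- ord[seq_len(sz)]
  ww <- c()
  for (a in seq_along(club)) for (b in seq_along(club)) {
    if (a < b && w[club[a], club[b]] > 0) ww <- c(ww, w[club[a], club[b]])
  }
  if (length(ww) == 0) return(NA_real_)
  all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  sum(ww) / sum(all_w[seq_along(ww)])
}

## connected components of an edge list by repeated flood fill; returns the
## per-edge component label and per-component sum of values
bf_components <- function(ei, ej, val) {
  nodes <- sort(unique(c(ei, ej)))
  comp_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0
  for (start in nodes) {
    if (!is.na(comp_of[as.character(start)])) next
    cid <- cid + 1
    frontier <- start
    while (length(frontier)) {
      comp_of[as.character(frontier)] <- cid
      nxt <- c()
      for (f in frontier) {
        nbs <- c(ej[ei == f], ei[ej == f])
        nxt <- c(nxt, nbs[is.na(comp_of[as.character(nbs)])])
      }
      frontier <- unique(nxt)
    }
  }
  edge_comp <- comp_of[as.character(ei)]
  sizes <- tapply(val, edge_comp, sum)
  list(edge_comp = unname(edge_comp), sizes = as.numeric(sizes))
}
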