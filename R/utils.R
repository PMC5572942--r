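## Internal helpers: seeded RNG streams, edge-list conversion, validation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded package
#' operations never perturb the user's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-stream seed from a base seed and operation name
#'
#' Each randomized stage draws from its own stream so that re-running any
#' single stage reproduces it exactly, independent of stage order.
#' @noRd
derive_seed <- function(seed, op, index = 0L) {
  h <- 0
  for (c in utf8ToInt(op)) h <- (h * 131 + c) %% 1048573
  as.integer((abs(as.numeric(seed)) * 7919 + h * 31 + index) %% 2147483629)
}

## Upper-triangle edge list of a symmetric matrix: data.frame(i, j, w)
edge_list <- function(w, keep_zero = FALSE) {
  n <- nrow(w)
  ut <- upper.tri(w)
  idx <- which(ut, arr.ind = TRUE)
  wt <- w[ut]
  if (!keep_zero) {
    nz <- wt > 0
    idx <- idx[nz, , drop = FALSE]
    wt <- wt[nz]
  }
  data.frame(i = idx[, 1], j = idx[, 2], w = wt)
}

## Rebuild a symmetric zero-diagonal matrix from an edge list
edges_to_matrix <- function(i, j, w, n) {
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- w
  m[cbind(j, i)] <- w
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
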