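## Small named graphs used across the metric and rich-club tests.

complete_graph <- function(n, weight = 1) {
  w <- matrix(weight, n, n); diag(w) <- 0; w
}

path_graph <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  for (k in 1:(n - 1)) w[k, k + 1] <- w[k + 1, k] <- weight
  w
}

star_graph <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- weight
  w
}

ring_lattice <- function(n, k = 4, weight = 1) {
  w <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:(k / 2)) {
    j <- ((i + d - 1) %% n) + 1
    w[i, j] <- w[j, i] <- weight
  }
  w
}

## small default-structure cohort for pipeline-level tests
small_cohort <- function(seed = 1, n_per_group = c(4L, 5L, 6L)) {
  generate_cohort(simulation_config(seed = seed, n_per_group = n_per_group))
}
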