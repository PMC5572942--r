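test_that("prevalence filter keeps the boundary and zeroes rare edges", {
  mk <- function(on) { w <- matrix(0, 4, 4); if (on) w[1, 2] <- w[2, 1] <- 0.5
                       w[3, 4] <- w[4, 3] <- 1; w }
  mats <- c(lapply(1:2, function(i) mk(TRUE)), lapply(3:10, function(i) mk(FALSE)))
  out <- apply_prevalence_filter(mats, 0.20)
  expect_equal(out$mask[1, 2], 1)  # present in exactly 20%: kept
  expect_equal(out$mask[3, 4], 1)  # present in all: kept
  mats1 <- c(lapply(1, function(i) mk(TRUE)), lapply(2:10, function(i) mk(FALSE)))
  out1 <- apply_prevalence_filter(mats1, 0.20)
  expect_equal(out1$mask[1, 2], 0)  # present in 10% < 20%: removed
  expect_true(all(vapply(out1$matrices, function(w) w[1, 2], 0) == 0))
  expect_error(apply_prevalence_filter(list(), 0.2), "empty")
})

test_that("metric identities hold on canonical graphs", {
  tri <- complete_graph(3)
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(clustering_coefficient(path_graph(4)), 0)

  K5 <- complete_graph(5)
  expect_equal(global_path_length(K5), 1)
  expect_equal(global_efficiency(K5), 1)
  expect_equal(fault_tolerant_efficiency(K5), 1)
  expect_equal(network_density(K5), 1)
  expect_equal(network_strength(K5), 4)

  two <- matrix(0, 2, 2); two[1, 2] <- two[2, 1] <- 0.5
  expect_equal(global_path_length(two), 2)  # 1/0.5

  expect_equal(fault_tolerant_efficiency(star_graph(6)), 0)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(global_efficiency(iso), 1 / 3)  # disconnected pairs give 0

  expect_equal(network_density(path_graph(4)), 0.5)
  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 0.5
  expect_equal(network_strength(one), 1 / 3)

  expect_error(shortest_path_lengths(iso), "disconnected")
})

test_that("assortativity handles aligned and degenerate strength structure", {
  ## two disjoint uniform cliques of different weight: endpoint strengths
  ## equal within every edge, nonzero spread across edges -> r = 1
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.2; w[4:6, 4:6] <- 0.9; diag(w) <- 0
  expect_equal(weighted_assortativity(w), 1)
  expect_warning(r <- weighted_assortativity(complete_graph(5, 0.3)), "undefined")
  expect_true(is.na(r))
  expect_error(weighted_assortativity(matrix(0, 3, 3)), "2 edges")
})

test_that("metrics match brute-force oracles on random small graphs", {
  for (s in 1:30) {
    w <- rnd_graph(sample(4:8, 1), runif(1, 0.3, 0.9), seed = s)
    expect_equal(network_strength(w), bf_strength(w), tolerance = 1e-12)
    expect_equal(network_density(w), bf_density(w), tolerance = 1e-12)
    expect_equal(clustering_coefficient(w), bf_clustering(w), tolerance = 1e-12)
    expect_equal(global_path_length(w), bf_lp(w), tolerance = 1e-12)
    expect_equal(global_efficiency(w), bf_eglob(w), tolerance = 1e-12)
    expect_equal(fault_tolerant_efficiency(w), bf_eloc(w), tolerance = 1e-12)
    expect_equal(weighted_assortativity(w), bf_assort(w), tolerance = 1e-12)
  }
})

test_that("uniform weight scaling transforms metrics as expected", {
  w <- rnd_graph(8, 0.6, seed = 42)
  c0 <- 3.7
  ws <- w * c0
  expect_equal(network_strength(ws), c0 * network_strength(w))
  expect_equal(global_path_length(ws), global_path_length(w) / c0)
  expect_equal(global_efficiency(ws), c0 * global_efficiency(w))
  expect_equal(clustering_coefficient(ws), c0 * clustering_coefficient(w))
  expect_equal(network_density(ws), network_density(w))
  expect_equal(weighted_assortativity(ws), weighted_assortativity(w))
})

test_that("adding an edge never decreases density or global efficiency", {
  w <- rnd_graph(7, 0.4, seed = 3)
  gap <- which(w == 0 & upper.tri(w), arr.ind = TRUE)[1, ]
  w2 <- w; w2[gap[1], gap[2]] <- w2[gap[2], gap[1]] <- 0.5
  expect_gte(network_density(w2), network_density(w))
  expect_gte(global_efficiency(w2), global_efficiency(w))
})

test_that("rewired nulls preserve degrees and the weight multiset", {
  w <- rnd_graph(8, 0.5, seed = 7)
  for (s in 1:5) {
    set.seed(s)
    nl <- rewire_preserving_degree(w)
    expect_equal(colSums(nl > 0), colSums(w > 0))
    expect_equal(sort(nl[upper.tri(nl)][nl[upper.tri(nl)] > 0]),
                 sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
    expect_equal(nl, t(nl))
  }
})

test_that("small-world normalization behaves on degenerate and lattice graphs", {
  sw <- small_world(complete_graph(8), n_null = 5, seed = 1)
  expect_equal(sw$gamma, 1)  # complete graph admits no swap
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  w <- rnd_graph(8, 0.5, seed = 11)
  sw1 <- small_world(w, n_null = 1, seed = 3)
  expect_equal(sw1$sigma, sw1$gamma / sw1$lambda)
  expect_identical(small_world(w, n_null = 3, seed = 5),
                   small_world(w, n_null = 3, seed = 5))

  ## clustered ring lattice: clustering well above its rewired nulls
  rl <- ring_lattice(20, k = 4)
  diag(rl) <- 0
  swl <- small_world(rl, n_null = 30, seed = 2)
  expect_gt(swl$gamma, 1)
})

test_that("compute_global_metrics bundles the panel and flags errors", {
  gm <- suppressWarnings(compute_global_metrics(complete_graph(6),
                                                analysis_config(n_null_smallworld = 3)))
  expect_s3_class(gm, "global_metrics")
  expect_equal(gm$cp, 1); expect_equal(gm$lp, 1); expect_equal(gm$s, 5)
  expect_equal(gm$e_glob, 1); expect_equal(gm$e_loc, 1)
  expect_equal(gm$density, 1); expect_equal(gm$sigma, 1)
  expect_true(is.na(gm$r_assort))
  expect_error(suppressWarnings(compute_global_metrics(matrix(0, 5, 5))),
               "no edges|disconnected")
})
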