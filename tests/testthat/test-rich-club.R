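test_that("voxel normalization divides out mask-size effects", {
  ## hand evaluation: 0.02 / ((500/1e5) * (250/1e5)) = 1600
  w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 0.02
  nt <- node_table(c("a", "b"), c("left", "right"), c(500, 250), 100000)
  expect_equal(voxel_normalize(w, nt)[1, 2], 1600)

  ## uniform voxel fraction is a pure rescaling: rankings unchanged
  g <- rnd_graph(6, 0.6, seed = 9)
  ntu <- node_table(letters[1:6], rep(c("left", "right"), 3), rep(300, 6), 30000)
  nw <- voxel_normalize(g, ntu)
  expect_equal(nw, g / (300 / 30000)^2)
  expect_equal(order(rowSums(nw)), order(rowSums(g)))
  expect_true(all(nw[g == 0] == 0))

  bad <- node_table(letters[1:6], rep("left", 6), rep(300, 6), 30000)
  bad$voxel_count[1] <- 0L
  expect_error(voxel_normalize(g, bad), "positive")
})

test_that("rich-club coefficient follows its ranked subset-sum definition", {
  expect_equal(rich_club_coefficient(complete_graph(6), 2 / 6), 1)
  expect_equal(rich_club_coefficient(complete_graph(6, 0.3), 3 / 6), 1)

  ## star: the hub alone has the top strength, no internal edges
  expect_true(is.na(rich_club_coefficient(star_graph(6), 1 / 6)))

  expect_error(rich_club_coefficient(complete_graph(6), 0.3), "integer")

  for (s in 1:25) {
    w <- rnd_graph(sample(c(4, 6, 8), 1), runif(1, 0.4, 0.9), seed = 100 + s)
    n <- nrow(w)
    for (k in 1:(n - 1)) {
      expect_equal(rich_club_coefficient(w, k / n), bf_phi(w, k / n),
                   tolerance = 1e-12)
    }
  }
})

test_that("phi stays in [0, 1] wherever defined", {
  for (s in 1:20) {
    w <- rnd_graph(7, runif(1, 0.3, 0.9), seed = 200 + s)
    for (k in 1:6) {
      phi <- rich_club_coefficient(w, k / 7)
      if (!is.na(phi)) { expect_gte(phi, 0); expect_lte(phi, 1) }
    }
  }
})

test_that("weight-reshuffle nulls keep topology and weight multiset", {
  w <- rnd_graph(8, 0.5, seed = 4)
  nulls <- reshuffled_nulls(w, 10, seed = 2)
  for (nl in nulls) {
    expect_equal(nl > 0, w > 0)
    expect_equal(sum(nl), sum(w))
    expect_equal(sort(nl[upper.tri(nl)]), sort(w[upper.tri(w)]))
  }
  ## uniform weights: every null is the original
  u <- complete_graph(5, 0.2)
  expect_true(all(vapply(reshuffled_nulls(u, 5, 1), identical, TRUE, u)))
})

test_that("reshuffle null mean matches the exhaustive permutation expectation", {
  ## 5-node graph with 6 edges: all 720 weight permutations enumerable
  w <- matrix(0, 5, 5)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 5), c(4, 5))
  wts <- c(0.9, 0.8, 0.15, 0.3, 0.45, 0.6)
  for (k in 1:6) { w[edges[k, 1], edges[k, 2]] <- wts[k]
                   w[edges[k, 2], edges[k, 1]] <- wts[k] }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  ## undefined draws (top-2 club without an internal edge) are excluded on
  ## both sides, mirroring how the curve averages its nulls
  exact <- mean(apply(perms, 1, function(p) {
    wp <- w; for (k in 1:6) { wp[edges[k, 1], edges[k, 2]] <- wts[p[k]]
                              wp[edges[k, 2], edges[k, 1]] <- wts[p[k]] }
    rich_club_coefficient(wp, 2 / 5)
  }), na.rm = TRUE)
  nulls <- reshuffled_nulls(w, 2000, seed = 6)
  sim <- vapply(nulls, rich_club_coefficient, 0, r = 2 / 5)
  se <- sd(sim, na.rm = TRUE) / sqrt(sum(!is.na(sim)))
  expect_lt(abs(mean(sim, na.rm = TRUE) - exact), 3 * se + 1e-12)
})

test_that("normalized curves evaluate the full richness grid", {
  gen <- small_cohort(seed = 3)
  w <- voxel_normalize(gen$cohort$matrices[[1]], gen$cohort$node_tables[[1]])
  cv <- normalized_curve(w, analysis_config(seed = 1, n_null_richclub = 50))
  expect_equal(nrow(cv), 14)
  expect_equal(cv$r, (1:14) / 15)
  expect_equal(cv$club_size, 6 * (1:14))
  expect_equal(cv$phi_norm, cv$phi / cv$phi_random_mean)
  expect_equal(attr(cv, "n_nulls"), 50L)

  ## uniform complete graph: phi_norm identically 1
  cvu <- normalized_curve(complete_graph(90, 0.5),
                          analysis_config(seed = 1, n_null_richclub = 20))
  expect_equal(cvu$phi_norm, rep(1, 14))

  ## phi_norm invariant to uniform weight scaling (same seed, same nulls)
  cv2 <- normalized_curve(w * 7.3, analysis_config(seed = 1, n_null_richclub = 50))
  expect_equal(cv2$phi_norm, cv$phi_norm, tolerance = 1e-12)

  expect_error(normalized_curve(rnd_graph(8, 0.5), analysis_config()),
               "denominator")
})

test_that("curve nulls agree with the matrix-level reshuffle path", {
  gen <- small_cohort(seed = 8)
  w <- voxel_normalize(gen$cohort$matrices[[5]], gen$cohort$node_tables[[5]])
  cfg <- analysis_config(seed = 11, n_null_richclub = 20)
  cv <- normalized_curve(w, cfg)
  nulls <- reshuffled_nulls(w, 20, seed = 11)
  direct <- rowMeans(vapply(nulls, function(m)
    vapply(1:14, function(k) rich_club_coefficient(m, k / 15), 0), numeric(14)),
    na.rm = TRUE)
  expect_equal(cv$phi_random_mean, direct, tolerance = 1e-12)
  expect_equal(cv$phi,
               vapply(1:14, function(k) rich_club_coefficient(w, k / 15), 0),
               tolerance = 1e-12)
})

test_that("rich-club regions come from the control group's mean network", {
  gen <- small_cohort(seed = 2)
  ch <- gen$cohort
  hc <- which(ch$subjects$group == "HC")
  nm <- lapply(hc, function(k) voxel_normalize(ch$matrices[[k]], ch$node_tables[[k]]))
  rn <- define_rich_club_nodes(nm, ch$node_tables[[hc[1]]], 2 / 15)
  expect_length(rn, 12)
  expect_named(rn)
  expect_setequal(unname(rn), gen$truth$hub_nodes)

  ## all-equal strengths: documented tie-break takes the first indices
  ties <- complete_graph(90, 0.4)
  ntu <- node_table(default_labels(90), rep(c("left", "right"), 45),
                    rep(500, 90), 60000)
  expect_equal(unname(define_rich_club_nodes(list(ties), ntu, 2 / 15)), 1:12)
  expect_error(define_rich_club_nodes(list(), ntu), "empty")
})

test_that("edge partition classifies and averages per class", {
  w <- matrix(0, 6, 6)
  w[1, 2] <- 0.6; w[1, 3] <- 0.2; w[2, 4] <- 0.4; w[3, 4] <- 0.1
  w[4, 5] <- 0.3; w[5, 6] <- 0.5
  w <- w + t(w)
  part <- partition_and_strengths(w, rich_nodes = c(1, 2))
  expect_equal(sum(part$class_edge_count), 6)
  ## hand enumeration: rich 1-2 (0.6); feeder 1-3, 2-4 (0.2, 0.4);
  ## local 3-4, 4-5, 5-6 (0.1, 0.3, 0.5)
  expect_equal(unname(part$class_edge_count), c(1L, 2L, 3L))
  expect_equal(unname(part$class_average_strength["rich_club"]), 0.6)
  expect_equal(unname(part$class_average_strength["feeder"]), mean(c(0.2, 0.4)))
  expect_equal(unname(part$class_average_strength["local"]), mean(c(0.1, 0.3, 0.5)))
  expect_error(partition_and_strengths(w, integer()), "proper subset")
  expect_error(partition_and_strengths(w, 1:6), "proper subset")
})

test_that("consensus rich-club edges require strictly more than the threshold", {
  mk <- function(with12) { w <- matrix(0, 5, 5)
    if (with12) { w[1, 2] <- w[2, 1] <- 1 }
    w[1, 3] <- w[3, 1] <- 1; w
  }
  mats <- c(lapply(1:4, function(i) mk(TRUE)), list(mk(FALSE)))
  ## edge 1-2 present in 4/5 = 80%: NOT selected at threshold 0.8
  sel <- richclub_edge_consensus(mats, c(1, 2, 3), threshold = 0.8)
  expect_false(any(sel$i == 1 & sel$j == 2))
  ## edge 1-3 in 100%: selected
  expect_true(any(sel$i == 1 & sel$j == 3))
  sel2 <- richclub_edge_consensus(mats, c(1, 2, 3), threshold = 0.7)
  expect_true(any(sel2$i == 1 & sel2$j == 2))
})

test_that("curve AUC integrates phi_norm over defined levels", {
  mkcurve <- function(phi_norm) {
    structure(data.frame(level = 1:14, r = (1:14) / 15, club_size = 6 * (1:14),
                         phi = phi_norm, phi_random_mean = 1,
                         phi_norm = phi_norm),
              class = c("rich_club_curve", "data.frame"))
  }
  expect_equal(curve_auc(mkcurve(rep(2.5, 14))), 2.5 * 13 / 15)
  lin <- 1 + (1:14) / 15
  expect_equal(curve_auc(mkcurve(lin)),
               sum(diff((1:14) / 15) * (head(lin, -1) + tail(lin, -1)) / 2))
  expect_equal(curve_auc(mkcurve(rep(2, 14)), method = "rectangle"), 2 * 13 / 15)
  ## independent numeric integration on a seeded synthetic curve
  gen <- small_cohort(seed = 6)
  w <- voxel_normalize(gen$cohort$matrices[[2]], gen$cohort$node_tables[[2]])
  cv <- normalized_curve(w, analysis_config(seed = 2, n_null_richclub = 30))
  ok <- !is.na(cv$phi_norm)
  expect_equal(curve_auc(cv),
               stats::integrate(stats::approxfun(cv$r[ok], cv$phi_norm[ok]),
                                min(cv$r[ok]), max(cv$r[ok]),
                                subdivisions = 1000L)$value,
               tolerance = 1e-4)
  one <- mkcurve(c(2, rep(NA, 13)))
  expect_error(curve_auc(one), "2 defined levels")
})
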