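toy_raw <- function() {
  data.frame(
    tmt_a = c(50, 60, 70, 55, 65, 75), tmt_b = c(120, 150, 200, 130, 170, 210),
    stroop_a = c(25, 30, 35, 27, 32, 37), stroop_c = c(60, 75, 95, 65, 80, 100),
    dst_forward = c(8, 7, 6, 8, 7, 6), dst_backward = c(6, 4, 3, 5, 4, 3),
    sdmt = c(40, 30, 20, 38, 28, 18),
    avlt_n1 = c(6, 4, 2, 5, 4, 3), avlt_n2 = c(7, 5, 3, 6, 5, 4),
    avlt_n3 = c(8, 6, 4, 7, 6, 5), avlt_n4 = c(8, 6, 4, 7, 6, 5),
    avlt_n5 = c(9, 6, 3, 8, 6, 4), lmt = c(12, 8, 4, 11, 8, 5))
}

test_that("composites are z-averages with reversal, robust to missingness", {
  raw <- toy_raw()
  comp <- cognitive_composites(raw)

  ## spreadsheet-style oracle
  z <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  exec_hand <- rowMeans(cbind(-z(raw$tmt_b - raw$tmt_a),
                              -z(raw$stroop_c - raw$stroop_a),
                              z(raw$dst_backward - raw$dst_forward)))
  speed_hand <- rowMeans(cbind(-z(raw$stroop_a), -z(raw$tmt_a), z(raw$sdmt)))
  mem_hand <- rowMeans(cbind(z(rowMeans(raw[, paste0("avlt_n", 1:5)])), z(raw$lmt)))
  expect_equal(comp$executive, exec_hand)
  expect_equal(comp$speed, speed_hand)
  expect_equal(comp$memory, mem_hand)

  ## a subject at the sample mean of every raw test scores 0 on all three
  ## composites (means of differences equal differences of means)
  raw0 <- rbind(raw, as.list(colMeans(raw)))
  comp0 <- cognitive_composites(raw0, standardization_sample = 1:6)
  expect_equal(unlist(comp0[7, ]), c(executive = 0, speed = 0, memory = 0),
               tolerance = 1e-12)

  ## slowing TMT-B strictly lowers executive function
  raw2 <- raw; raw2$tmt_b[1] <- raw2$tmt_b[1] + 40
  comp2 <- cognitive_composites(raw2)
  expect_lt(comp2$executive[1], comp$executive[1])

  ## pairwise missing: TMT-less subject still gets an executive composite
  raw3 <- raw; raw3$tmt_a[2] <- NA; raw3$tmt_b[2] <- NA
  comp3 <- cognitive_composites(raw3)
  expect_false(is.na(comp3$executive[2]))
  expect_equal(comp3$executive[2],
               mean(c(-z(raw3$stroop_c - raw3$stroop_a)[2],
                      z(raw3$dst_backward - raw3$dst_forward)[2])))

  ## affine rescaling of any raw test is absorbed by z-scoring
  raw4 <- raw; raw4$sdmt <- raw4$sdmt * 3 + 10
  expect_equal(cognitive_composites(raw4)$speed, comp$speed, tolerance = 1e-12)

  rawc <- raw; rawc$sdmt <- 5
  expect_error(cognitive_composites(rawc), "zero variance")
})

test_that("memory status uses the stratum cutoff and refuses missing strata", {
  expect_equal(classify_memory_status(55, 9, 4), "memory_deficit")
  expect_equal(classify_memory_status(55, 9, 5), "intact")
  expect_error(classify_memory_status(85, 9, 4), "no norm-table stratum")
  tab <- rbind(default_avlt_norms(),
               data.frame(age_min = 60, age_max = 79, edu_min = 0,
                          edu_max = Inf, cutoff = 5))
  expect_equal(classify_memory_status(c(55, 70, 70), c(9, 9, 9), c(5, 5, 6), tab),
               c("intact", "memory_deficit", "intact"))
})

test_that("adjusted permutation tests are seeded, calibrated reductions", {
  set.seed(10)
  n <- c(15, 24, 30)
  groups <- rep(c("A", "B", "C"), n)
  covs <- data.frame(age = rnorm(sum(n), 65, 5),
                     gender = sample(c("M", "F"), sum(n), TRUE))
  vals <- rnorm(sum(n))

  r1 <- adjusted_permutation_test(vals, groups, covs, n_perm = 300, seed = 5)
  r2 <- adjusted_permutation_test(vals, groups, covs, n_perm = 300, seed = 5)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_true(r1$p_perm > 0 && r1$p_perm <= 1)
  expect_equal(nrow(r1$posthoc), 3)

  ## observed F invariant to subject order
  perm <- sample(sum(n))
  r3 <- adjusted_permutation_test(vals[perm], groups[perm], covs[perm, ],
                                  n_perm = 300, seed = 5)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-10)

  ## no covariate effect in the generator: adjusting for an irrelevant
  ## covariate reproduces the unadjusted p closely across replicates
  ps <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    v <- rnorm(sum(n))
    c(adjusted_permutation_test(v, groups, NULL, n_perm = 500, seed = s)$p_perm,
      adjusted_permutation_test(v, groups, data.frame(age = covs$age),
                                n_perm = 500, seed = s)$p_perm)
  }, numeric(2))
  expect_gt(cor(ps[1, ], ps[2, ]), 0.85)
  expect_lt(mean(abs(ps[1, ] - ps[2, ])), 0.1)

  ## planted 1 SD shift at the study's group sizes is detected
  shifted <- vals + (groups == "C") * 1
  r_pow <- adjusted_permutation_test(shifted, groups, covs, n_perm = 500, seed = 7)
  expect_lt(r_pow$p_perm, 0.05)

  expect_error(adjusted_permutation_test(vals, rep("A", sum(n)), covs),
               "2 groups")
  expect_error(adjusted_permutation_test(vals, groups,
                                         data.frame(x = covs$age, y = covs$age)),
               "singular")
})

test_that("ANCOVA reduces to ANOVA and to squared LSD t as appropriate", {
  set.seed(2)
  groups <- rep(c("A", "B", "C"), c(8, 9, 10))
  vals <- rnorm(27) + (groups == "B") * 0.8

  ## no covariates: one-way ANOVA
  r <- ancova_lsd(vals, groups)
  a <- anova(lm(vals ~ groups))
  expect_equal(r$statistic, a$`F value`[1])
  expect_equal(r$p, a$`Pr(>F)`[1])

  ## two groups: omnibus F equals squared LSD t
  g2 <- groups[groups != "C"]; v2 <- vals[groups != "C"]
  cv2 <- data.frame(age = rnorm(length(v2), 60, 4))
  r2 <- ancova_lsd(v2, g2, cv2)
  expect_equal(r2$statistic, r2$posthoc$t[1]^2, tolerance = 1e-10)
})

test_that("ANCOVA adjusted means and LSD match an independent implementation", {
  skip_if_not_installed("emmeans")
  set.seed(4)
  groups <- rep(c("A", "B", "C"), c(10, 12, 14))
  covs <- data.frame(age = rnorm(36, 65, 6), education = rnorm(36, 10, 3))
  vals <- 0.05 * covs$age + (groups == "A") * -0.5 + rnorm(36, 0, 0.7)
  r <- ancova_lsd(vals, groups, covs)
  dat <- data.frame(.y = vals, .g = factor(groups), covs)
  fit <- lm(.y ~ ., data = dat)
  emm <- emmeans::emmeans(fit, ".g", data = dat)
  expect_equal(unname(r$adjusted_means),
               summary(emm)$emmean, tolerance = 1e-8)
  prs <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
  expect_equal(r$posthoc$estimate, prs$estimate, tolerance = 1e-8)
  expect_equal(r$posthoc$p, prs$p.value, tolerance = 1e-8)
})

test_that("permutation and ANCOVA group tests agree on Gaussian data", {
  agree <- 0
  for (s in 1:200) {
    set.seed(400 + s)
    groups <- rep(c("A", "B"), c(12, 14))
    covs <- data.frame(age = rnorm(26, 65, 5))
    vals <- 0.03 * covs$age + rnorm(26) + (groups == "B") * runif(1, 0, 1)
    pp <- adjusted_permutation_test(vals, groups, covs, n_perm = 200,
                                    seed = s)$p_perm
    pa <- ancova_lsd(vals, groups, covs)$p
    agree <- agree + ((pp < 0.05) == (pa < 0.05))
  }
  expect_gte(agree / 200, 0.9)
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(8)
  control <- rnorm(8)
  x <- 0.5 * control + rnorm(8)
  y <- -0.3 * control + rnorm(8)
  pc <- partial_correlation(x, y, control)
  ## closed-form first-order partial correlation
  rxy <- cor(x, y); rxz <- cor(x, control); ryz <- cor(y, control)
  r_hand <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  expect_equal(pc$df, 5)

  expect_equal(partial_correlation(x, x, control)$r, 1)
  expect_error(partial_correlation(x[1:3], y[1:3], control[1:3]), "4 subjects")
  expect_error(partial_correlation(rep(1, 8), y, control), "zero variance")

  ## with an irrelevant control on a large sample, partial ~= plain Pearson
  set.seed(9)
  xx <- rnorm(4000); yy <- 0.5 * xx + rnorm(4000); cc <- rnorm(4000)
  expect_equal(partial_correlation(xx, yy, cc)$r, cor(xx, yy), tolerance = 0.02)
})

test_that("stepwise regression keeps signal, drops noise, forces the covariate", {
  set.seed(12)
  n <- 60
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  hrsd <- rnorm(n)

  ## pure-noise candidates: only the forced covariate remains
  y0 <- rnorm(n)
  r0 <- stepwise_regression(y0, cand["a"], hrsd)
  expect_length(r0$selected, 0)
  expect_true("forced" %in% r0$coefficients$term)

  ## strong single signal is selected with beta near its true value
  y1 <- cand$b + rnorm(n, 0, 0.3)
  r1 <- stepwise_regression(y1, cand, hrsd)
  expect_equal(r1$selected, "b")

  ## exact relation: beta = 1 and independent forced covariate near 0
  ## (suppress lm's perfect-fit chatter)
  y2 <- cand$a
  r2 <- suppressWarnings(stepwise_regression(y2, cand["a"], hrsd))
  cf <- r2$coefficients
  expect_equal(cf$beta[cf$term == "a"], 1, tolerance = 1e-8)
  expect_lt(abs(cf$estimate[cf$term == "forced"]), 1e-8)

  ## collinear candidate dropped with a warning
  cand2 <- cand; cand2$dup <- cand$a * 2
  y3 <- cand$a + rnorm(n, 0, 0.2)
  expect_warning(r3 <- stepwise_regression(y3, cand2[c("a", "dup")], hrsd),
                 "collinear")
  expect_equal(r3$selected, "a")
})
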