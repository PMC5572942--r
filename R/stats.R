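## Cognitive composites, memory-status grouping, covariate-adjusted
## permutation tests, ANCOVA with LSD post hoc comparisons, HDRS-adjusted
## partial correlations, and stepwise multiple regression.

#' Cognitive domain composites from raw neuropsychological scores
#'
#' Builds executive-function, processing-speed and memory z-score
#' composites:
#' \itemize{
#' \item executive: reverse of (TMT-B - TMT-A completion time), reverse of
#'   (Stroop-C - Stroop-A completion time), and (DST backward - DST
#'   forward);
#' \item speed: reverse Stroop-A time, reverse TMT-A time, and the SDMT
#'   correct count;
#' \item memory: the mean of AVLT N1..N5 and the LMT long-term score.
#' }
#' Each component is z-scored over the standardization sample and "reverse"
#' components are sign-negated so that higher always means better; a domain
#' composite is the unweighted mean of its available components (missing
#' scores are excluded pairwise, so a subject lacking one test still gets a
#' composite from the rest).
#'
#' @param raw_tests Data frame with one row per subject and columns
#'   `tmt_a`, `tmt_b`, `stroop_a`, `stroop_c`, `dst_forward`,
#'   `dst_backward`, `sdmt`, `avlt_n1`..`avlt_n5`, `lmt` (missing scores as
#'   NA).
#' @param standardization_sample Row indices (or logical) of the subjects
#'   defining the z-score means and SDs; defaults to all subjects.
#' @return Data frame with columns `executive`, `speed`, `memory`.
#' @export
cognitive_composites <- function(raw_tests, standardization_sample = NULL) {
  if (is.null(standardization_sample)) standardization_sample <- seq_len(nrow(raw_tests))
  zc <- function(x, reverse = FALSE) {
    ref <- x[standardization_sample]
    s <- sd(ref, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stopf("zero variance in a composite component over the standardization sample")
    z <- (x - mean(ref, na.rm = TRUE)) / s
    if (reverse) -z else z
  }
  comp_mean <- function(...) rowMeans(cbind(...), na.rm = TRUE)
  executive <- comp_mean(zc(raw_tests$tmt_b - raw_tests$tmt_a, reverse = TRUE),
                         zc(raw_tests$stroop_c - raw_tests$stroop_a, reverse = TRUE),
                         zc(raw_tests$dst_backward - raw_tests$dst_forward))
  speed <- comp_mean(zc(raw_tests$stroop_a, reverse = TRUE),
                     zc(raw_tests$tmt_a, reverse = TRUE),
                     zc(raw_tests$sdmt))
  avlt <- rowMeans(raw_tests[, paste0("avlt_n", 1:5)], na.rm = TRUE)
  memory <- comp_mean(zc(avlt), zc(raw_tests$lmt))
  out <- data.frame(executive = executive, speed = speed, memory = memory)
  out[is.nan(as.matrix(out))] <- NA
  out
}

#' Default age/education norm table for the AVLT-N5 memory-deficit cutoff
#'
#' Ships only the published stratum (ages 50-59: delayed recall <= 4 marks
#' a memory deficit, i.e. 1.5 SD below the age/education-adjusted norm);
#' users supply additional strata for other ages.
#' @return Data frame with columns `age_min`, `age_max`, `edu_min`,
#'   `edu_max`, `cutoff`.
#' @export
default_avlt_norms <- function() {
  data.frame(age_min = 50, age_max = 59, edu_min = 0, edu_max = Inf, cutoff = 4)
}

#' Classify memory status from the AVLT delayed-recall score
#'
#' A subject has a memory deficit iff their AVLT-N5 score is at or below
#' the cutoff of their age/education stratum (scores <= 1.5 SD under the
#' adjusted norm). A missing stratum is an error, never a silent default.
#'
#' @param age,education,avlt_n5 Subject values (vectorized).
#' @param norm_table Cutoff table as in [default_avlt_norms()].
#' @return Character vector, "memory_deficit" or "intact".
#' @export
classify_memory_status <- function(age, education, avlt_n5,
                                   norm_table = default_avlt_norms()) {
  mapply(function(a, e, s) {
    row <- which(a >= norm_table$age_min & a <= norm_table$age_max &
                 e >= norm_table$edu_min & e <= norm_table$edu_max)
    if (length(row) == 0)
      stopf("no norm-table stratum for age %s, education %s", a, e)
    if (s <= norm_table$cutoff[row[1]]) "memory_deficit" else "intact"
  }, age, education, avlt_n5, USE.NAMES = FALSE)
}

## Build the covariate design matrix (intercept + numeric columns; factors
## and character columns, e.g. gender, become indicator columns).
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(1, n, 1))
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = covariates)
  if (qr(mm)$rank < ncol(mm)) stopf("singular covariate design")
  mm
}

## F statistics for many response vectors at once, comparing the full
## design [Z, G] against the reduced design Z.
f_stats_matrix <- function(Y, Qz, Qw, q, df_res) {
  rss_z <- colSums(Y^2) - colSums((crossprod(Qz, Y))^2)
  rss_w <- colSums(Y^2) - colSums((crossprod(Qw, Y))^2)
  ((rss_z - rss_w) / q) / (rss_w / df_res)
}

#' Covariate-adjusted permutation test for group differences
#'
#' Tests an omnibus between-group difference in a per-subject value while
#' adjusting for covariates (e.g. age, education, gender), by permutation.
#' The default Freedman-Lane scheme fits the value on the covariates alone,
#' permutes the residuals, adds back the covariate fit, and recomputes the
#' group F statistic on the reconstructed data; the simpler
#' residual-permutation dialect permutes and tests the covariate residuals
#' directly. p = (1 + #(F_perm >= F_obs)) / (1 + n_perm). Pairwise post hoc
#' tests use the same scheme restricted to each group pair, uncorrected
#' (LSD-style).
#'
#' @param values Numeric per-subject outcome.
#' @param groups Group labels (factor or character).
#' @param covariates Data frame of per-subject covariates (or NULL for an
#'   unadjusted test).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param scheme "freedman_lane" (default) or "residual".
#' @return A `group_test` list: `statistic` (observed F), `p_perm`,
#'   `n_perm`, `posthoc` (pairwise permutation p-values with adjusted mean
#'   differences), `adjusted_means`, `covariates_used`.
#' @export
adjusted_permutation_test <- function(values, groups, covariates = NULL,
                                      n_perm = 10000L, seed = 1L,
                                      scheme = c("freedman_lane", "residual")) {
  scheme <- match.arg(scheme)
  groups <- droplevels(factor(groups))
  n <- length(values)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("each group needs at least 2 subjects")
  Z <- covariate_design(covariates, n)
  G <- stats::model.matrix(~ groups)[, -1, drop = FALSE]
  W <- cbind(Z, G)
  Qz <- qr.Q(qr(Z)); Qw <- qr.Q(qr(W))
  q <- ncol(G); df_res <- n - ncol(W)

  fit_z <- lm.fit(Z, values)
  e <- fit_z$residuals; f <- fit_z$fitted.values
  f_obs <- f_stats_matrix(cbind(values), Qz, Qw, q, df_res)

  perms <- vapply(seq_len(n_perm),
                  function(p) with_seed(derive_seed(seed, "group_perm", p),
                                        sample.int(n)),
                  integer(n))
  Ystar <- if (scheme == "freedman_lane") f + matrix(e[perms], n) else matrix(e[perms], n)
  f_perm <- f_stats_matrix(Ystar, Qz, Qw, q, df_res)
  p_perm <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)

  ## adjusted means: model prediction per group at mean covariates
  dat <- data.frame(.y = values, .g = groups)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- lm(.y ~ ., data = dat)
  adj <- adjusted_group_means(fit, dat)

  lev <- levels(groups)
  ph <- NULL
  if (length(lev) > 2) {
    prs <- utils::combn(lev, 2)
    ph <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      sel <- groups %in% prs[, k]
      sub_cov <- if (is.null(covariates)) NULL else as.data.frame(covariates)[sel, , drop = FALSE]
      r <- adjusted_permutation_test(values[sel], groups[sel], sub_cov,
                                     n_perm = n_perm,
                                     seed = derive_seed(seed, paste0("posthoc_", k)),
                                     scheme = scheme)
      data.frame(group1 = prs[1, k], group2 = prs[2, k],
                 diff_adjusted = adj[prs[1, k]] - adj[prs[2, k]],
                 p_perm = r$p_perm, row.names = NULL)
    }))
  }
  structure(list(statistic = unname(f_obs), p_perm = p_perm, n_perm = n_perm,
                 posthoc = ph, adjusted_means = adj,
                 covariates_used = if (is.null(covariates)) character()
                                   else names(as.data.frame(covariates)),
                 scheme = scheme),
            class = "group_test")
}

## Model-based group means with covariates held at their sample means.
adjusted_group_means <- function(fit, dat) {
  lev <- levels(dat$.g)
  newd <- dat[rep(1, length(lev)), , drop = FALSE]
  newd$.g <- factor(lev, levels = lev)
  for (nm in setdiff(names(dat), c(".y", ".g"))) {
    v <- dat[[nm]]
    if (is.numeric(v)) newd[[nm]] <- mean(v)
    else newd[[nm]] <- v[1]  # reference level for factors (documented)
  }
  setNames(as.numeric(predict(fit, newdata = newd)), lev)
}

#' ANCOVA with LSD post hoc comparisons
#'
#' Linear model of the outcome on group indicators plus covariates; the
#' omnibus group effect is the partial F comparing the model with and
#' without the group factor. Post hoc LSD comparisons are pairwise t-tests
#' on adjusted group means using the full model's residual variance,
#' without multiplicity correction.
#'
#' @inheritParams adjusted_permutation_test
#' @return A `group_test` list: `statistic` (F), `p` (parametric), `df`,
#'   `posthoc` (pairwise estimate, t, p), `adjusted_means`,
#'   `covariates_used`.
#' @export
ancova_lsd <- function(values, groups, covariates = NULL) {
  groups <- droplevels(factor(groups))
  n <- length(values)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  dat <- data.frame(.y = values, .g = groups)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  full <- lm(.y ~ ., data = dat)
  red <- lm(.y ~ . - .g, data = dat)
  an <- anova(red, full)
  f_obs <- an$F[2]; p <- an$`Pr(>F)`[2]
  df <- c(an$Df[2], full$df.residual)

  adj <- adjusted_group_means(full, dat)
  lev <- levels(groups)
  V <- stats::vcov(full)
  cf <- names(coef(full))
  prs <- utils::combn(lev, 2)
  ph <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    ## contrast of the two group coefficients (reference level = 0)
    cvec <- setNames(numeric(length(cf)), cf)
    ca <- paste0(".g", a); cb <- paste0(".g", b)
    if (ca %in% cf) cvec[ca] <- 1
    if (cb %in% cf) cvec[cb] <- -1
    est <- sum(cvec * coef(full))
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tv <- est / se
    data.frame(group1 = a, group2 = b, estimate = est, t = tv,
               p = 2 * pt(-abs(tv), full$df.residual), row.names = NULL)
  }))
  structure(list(statistic = f_obs, p = p, df = df, posthoc = ph,
                 adjusted_means = adj,
                 covariates_used = if (is.null(covariates)) character()
                                   else names(as.data.frame(covariates)),
                 model = full),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> F = %.3f, %s\n", x$statistic,
              if (!is.null(x$p_perm)) sprintf("permutation p = %.4g (%d perms)", x$p_perm, x$n_perm)
              else sprintf("p = %.4g", x$p)))
  if (!is.null(x$posthoc)) { cat("post hoc (LSD):\n"); print(x$posthoc) }
  invisible(x)
}

#' First-order partial Pearson correlation
#'
#' Correlation of x and y with one control variable (e.g. HDRS) partialled
#' out: the Pearson correlation of the residuals of x and y after
#' regression on the control. p-value from the t transform with n - 3
#' degrees of freedom. Any Bonferroni divisor (e.g. /3 across cognitive
#' domains) is applied at reporting, not inside the statistic.
#'
#' @param x,y Numeric vectors (>= 4 complete observations).
#' @param control Numeric control variable.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, control) {
  ok <- complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; control <- control[ok]
  n <- length(x)
  if (n < 4) stopf("partial correlation needs at least 4 subjects")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance in x or y")
  rx <- resid(lm(x ~ control))
  ry <- resid(lm(y ~ control))
  r <- cor(rx, ry)
  df <- n - 3
  tv <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tv), df), df = df, n = n)
}

#' Stepwise multiple regression with a forced covariate
#'
#' Forward selection / backward elimination on candidate predictors (e.g.
#' rich-club, feeder and local connective average strengths) with a
#' covariate (e.g. HDRS) forced into every model. Candidates enter at
#' p < `p_enter` (partial t test) and leave at p > `p_remove`, the common
#' statistical-package defaults. Collinear candidates (aliased in the fit)
#' are dropped with a warning. Standardized coefficients (beta) are
#' reported per retained term.
#'
#' @param response Numeric outcome (e.g. a cognitive composite).
#' @param candidates Data frame of candidate predictors.
#' @param forced_covariate Numeric vector (or single-column data frame)
#'   always kept in the model; NULL for none.
#' @param p_enter,p_remove Entry / removal thresholds (defaults 0.05 /
#'   0.10).
#' @return List with `selected` (candidate names in entry order),
#'   `coefficients` (term, estimate, beta, p for every term in the final
#'   model), and `model` (the `lm` fit).
#' @export
stepwise_regression <- function(response, candidates, forced_covariate = NULL,
                                p_enter = 0.05, p_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) < ncol(candidates) + 3)
    stopf("need at least %d subjects for %d candidates",
          ncol(candidates) + 3, ncol(candidates))
  dat <- data.frame(.y = response)
  if (!is.null(forced_covariate)) {
    fc <- as.data.frame(forced_covariate)
    if (ncol(fc) == 1 && is.null(names(forced_covariate))) names(fc) <- "forced"
    dat <- cbind(dat, fc)
  }
  forced_terms <- setdiff(names(dat), ".y")
  dat <- cbind(dat, candidates)
  cand_names <- names(candidates)

  term_p <- function(fit, term) {
    sm <- summary(fit)$coefficients
    if (!term %in% rownames(sm)) return(NA_real_)  # aliased
    sm[term, 4]
  }
  fit_terms <- function(terms) {
    fml <- stats::reformulate(c("1", forced_terms, terms), response = ".y")
    lm(fml, data = dat)
  }

  selected <- character()
  repeat {
    changed <- FALSE
    ## forward step
    pool <- setdiff(cand_names, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(tm) {
        p <- term_p(fit_terms(c(selected, tm)), tm)
        if (is.na(p)) {
          warning(sprintf("candidate '%s' is collinear and was dropped", tm),
                  call. = FALSE)
          cand_names <<- setdiff(cand_names, tm)
          Inf
        } else p
      }, 0)
      if (length(pvals) && min(pvals) < p_enter) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    ## backward step
    if (length(selected)) {
      fit <- fit_terms(selected)
      pvals <- vapply(selected, function(tm) term_p(fit, tm), 0)
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- fit_terms(selected)
  terms <- setdiff(names(coef(fit)), "(Intercept)")
  sm <- summary(fit)$coefficients
  sy <- sd(response)
  coefs <- do.call(rbind, lapply(terms, function(tm) {
    b <- coef(fit)[[tm]]
    data.frame(term = tm, estimate = b,
               beta = b * sd(dat[[tm]]) / sy,
               p = sm[tm, 4], row.names = NULL)
  }))
  list(selected = selected, coefficients = coefs, model = fit)
}
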