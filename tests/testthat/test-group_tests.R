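test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.038, 4), 0.152)
  expect_equal(bonferroni(0.01, 26), 0.26)
  expect_equal(bonferroni(0.5, 4), 1.0)
  expect_equal(bonferroni(c(0.02, 0.9), 3), c(0.06, 1.0))
})

test_that("exact permutation p equals the full-enumeration oracle", {
  set.seed(51)
  for (rep in 1:3) {
    X <- matrix(rnorm(6 * 4), 6, 4)
    labels <- rep(c("a", "b"), each = 3)
    oracle <- enum_perm_p(X, labels)
    res <- procrustes_anova(X, labels, exact = TRUE)
    expect_equal(res$statistic, oracle$f_obs, tolerance = 1e-12)
    expect_equal(res$p, oracle$p, tolerance = 1e-12)
    expect_equal(res$n_perm, 20L)  # C(6,3) = 20 label arrangements
  }
})

test_that("sampled permutation p is within Monte-Carlo error of enumeration", {
  set.seed(52)
  X <- matrix(rnorm(6 * 3), 6, 3)
  labels <- rep(c("a", "b"), each = 3)
  exact_p <- enum_perm_p(X, labels)$p
  res <- procrustes_anova(X, labels, n_perm = 999, seed = 7)
  mc_se <- sqrt(exact_p * (1 - exact_p) / 999)
  expect_lt(abs(res$p - exact_p), 2 * mc_se + 2 / 999)
})

test_that("separated groups with zero within-variance reach the minimum p", {
  X <- rbind(matrix(0, 10, 3), matrix(5, 10, 3))
  labels <- rep(c("a", "b"), each = 10)
  res <- procrustes_anova(X, labels, n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)
  expect_true(is.infinite(res$statistic) || res$statistic > 1e10)
})

test_that("procrustes_anova validates its inputs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(procrustes_anova(X, rep("a", 4)), "2 groups")
  expect_error(procrustes_anova(X, c("a", "a", "a", "b"), n_perm = 0),
               "n_perm")
})

test_that("permutation tests are deterministic under a fixed seed", {
  set.seed(53)
  X <- matrix(rnorm(30), 10, 3)
  labels <- rep(c("a", "b"), each = 5)
  p1 <- procrustes_anova(X, labels, n_perm = 499, seed = 11)$p
  p2 <- procrustes_anova(X, labels, n_perm = 499, seed = 11)$p
  expect_identical(p1, p2)
  # the seeded RNG is restored, not leaked into the caller's stream
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(procrustes_anova(X, labels, n_perm = 99, seed = 3))
  expect_identical(runif(1), before)
})

test_that("Pillai trace matches the direct H/E formula oracle and stats::manova", {
  set.seed(54)
  Y <- matrix(rnorm(14 * 2), 14, 2)
  Y[8:14, 1] <- Y[8:14, 1] + 1
  labels <- rep(c("a", "b"), each = 7)
  res <- manova_pillai(Y, labels)
  oracle <- pillai_direct(Y, labels)
  expect_equal(res$pillai, oracle$pillai, tolerance = 1e-10)
  expect_equal(res$statistic, oracle$approx_f, tolerance = 1e-10)

  fit <- summary(manova(Y ~ factor(labels)), test = "Pillai")
  stats_row <- fit$stats[1, ]
  expect_equal(res$pillai, unname(stats_row["Pillai"]), tolerance = 1e-10)
  expect_equal(res$statistic, unname(stats_row["approx F"]), tolerance = 1e-10)
  expect_equal(res$p, unname(stats_row["Pr(>F)"]), tolerance = 1e-10)
})

test_that("manova_pillai reduces to one-way ANOVA at q = 1", {
  set.seed(55)
  y <- rnorm(12) + rep(c(0, 1.5), each = 6)
  labels <- rep(c("a", "b"), each = 6)
  res <- manova_pillai(matrix(y, ncol = 1), labels)
  a <- anova(lm(y ~ factor(labels)))
  expect_equal(res$statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, a$`Pr(>F)`[1], tolerance = 1e-10)
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  expect_equal(res$pillai, ssb / (ssb + ssw), tolerance = 1e-10)
})

test_that("identical group means give Pillai 0 and p = 1", {
  set.seed(56)
  block <- matrix(rnorm(10 * 2), 10, 2)
  Y <- rbind(block, block)  # both groups contain the same rows
  labels <- rep(c("a", "b"), each = 10)
  res <- manova_pillai(Y, labels)
  expect_lt(res$pillai, 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("manova_pillai enforces the residual-df precondition", {
  Y <- matrix(rnorm(8 * 7), 8, 7)
  expect_error(manova_pillai(Y, rep(c("a", "b"), each = 4)),
               "residual degrees of freedom")
})

test_that("per-axis ANOVAs adjust with the axis-count family", {
  set.seed(57)
  q <- 8
  n <- 40
  Y <- matrix(rnorm(n * q), n, q)
  labels <- rep(c("a", "b"), each = n / 2)
  Y[, 3] <- as.integer(labels == "b")  # an axis equal to the group indicator
  # the indicator column is a deliberately perfect fit; stats::anova warns
  res <- suppressWarnings(per_axis_anova(Y, labels))
  expect_equal(nrow(res), q)
  expect_equal(res$p_adjusted, bonferroni(res$p_raw, q))
  expect_lt(res$p_raw[3], 1e-12)
  expect_lt(res$p_adjusted[3], 0.05)
  # single column: no adjustment
  res1 <- per_axis_anova(Y[, 1, drop = FALSE], labels)
  expect_equal(res1$p_adjusted, res1$p_raw)
})

test_that("pure-noise axes reject at roughly the nominal rate", {
  set.seed(58)
  q <- 400
  n <- 30
  Y <- matrix(rnorm(n * q), n, q)
  labels <- rep(c("a", "b"), each = n / 2)
  res <- per_axis_anova(Y, labels)
  rate <- mean(res$p_raw < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / q))
})

test_that("covariate_test with the group factor reproduces the group tests", {
  s <- make_two_group_sample(n_focal = 6, n_other = 8, preset = "tiny",
                             seed = 21)
  fit <- gpa(s)
  direct <- procrustes_anova(fit, s$groups, n_perm = 199, seed = 3)
  via_cov <- covariate_test(fit, as.character(s$groups), n_perm = 199,
                            seed = 3)
  expect_equal(via_cov$statistic, direct$statistic, tolerance = 1e-12)
  expect_identical(via_cov$p, direct$p)

  pca <- tangent_pca(fit)
  scores <- pca$scores[, 1:4]
  direct_m <- manova_pillai(scores, s$groups)
  via_m <- covariate_test(scores, as.character(s$groups))
  expect_equal(via_m$pillai, direct_m$pillai, tolerance = 1e-12)
  expect_equal(via_m$p, direct_m$p, tolerance = 1e-12)
})

test_that("covariate_test applies the family-size Bonferroni adjustment", {
  set.seed(59)
  scores <- matrix(rnorm(30), 10, 3)
  x <- rnorm(10)
  res <- covariate_test(scores, x, n_predictors = 4)
  expect_equal(res$p_adjusted, bonferroni(res$p, 4))
  expect_equal(bonferroni(0.038, 4), 0.152)
})

test_that("covariate_test drops missing values and rejects constants", {
  set.seed(60)
  scores <- matrix(rnorm(24), 8, 3)
  x <- c(rnorm(6), NA, NA)
  expect_message(res <- covariate_test(scores, x), "2 specimen")
  expect_equal(res$df_resid + res$df_effect + 1, 6)
  expect_error(covariate_test(scores, rep(1, 8)), "constant")
  expect_error(covariate_test(scores, rep("u", 8)), "constant")
})

test_that("continuous-predictor p-values are uniform under the null", {
  set.seed(61)
  n <- 25
  reps <- 500
  ps <- vapply(seq_len(reps), function(b) {
    scores <- matrix(rnorm(n * 3), n, 3)
    covariate_test(scores, rnorm(n))$p
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})
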