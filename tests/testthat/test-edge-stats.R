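test_that("chi-square test reproduces the demographic statistics", {
  sex <- matrix(c(14, 35, 14, 27), 2, byrow = TRUE)
  edu <- matrix(c(16, 33, 20, 21), 2, byrow = TRUE)
  expect_equal(round(chi_square_test(sex)$statistic, 3), 0.324)
  expect_equal(round(chi_square_test(edu)$statistic, 3), 2.419)
  # equal row proportions give exactly zero
  expect_equal(chi_square_test(matrix(c(10, 20, 5, 10), 2))$statistic, 0)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
})

test_that("two-sample KS matches a brute-force ECDF sweep", {
  set.seed(20)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  expect_equal(ks_two_sample(a, b)$D, ks_d_oracle(a, b), tolerance = 1e-12)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
})

test_that("KS normality check behaves under H0 and H1", {
  set.seed(21)
  h0 <- replicate(40, ks_normality(rnorm(10000))$p > 0.05)
  expect_gte(mean(h0), 0.95)
  h1 <- replicate(40, ks_normality(rexp(200))$p < 0.05)
  expect_gte(mean(h1), 0.95)
  expect_error(ks_normality(rep(1, 10)), "variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("global measure t-test matches the textbook formula", {
  set.seed(22)
  a <- rnorm(15); b <- rnorm(12, 0.3)
  res <- global_measure_test(a, b)
  expect_equal(res$t, pooled_t_oracle(a, b), tolerance = 1e-12)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  same <- c(1, 2, 3, 4)
  expect_equal(global_measure_test(same, same)$t, 0)
  expect_equal(global_measure_test(same, same)$p, 1)
  expect_error(global_measure_test(rep(0, 4), rep(1, 4)), "pooled variance")
})

test_that("design construction rejects confounded covariates", {
  groups <- rep(c("control", "depression"), each = 6)
  expect_silent(build_design(groups))
  # a covariate equal to the group indicator is confounded
  expect_error(build_design(groups, cbind(dep = as.numeric(groups == "depression"))),
               "rank deficient")
  # diagnosis dummies that jointly sum to the depression indicator, too
  d1 <- c(rep(0, 6), 1, 1, 1, 1, 0, 0)
  d2 <- c(rep(0, 6), 0, 0, 0, 0, 1, 1)
  expect_error(build_design(groups, cbind(d1, d2)), "rank deficient")
  expect_silent(build_design(groups, cbind(d2)))   # one dummy is fine
  expect_error(build_design(rep("control", 5)), "both groups")
})

test_that("edge test recovers t-statistics and respects the p-value floor", {
  set.seed(23)
  n_nodes <- 8
  n_edges <- n_nodes * (n_nodes - 1) / 2
  groups <- rep(c("control", "depression"), times = c(7, 6))
  Y <- matrix(rnorm(13 * n_edges, 0.4, 0.1), 13, n_edges)
  mats <- toy_matrices_from_edges(Y, n_nodes)
  res <- edgewise_group_test(mats, groups, alpha = 0.05, n_perm = 99, seed = 1)
  # observed t equals the pooled two-sample t, edge by edge
  want <- apply(Y, 2, function(y) pooled_t_oracle(y[groups == "control"],
                                                  y[groups == "depression"]))
  expect_equal(res$edges$t, unname(want), tolerance = 1e-10)
  expect_true(all(res$edges$p_perm >= 1 / 100))
  expect_true(all(res$edges$p_perm <= 1))
  # swapping the group coding flips every t
  flipped <- ifelse(groups == "control", "depression", "control")
  res_fl <- edgewise_group_test(mats, flipped, alpha = 0.05, n_perm = 99, seed = 1)
  expect_equal(res_fl$edges$t, -res$edges$t, tolerance = 1e-10)
})

test_that("label-permutation and Freedman-Lane paths agree", {
  set.seed(24)
  n_nodes <- 6
  groups <- rep(c("control", "depression"), times = c(6, 6))
  Y <- matrix(runif(12 * 15, -0.2, 0.6), 12, 15)
  Y[groups == "control", 3] <- Y[groups == "control", 3] + 0.3
  mats <- toy_matrices_from_edges(Y, n_nodes)
  fast <- edgewise_group_test(mats, groups, alpha = 0.1, n_perm = 3000, seed = 5)
  # with an intercept-only reduced model, Freedman-Lane residual
  # permutation is equivalent to permuting group labels
  slow <- edgewise_group_test(mats, groups, alpha = 0.1, n_perm = 3000,
                              seed = 5, use_fast_path = FALSE)
  expect_equal(slow$edges$t, fast$edges$t, tolerance = 1e-9)
  expect_lt(max(abs(slow$edges$p_perm - fast$edges$p_perm)), 0.05)
  expect_equal(slow$edges$significant[3], fast$edges$significant[3])
})

test_that("covariates orthogonal to the contrast leave t unchanged", {
  set.seed(25)
  n_nodes <- 6
  groups <- rep(c("control", "depression"), times = c(6, 6))
  Y <- matrix(runif(12 * 15, -0.5, 0.8), 12, 15)
  mats <- toy_matrices_from_edges(Y, n_nodes)
  g <- as.numeric(groups == "control")
  cov_orth <- residuals(lm(rnorm(12) ~ g))       # orthogonal to intercept+group
  withcov <- edgewise_group_test(mats, groups, covariates = cbind(c1 = cov_orth),
                                 n_perm = 10, seed = 1)
  # exact check against per-edge lm fits
  want <- apply(Y, 2, function(y) {
    fit <- summary(lm(y ~ cov_orth + g))
    fit$coefficients["g", "t value"]
  })
  expect_equal(withcov$edges$t, unname(want), tolerance = 1e-10)
})

test_that("an all-null cohort yields no discoveries at a strict level", {
  set.seed(26)
  groups <- rep(c("control", "depression"), each = 10)
  Y <- matrix(rnorm(20 * 210, 0.3, 0.1), 20, 210)   # 21 nodes -> 210 edges
  mats <- toy_matrices_from_edges(Y, 21)
  res <- edgewise_group_test(mats, groups, alpha = 1e-4, n_perm = 500, seed = 2)
  expect_equal(res$n_significant_edges, 0L)
  expect_equal(res$n_involved_nodes, 0L)
})

test_that("FDR control holds on average over null replicates", {
  set.seed(27)
  alpha <- 0.05
  n_rep <- 120
  fdp <- vapply(seq_len(n_rep), function(r) {
    groups <- rep(c("control", "depression"), each = 20)
    Y <- matrix(rnorm(40 * 435, 0.3, 0.1), 40, 435)  # 30 nodes
    mats <- toy_matrices_from_edges(Y, 30)
    res <- edgewise_group_test(mats, groups, alpha = alpha, n_perm = 300,
                               seed = r)
    if (res$n_significant_edges == 0) 0 else 1      # all discoveries are false
  }, 0)
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(mean(fdp), alpha + 2 * se)
})
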