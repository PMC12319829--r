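test_that("perfect linear association attains the minimal p-value", {
  set.seed(80)
  D <- matrix(rnorm(80), 40, 2)
  R <- D %*% c(1, -2)
  res <- permutation_regression_test(D, R, n_perm = 999, seed = 81)
  expect_equal(res$pvals, 1 / 1000)
  expect_equal(res$statistic, 1, tolerance = 1e-10)
})

test_that("regression test separates signal from null columns", {
  set.seed(82)
  D <- matrix(rnorm(60), 60, 1)
  R <- cbind(rnorm(60), D[, 1] * 2 + rnorm(60, sd = 0.3))
  res <- permutation_regression_test(D, R, n_perm = 499, seed = 83)
  expect_gt(res$pvals[1], 0.05)
  expect_lt(res$pvals[2], 0.01)
})

test_that("correlation test: identical columns, two-sided symmetry", {
  set.seed(84)
  x <- rnorm(30)
  D <- cbind(x)
  res <- permutation_correlation_test(D, cbind(x), n_perm = 199, seed = 85)
  expect_equal(res$pvals[1, 1], 1 / 200)
  # sign flip leaves the two-sided p unchanged
  res2 <- permutation_correlation_test(D, cbind(-x), n_perm = 199, seed = 85)
  expect_equal(res$pvals, res2$pvals)
  expect_error(permutation_correlation_test(D, cbind(rep(1, 30)), n_perm = 9),
               "Zero-variance")
})

test_that("p-values respect the add-one lower bound", {
  set.seed(86)
  D <- matrix(rnorm(25), 25, 1)
  for (np in c(19, 99)) {
    res <- permutation_regression_test(D, rnorm(25), n_perm = np, seed = 87)
    expect_gte(res$pvals, 1 / (np + 1))
    expect_lte(res$pvals, 1)
  }
})

test_that("deconfounding projects out confounds and only confounds", {
  set.seed(88)
  n <- 50
  C <- matrix(rnorm(n * 2), n, 2)
  # M built orthogonal to [1, C] stays untouched
  Q <- qr.Q(qr(cbind(1, C, matrix(rnorm(n * 2), n, 2))))
  M_orth <- Q[, 4:5]
  expect_lt(max(abs(deconfound(M_orth, C) - M_orth)), 1e-10)
  # M inside the span of C is annihilated
  M_in <- C %*% rbind(c(1, -1), c(2, 0.5))
  expect_lt(max(abs(deconfound(M_in, C))), 1e-10)
  # residuals orthogonal to the confound columns (normal equations)
  M <- matrix(rnorm(n * 3), n, 3)
  res <- deconfound(M, C)
  expect_lt(max(abs(crossprod(cbind(1, C), res))), 1e-8)
})

test_that("deconfounding removes a purely confound-driven association", {
  set.seed(89)
  n <- 60
  C <- rnorm(n)
  D <- cbind(2 * C + rnorm(n, sd = 0.2))
  R <- cbind(-1.5 * C + rnorm(n, sd = 0.2))
  raw <- permutation_regression_test(D, R, n_perm = 199, seed = 90)
  adj <- permutation_regression_test(D, R, C = cbind(C), n_perm = 199, seed = 90)
  expect_lt(raw$pvals, 0.01)
  expect_gt(adj$pvals, 0.05)
})

test_that("multiple-comparison corrections match their definitions", {
  expect_equal(correct_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04), "benjamini_hochberg"),
               rep(0.04, 4))
  expect_equal(correct_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(correct_pvalues(0.03, "benjamini_hochberg"), 0.03)
  # BH is monotone in the raw ordering
  set.seed(91)
  p <- runif(20)
  adj <- correct_pvalues(p, "benjamini_hochberg")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
})

test_that("cluster correction finds embedded clusters and nothing else", {
  set.seed(92)
  Tn <- 60
  null <- matrix(rnorm(99 * Tn), 99, Tn)
  obs <- rnorm(Tn)
  expect_equal(nrow(cluster_correction(obs - 10, null, 2)$clusters), 0L)
  # one huge spike exceeding every null maximum
  obs2 <- obs; obs2[20:24] <- 50
  cc <- cluster_correction(obs2, null, 2)
  big <- cc$clusters[which.max(cc$clusters$mass), ]
  expect_equal(c(big$start, big$end), c(20, 24))
  expect_equal(big$pval, 0.01)
})

test_that("across-visits test flags true state-signal coupling", {
  sc <- generate_scenario("visits_signal", seed = 93)
  res <- across_visits_test(sc$states, sc$S, sc$data$indices,
                            contrast = "all_states", n_perm = 199, seed = 94)
  expect_lt(res$pvals, 0.05)
  # exact dependence: minimal p
  S_exact <- c(-1, 0, 1)[sc$states]
  res2 <- across_visits_test(sc$states, S_exact, sc$data$indices,
                             n_perm = 199, seed = 95)
  expect_equal(res2$pvals, 1 / 200)
  # pairwise contrast where only state 3 differs
  S3 <- ifelse(sc$states == 3, 2, 0) + rnorm(length(sc$states), sd = 0.5)
  r_all <- across_visits_test(sc$states, S3, sc$data$indices,
                              contrast = "all_states", n_perm = 99, seed = 96)
  r_k3 <- across_visits_test(sc$states, S3, sc$data$indices,
                             contrast = "one_vs_rest", k = 3,
                             n_perm = 99, seed = 96)
  expect_lt(r_all$pvals, 0.05)
  expect_lt(r_k3$pvals, 0.05)
  expect_error(across_visits_test(sc$states, S3, sc$data$indices,
                                  contrast = "one_vs_rest", k = 99),
               "never visited")
})

test_that("per-time-point testing localises a condition effect in time", {
  sc <- generate_scenario("sequential_task",
                          overrides = list(n_trials = 30L, trial_len = 30L,
                                           effect = 0.8),
                          seed = 97)
  fit <- glhmm(sc$data, K = 4, mean_mode = "state", cov_mode = "shared",
               cov_shape = "diagonal", mask = sc$mask, seed = 98,
               control = quiet_control(max_cycles = 25))
  res <- timecourse_regression_test(fit$gamma, sc$data$indices, sc$R,
                                    n_perm = 199, seed = 99,
                                    correction = "benjamini_hochberg")
  expect_equal(dim(res$pvals), c(30L, 1L))
  expect_true(all(res$pvals_corrected >= res$pvals - 1e-12))
  # a faster progression under condition 1 shows up at some mid-trial times
  expect_lt(min(res$pvals), 0.05)
})
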