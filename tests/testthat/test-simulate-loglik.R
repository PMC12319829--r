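test_that("simulator respects the chain: absorbing, reproducible, calibrated", {
  cfg <- glhmm_config(K = 3, mean_mode = "state", cov_mode = "identity")
  params <- glhmm_params(cfg, mu = diag(3) * 2, q = 3, theta = diag(3))
  sim <- sample_glhmm(params, segment_lengths = c(50, 50, 50), seed = 1)
  # identity theta: each segment stays in its initial state throughout
  for (i in 1:3) {
    seg <- sim$states[seq((i - 1) * 50 + 1, i * 50)]
    expect_equal(length(unique(seg)), 1L)
  }
  # determinism under the seed
  sim2 <- sample_glhmm(params, segment_lengths = c(50, 50, 50), seed = 1)
  expect_identical(sim$data$Y, sim2$data$Y)
  expect_identical(sim$states, sim2$states)
})

test_that("per-state emissions are standard normal when mu = 0, Sigma = I", {
  cfg <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "identity")
  params <- glhmm_params(cfg, mu = matrix(0, 2, 2), q = 2)
  sim <- sample_glhmm(params, 4000, seed = 2)
  for (k in 1:2) {
    n <- sum(sim$states == k)
    expect_lt(max(abs(colMeans(sim$data$Y[sim$states == k, ]))), 4 / sqrt(n))
  }
})

test_that("long-chain state frequencies match the stationary distribution", {
  params <- two_state_params(stay = 0.8)
  # stationary distribution: leading left eigenvector of theta
  ev <- eigen(t(params$theta))
  statd <- Re(ev$vectors[, 1]); statd <- statd / sum(statd)
  sim <- sample_glhmm(params, 20000, seed = 3)
  freq <- tabulate(sim$states, 2) / 20000
  # Monte Carlo standard error inflated by chain autocorrelation
  rho <- 2 * 0.8 - 1
  se <- sqrt(statd * (1 - statd) / 20000) * sqrt((1 + rho) / (1 - rho))
  expect_true(all(abs(freq - statd) < 3 * se))
})

test_that("empirical transition counts match theta within Monte Carlo error", {
  params <- two_state_params(stay = 0.85)
  sim <- sample_glhmm(params, rep(10000, 10), seed = 4)
  s <- sim$states
  idx <- sim$data$indices
  counts <- matrix(0, 2, 2)
  for (i in seq_len(nrow(idx))) {
    seg <- s[idx[i, 1]:idx[i, 2]]
    for (t in 2:length(seg)) counts[seg[t - 1], seg[t]] <- counts[seg[t - 1], seg[t]] + 1
  }
  est <- counts / rowSums(counts)
  n_row <- rowSums(counts)
  se <- sqrt(params$theta * (1 - params$theta) / n_row)
  expect_true(all(abs(est - params$theta) <= 3 * se))
})

test_that("state_loglik matches a direct multivariate normal evaluation", {
  set.seed(5)
  cfg <- glhmm_config(K = 2, mean_mode = "state", beta_mode = "state",
                      cov_mode = "state")
  q <- 3; p <- 2
  A1 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  A2 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  params <- glhmm_params(cfg, mu = matrix(rnorm(2 * q), 2, q),
                         beta = array(rnorm(p * q * 2), c(p, q, 2)),
                         Sigma = array(c(A1, A2), c(q, q, 2)))
  X <- matrix(rnorm(20 * p), 20, p)
  sim <- sample_glhmm(params, 20, X = X, seed = 6)
  L <- state_loglik(sim$data, params)
  # textbook density oracle via mahalanobis() and determinant()
  for (k in 1:2) {
    S <- params$Sigma[, , k]
    mean_mat <- matrix(params$mu[k, ], 20, q, byrow = TRUE) + X %*% params$beta[, , k]
    maha <- mahalanobis(sim$data$Y - mean_mat, center = FALSE, cov = S)
    lref <- -0.5 * (q * log(2 * pi) +
                      determinant(S, logarithm = TRUE)$modulus[1] + maha)
    expect_equal(L[, k], as.numeric(lref), tolerance = 1e-10)
  }
})

test_that("state_loglik basics: standard normal at origin, symmetric states,
          segment invariance, diagonal factorisation", {
  cfg <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "shared")
  params <- glhmm_params(cfg, mu = matrix(0, 2, 1),
                         Sigma = array(1, c(1, 1, 1)))
  d <- glhmm_data(matrix(0, 1, 1))
  expect_equal(state_loglik(d, params)[1, 1], -0.5 * log(2 * pi))
  # identical states give identical columns
  set.seed(7)
  d2 <- glhmm_data(matrix(rnorm(30), 30, 1))
  L <- state_loglik(d2, params)
  expect_equal(L[, 1], L[, 2])
  # invariant to the segment partition
  d3 <- glhmm_data(d2$Y, indices = rbind(c(1, 10), c(11, 30)))
  expect_equal(state_loglik(d3, params), L)
  # diagonal covariance = sum of univariate log densities
  cfgd <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "state",
                       cov_shape = "diagonal")
  sd2 <- c(0.5, 2)
  paramsd <- glhmm_params(cfgd, mu = matrix(c(0, 1, -1, 2), 2, 2),
                          Sigma = array(c(diag(sd2^2), diag(rev(sd2)^2)),
                                        c(2, 2, 2)))
  Y <- matrix(rnorm(20), 10, 2)
  Ld <- state_loglik(glhmm_data(Y), paramsd)
  for (k in 1:2) {
    s <- sqrt(diag(paramsd$Sigma[, , k]))
    ref <- dnorm(Y[, 1], paramsd$mu[k, 1], s[1], log = TRUE) +
      dnorm(Y[, 2], paramsd$mu[k, 2], s[2], log = TRUE)
    expect_equal(Ld[, k], ref, tolerance = 1e-12)
  }
})
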