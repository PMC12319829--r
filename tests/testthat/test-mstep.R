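test_that("chain update counts one-hot paths correctly", {
  cfg <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "identity",
                      dirichlet_diag = 10)
  # path 1 -> 2 -> 2 (one segment), one-hot
  start_counts <- c(1, 0)
  trans_counts <- rbind(c(0, 1), c(0, 1))
  post <- update_chain(start_counts, trans_counts, cfg)
  base <- cfg$prior$dirichlet_base
  expect_equal(post$pi_alpha, base + c(1, 0))
  expect_equal(post$theta_alpha,
               rbind(c(base + 10, base + 1), c(base, base + 10 + 1)))
})

test_that("huge dirichlet_diag drives expected self-transitions to 1", {
  cfg <- glhmm_config(K = 3, mean_mode = "state", cov_mode = "identity",
                      dirichlet_diag = 1e8)
  post <- update_chain(rep(1, 3), matrix(5, 3, 3), cfg)
  theta_mean <- post$theta_alpha / rowSums(post$theta_alpha)
  expect_true(all(diag(theta_mean) > 0.999))
})

test_that("chain posterior equals prior plus hand-summed expected counts", {
  set.seed(20)
  cfg <- glhmm_config(K = 3, mean_mode = "state", cov_mode = "identity",
                      dirichlet_diag = 2.5)
  g <- matrix(runif(30), 10, 3); g <- g / rowSums(g)
  idx <- rbind(c(1, 6), c(7, 10))
  L <- matrix(rnorm(30), 10, 3)
  ch <- rand_chain(3)
  fb <- forward_backward(L, log(ch$pi), log(ch$theta), idx)
  post <- update_chain(fb$start_counts, fb$trans_counts, cfg)
  # direct summation oracle
  starts <- fb$gamma[c(1, 7), ]
  expect_equal(post$pi_alpha, cfg$prior$dirichlet_base + colSums(starts))
  hand <- matrix(0, 3, 3)
  for (i in 1:2) for (t in seq_len(dim(fb$xi[[i]])[1]))
    hand <- hand + fb$xi[[i]][t, , ]
  expect_equal(post$theta_alpha,
               matrix(cfg$prior$dirichlet_base, 3, 3) + diag(2.5, 3) + hand,
               tolerance = 1e-12)
})

test_that("single-state diffuse-prior posterior mean equals the sample mean", {
  set.seed(21)
  Y <- matrix(rnorm(200 * 2, mean = c(1, -2)), 200, 2, byrow = TRUE)
  d <- glhmm_data(Y)
  cfg <- glhmm_config(K = 1, mean_mode = "state", cov_mode = "shared",
                      prior = list(coef_var = 1e8))
  post <- update_observation_model(d, matrix(1, 200, 1), cfg)
  expect_equal(as.numeric(post$coefficients$mu), colMeans(Y), tolerance = 1e-6)
})

test_that("one-hot gamma reproduces per-subset Bayesian regression", {
  set.seed(22)
  Tn <- 120; p <- 2; q <- 1
  X <- matrix(rnorm(Tn * p), Tn, p)
  assign <- rep(1:2, each = Tn / 2)
  b_true <- list(c(2, -1), c(-2, 1))
  Y <- matrix(0, Tn, q)
  for (k in 1:2) Y[assign == k, ] <- X[assign == k, ] %*% b_true[[k]] +
      rnorm(Tn / 2, sd = 0.3)
  d <- glhmm_data(Y, X = X)
  cfg <- glhmm_config(K = 2, mean_mode = "none", beta_mode = "state",
                      cov_mode = "identity", prior = list(coef_var = 1e6))
  g <- cbind(assign == 1, assign == 2) + 0
  post <- update_observation_model(d, g, cfg)
  for (k in 1:2) {
    rows <- assign == k
    # with identity covariance and a diffuse prior this is per-subset OLS
    ols <- qr.coef(qr(X[rows, ]), Y[rows, ])
    expect_equal(as.numeric(post$coefficients$beta[, , k]), as.numeric(ols),
                 tolerance = 1e-4)
  }
})

test_that("a state with zero responsibility keeps its prior", {
  set.seed(23)
  d <- glhmm_data(matrix(rnorm(60), 30, 2))
  cfg <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "state")
  g <- cbind(rep(1, 30), rep(0, 30))
  post <- update_observation_model(d, g, cfg)
  # state 2 mean stays at the prior mean (zero) with prior covariance
  expect_equal(as.numeric(post$obs$m[[1]][2, , ]), c(0, 0))
  expect_equal(post$obs$S[[1]][[2]][[1]][1, 1], cfg$prior$coef_var)
  # state 2 precision posterior has prior dof
  expect_equal(post$cov$nu[2], build_priors(cfg, 2)$nu0)
})
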