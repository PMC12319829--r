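cohort_fit <- local({
  sc <- generate_scenario("cohort_traits", seed = 110)
  fit <- glhmm(sc$data, K = 3, seed = 111, control = quiet_control())
  list(sc = sc, fit = fit)
})

test_that("identical subjects get identical Fisher score rows", {
  sc <- cohort_fit$sc
  d <- sc$data
  # duplicate subject 1's rows as a fake subject 25
  rows <- 1:300
  Y2 <- rbind(d$Y, d$Y[rows, ])
  idx2 <- rbind(d$indices, d$indices[1:2, ] + d$T)
  subj2 <- c(d$subjects, rep(25L, 2))
  d2 <- glhmm_data(Y2, indices = idx2, subjects = subj2)
  fit2 <- cohort_fit$fit
  fit2$data <- d2
  fit2$meta <- glhmmr:::build_design(fit2$config, d2)
  sco <- fisher_scores(fit2, normalise = "T")
  expect_equal(sco[1, ], sco[25, ], tolerance = 1e-10)
})

test_that("Fisher scores nearly sum to zero at the group estimate", {
  sco <- fisher_scores(cohort_fit$fit, normalise = "none")
  tot <- colSums(sco) / cohort_fit$sc$data$T
  # the Bayesian group estimate is not the exact ML optimum, so allow the
  # prior-induced O(1/T) bias
  expect_lt(max(abs(tot)), 5e-3)
})

test_that("Fisher mu-scores agree with a finite-difference gradient", {
  fit <- cohort_fit$fit
  co <- coef(fit)
  sub <- glhmmr:::subset_segments(fit$data, 1:2)
  cfg <- fit$config
  loglik_at <- function(mu) {
    params <- glhmm_params(cfg, mu = mu, Sigma = co$Sigma, pi = co$pi,
                           theta = co$theta, q = 3)
    L <- state_loglik(sub, params)
    sum(forward_backward(L, log(co$pi), log(co$theta), sub$indices)$logZ)
  }
  sco <- fisher_scores(fit, include = "mu", normalise = "none")
  eps <- 1e-5
  for (probe in list(c(1, 1), c(2, 3), c(3, 2))) {
    mu_p <- co$mu; mu_m <- co$mu
    mu_p[probe[1], probe[2]] <- mu_p[probe[1], probe[2]] + eps
    mu_m[probe[1], probe[2]] <- mu_m[probe[1], probe[2]] - eps
    fd <- (loglik_at(mu_p) - loglik_at(mu_m)) / (2 * eps)
    # score layout: states are concatenated, q channels per state
    analytic <- unname(sco[1, (probe[1] - 1) * 3 + probe[2]])
    expect_equal(analytic, fd, tolerance = 1e-3)
  }
  # a subject with an upward-shifted mean has positive mu-scores overall
  fit2 <- fit
  d <- fit$data
  Y2 <- d$Y; Y2[1:300, ] <- Y2[1:300, ] + 1
  fit2$data <- glhmm_data(Y2, indices = d$indices, subjects = d$subjects)
  sco2 <- fisher_scores(fit2, include = "mu", normalise = "T")
  expect_gt(sum(sco2[1, ]), sum(sco[1, ] / fit$data$T))
})

test_that("kernels are symmetric, PSD, and behave on degenerate input", {
  set.seed(112)
  S <- matrix(rnorm(10 * 4), 10, 4)
  for (kind in c("linear", "gaussian")) {
    Km <- build_kernel(S, kind)
    expect_equal(Km, t(Km))
    expect_gt(min(eigen(Km, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  S2 <- rbind(S, S[1, ])
  expect_equal(build_kernel(S2, "gaussian")[1, 11], 1)
  v <- S[, 1, drop = FALSE]
  expect_equal(build_kernel(v, "linear"), tcrossprod(v))
  expect_error(build_kernel(S, "gaussian", bandwidth = -1), "positive")
})

test_that("summary features have the documented width and match summaries", {
  fit <- cohort_fit$fit
  Fm <- summary_features(fit)
  K <- fit$K
  expect_equal(ncol(Fm), 3 * K + 2)
  ag <- aggregate_stats(fit)
  expect_equal(unname(Fm[, 1:K]), unname(ag$FO))
  expect_equal(unname(Fm[, ncol(Fm)]), unname(ag$entropy))
})

test_that("group-aware folds never split a group", {
  for (s in 1:5) {
    groups <- sample(rep(1:8, times = sample(1:3, 8, replace = TRUE)))
    plan <- make_folds(length(groups), 4, groups, seed = s)
    tab <- table(groups, plan$fold)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_error(make_folds(6, 4, groups = rep(1, 6)), "More folds")
  # singleton groups reduce to ordinary K-fold
  plan <- make_folds(12, 3, seed = 1)
  expect_equal(as.integer(sort(table(plan$fold))), rep(4L, 3))
})

test_that("kernel ridge: shrinkage limit, recovery, and null behaviour", {
  set.seed(113)
  N <- 40
  S <- matrix(rnorm(N * 5), N, 5)
  y <- as.numeric(S %*% c(1, -1, 0.5, 0, 0))
  Km <- build_kernel(S, "linear")
  folds <- make_folds(N, 5, seed = 114)
  # noiseless linear signal: near-perfect held-out EV
  res <- kernel_ridge_cv(Km, y, folds, ridge_grid = c(1e-6, 1e-4), seed = 115)
  expect_gte(res$ev, 0.95)
  # huge ridge shrinks to the training-fold mean
  fitk <- glhmmr:::krr_train(Km[1:30, 1:30], y[1:30], lambda = 1e9)
  pr <- glhmmr:::krr_predict(fitk, Km[31:40, 1:30])
  expect_lt(max(abs(pr - mean(y[1:30]))), 0.01)
  # shuffled target: no skill
  res0 <- kernel_ridge_cv(Km, sample(y), folds, seed = 116)
  expect_lt(res0$ev, 0.2)
})

test_that("CV-safe deconfounding never uses test-fold confound fits", {
  set.seed(117)
  N <- 40
  conf <- rnorm(N)
  S <- matrix(rnorm(N * 3), N, 3)
  y <- conf                     # the target IS the confound: leakage probe
  Km <- build_kernel(S, "linear")
  folds <- make_folds(N, 5, seed = 118)
  res <- kernel_ridge_cv(Km, y, folds, confounds = cbind(conf), seed = 119)
  # after deconfounding there is nothing left to predict
  expect_lt(res$ev, 0.2)
  expect_lt(stats::sd(res$observed), 0.1)
})

test_that("kernel classification separates separable clusters, chance on null", {
  set.seed(120)
  N <- 40
  lab <- rep(c(0, 1), each = N / 2)
  S <- matrix(rnorm(N * 3), N, 3) + 4 * lab
  Km <- build_kernel(S, "linear")
  folds <- make_folds(N, 4, seed = 121)
  res <- kernel_classify_cv(Km, lab, folds, seed = 122)
  expect_equal(res$accuracy, 1)
  lab0 <- sample(lab)
  res0 <- kernel_classify_cv(build_kernel(matrix(rnorm(N * 3), N, 3), "linear"),
                             lab0, folds, seed = 123)
  expect_lt(abs(res0$accuracy - 0.5), 0.25)
  expect_error(kernel_classify_cv(Km, rep(1, N), folds), "binary")
})

test_that("trait-dependent cohorts are predictable; exact nulls are not", {
  sc <- cohort_fit$sc
  fit <- cohort_fit$fit
  sco <- fisher_scores(fit, normalise = "T")
  Km <- build_kernel(sco, "linear")
  folds <- make_folds(length(sc$trait), 5, groups = sc$blocks, seed = 124)
  res <- kernel_ridge_cv(Km, sc$trait, folds, seed = 125)
  expect_gt(res$ev, 0)          # beats the intercept-only baseline
  sc0 <- generate_scenario("cohort_traits", overrides = list(effect = 0),
                           seed = 110)
  fit0 <- glhmm(sc0$data, K = 3, seed = 111, control = quiet_control())
  sco0 <- fisher_scores(fit0, normalise = "T")
  res0 <- kernel_ridge_cv(build_kernel(sco0, "linear"), sc0$trait,
                          make_folds(length(sc0$trait), 5, groups = sc0$blocks,
                                     seed = 124), seed = 125)
  expect_lt(res0$ev, res$ev)
  expect_lt(res0$ev, 0.15)
})
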