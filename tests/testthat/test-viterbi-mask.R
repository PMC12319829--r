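test_that("transition-structure masks have the expected patterns", {
  m <- make_transition_mask("sequential", 4)
  expect_equal(sum(m$allowed), 7L)           # 4 self + 3 forward
  expect_true(all(diag(m$allowed)))
  mc <- make_transition_mask("circular", 4)
  expect_equal(sum(mc$allowed), 8L)
  expect_true(mc$allowed[4, 1])
  mf <- make_transition_mask("forward_only", 3)
  expect_equal(sum(mf$allowed), 6L)
  expect_true(all(mf$allowed[upper.tri(mf$allowed, diag = TRUE)]))
  mb <- make_transition_mask("blocks", 4, blocks = list(1:2, 3:4),
                             gates = rbind(c(2, 3)))
  expect_true(mb$allowed[2, 3])
  expect_false(mb$allowed[1, 3])
  expect_error(make_transition_mask("blocks", 4, blocks = list(1:2, 3)),
               "partition")
})

test_that("Viterbi matches the exhaustive argmax and is constant for K = 1", {
  set.seed(50)
  for (rep in 1:6) {
    K <- 3; Tn <- 6
    L <- matrix(rnorm(Tn * K, sd = 2), Tn, K)
    ch <- rand_chain(K)
    or <- enum_oracle(L, log(ch$pi), log(ch$theta))
    expect_equal(viterbi(L, log(ch$pi), log(ch$theta)), or$vpath)
  }
  expect_equal(viterbi(matrix(rnorm(5), 5, 1), 0, matrix(0, 1, 1)),
               rep(1L, 5))
})

test_that("Viterbi path beats the gamma-argmax path in joint probability", {
  set.seed(51)
  score <- function(s, L, lp, lth)
    lp[s[1]] + sum(lth[cbind(s[-length(s)], s[-1])]) +
    sum(L[cbind(seq_along(s), s)])
  for (rep in 1:5) {
    L <- matrix(rnorm(30 * 3), 30, 3)
    ch <- rand_chain(3)
    fb <- forward_backward(L, log(ch$pi), log(ch$theta))
    vp <- viterbi(L, log(ch$pi), log(ch$theta))
    ga <- apply(fb$gamma, 1, which.max)
    expect_gte(score(vp, L, log(ch$pi), log(ch$theta)),
               score(ga, L, log(ch$pi), log(ch$theta)))
  }
})

test_that("masked decoding never violates the mask; ties break low", {
  set.seed(52)
  mask <- make_transition_mask("sequential", 3)
  th <- glhmmr:::row_normalise(mask$allowed * 1)
  for (rep in 1:10) {
    L <- matrix(rnorm(20 * 3), 20, 3)
    vp <- viterbi(L, log(rep(1 / 3, 3)), log(th), mask = mask)
    expect_true(all(diff(vp) %in% c(0, 1)))
  }
  # exact ties resolve to the lowest state index
  L <- matrix(0, 4, 2)
  vp <- viterbi(L, log(c(0.5, 0.5)), log(matrix(0.5, 2, 2)))
  expect_equal(vp, rep(1L, 4))
  # infeasible path under a mask errors
  m <- make_transition_mask("custom", 2, allowed = rbind(c(TRUE, FALSE),
                                                         c(FALSE, TRUE)))
  lth <- log(rbind(c(1, 0), c(0, 1)))
  L2 <- matrix(c(0, -Inf, -Inf, 0), 2, 2)  # forces 1 then 2: impossible
  expect_error(viterbi(L2, log(c(1, 0) + 1e-300), lth, mask = m),
               "feasible|All-zero|Inf")
})

test_that("fitting with a sequential mask yields non-decreasing expected paths", {
  sc <- generate_scenario("sequential_task",
                          overrides = list(n_trials = 16L, trial_len = 40L),
                          seed = 53)
  fit <- glhmm(sc$data, K = 4, mean_mode = "state", cov_mode = "shared",
               cov_shape = "diagonal", mask = sc$mask, seed = 54,
               control = quiet_control(max_cycles = 30))
  idx <- sc$data$indices
  for (i in seq_len(nrow(idx))) {
    seg <- fit$vpath[idx[i, 1]:idx[i, 2]]
    expect_true(all(diff(seg) >= 0))
    eidx <- fit$gamma[idx[i, 1]:idx[i, 2], ] %*% 1:4
    expect_true(all(diff(as.numeric(eidx)) >= -0.3)) # soft path drifts forward
  }
  # posterior mass on masked transitions is exactly zero
  expect_true(all(coef(fit)$theta[!sc$mask$allowed] == 0))
})
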