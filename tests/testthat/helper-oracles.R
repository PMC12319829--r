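# Independent oracles and small fixtures used across the suite.

# Exhaustive-path oracle: smoothed marginals, pairwise marginals, evidence
# and the best path by enumerating all K^T state sequences of one segment.
enum_oracle <- function(L, log_pi, log_theta) {
  Tn <- nrow(L)
  K <- ncol(L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lpost <- apply(paths, 1L, function(s) {
    v <- log_pi[s[1L]] + sum(L[cbind(seq_len(Tn), s)])
    if (Tn > 1L) v <- v + sum(log_theta[cbind(s[-Tn], s[-1L])])
    v
  })
  m <- max(lpost)
  w <- exp(lpost - m)
  logZ <- m + log(sum(w))
  w <- w / sum(w)
  gamma <- sapply(seq_len(K), function(k)
    sapply(seq_len(Tn), function(t) sum(w[paths[, t] == k])))
  xi <- if (Tn > 1L) {
    x <- array(0, c(Tn - 1L, K, K))
    for (t in seq_len(Tn - 1L)) {
      cell <- (paths[, t + 1L] - 1L) * K + paths[, t]
      sums <- vapply(seq_len(K * K), function(j) sum(w[cell == j]), numeric(1))
      x[t, , ] <- matrix(sums, K, K)
    }
    x
  } else array(0, c(0L, K, K))
  list(gamma = matrix(gamma, Tn, K), xi = xi, logZ = logZ,
       vpath = as.integer(paths[which.max(lpost), ]))
}

rand_chain <- function(K) {
  pi0 <- stats::runif(K) + 0.1
  pi0 <- pi0 / sum(pi0)
  th <- matrix(stats::runif(K * K) + 0.1, K, K)
  list(pi = pi0, theta = th / rowSums(th))
}

# standard 2-state sticky fixture
two_state_params <- function(sep = 3, stay = 0.9) {
  cfg <- glhmm_config(K = 2, mean_mode = "state", cov_mode = "shared")
  glhmm_params(cfg, mu = rbind(c(-sep, 0), c(sep, 0)),
               Sigma = array(diag(2), c(2, 2, 1)),
               theta = matrix(c(stay, 1 - stay, 1 - stay, stay), 2,
                              byrow = TRUE))
}

quiet_control <- function(max_cycles = 30, n_inits = 2, init_cycles = 4,
                          tol = 1e-6) {
  glhmm_control(max_cycles = max_cycles, tol = tol, n_inits = n_inits,
                init_cycles = init_cycles)
}
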