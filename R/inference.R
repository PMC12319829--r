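# Variational inference engine for the GLHMM.
#
# Variational factorisation: q(s) q(pi) q(theta rows) x Gaussian factors for
# the regression coefficients (per state or shared, factorised over output
# channels) x Wishart (full) or Gamma (diagonal) factors for the precisions.
# The E-step uses expected log parameters (digamma-based) from the Dirichlet
# posteriors and expected precisions from the Wishart/Gamma posteriors, which
# is the standard variational treatment and guarantees a monotonically
# decreasing free energy under exact coordinate updates.

# ---- design matrix and coefficient block structure ----------------------

build_design <- function(config, data) {
  cols <- list()
  D <- NULL
  blocks <- list()
  d <- 0L
  if (config$mean_mode != "none") {
    D <- cbind(D, rep(1, data$T))
    blocks[[length(blocks) + 1L]] <- list(name = "mu", cols = d + 1L,
                                          mode = config$mean_mode, nb = 1L)
    d <- d + 1L
  }
  if (config$beta_mode != "none") {
    if (is.null(data$X))
      stop("beta_mode != 'none' requires independent data `X`.", call. = FALSE)
    D <- cbind(D, data$X)
    blocks[[length(blocks) + 1L]] <- list(name = "beta", cols = d + seq_len(data$p),
                                          mode = config$beta_mode, nb = data$p)
    d <- d + data$p
  }
  list(D = D, blocks = blocks, d = d)
}

build_priors <- function(config, q) {
  nu0 <- config$prior$wishart_dof %||% q
  scale <- config$prior$wishart_scale %||% (1 / q)
  list(coef_var = config$prior$coef_var,
       nu0 = nu0,
       V0 = diag(scale, q), V0inv = diag(1 / scale, q),
       a0 = nu0 / 2, b0 = 1 / (2 * scale),
       dir_base = config$prior$dirichlet_base,
       dir_diag = config$dirichlet_diag)
}

# Dirichlet prior concentration matrices for pi and theta (0 on masked entries)
chain_priors <- function(config, priors) {
  K <- config$K
  A <- mask_matrix(config$transition_mask, K)
  theta0 <- matrix(priors$dir_base, K, K) + diag(priors$dir_diag, K)
  theta0[!A] <- 0
  list(pi0 = rep(priors$dir_base, K), theta0 = theta0, mask = A)
}

# ---- posterior container -------------------------------------------------

# Fresh posterior with all factors at their priors.
init_posterior <- function(config, priors, q, meta) {
  K <- config$K
  obs <- list(blocks = meta$blocks, m = list(), S = list())
  for (b in seq_along(meta$blocks)) {
    blk <- meta$blocks[[b]]
    ns <- if (blk$mode == "state") K else 1L
    obs$m[[b]] <- array(0, c(ns, blk$nb, q))
    obs$S[[b]] <- lapply(seq_len(ns), function(i)
      lapply(seq_len(q), function(j) diag(priors$coef_var, blk$nb)))
  }
  cov <- switch(config$cov_mode,
    identity = list(type = "identity",
                    ELambda = array(diag(q), c(q, q, 1L)), Elogdet = 0),
    {
      Kc <- if (config$cov_mode == "state") K else 1L
      if (config$cov_shape == "full") {
        list(type = "wishart",
             V = array(priors$V0, c(q, q, Kc)), nu = rep(priors$nu0, Kc),
             ELambda = array(priors$nu0 * priors$V0, c(q, q, Kc)),
             Elogdet = rep(wishart_elogdet(priors$V0, priors$nu0), Kc))
      } else {
        a <- matrix(priors$a0, Kc, q); bb <- matrix(priors$b0, Kc, q)
        list(type = "gamma", a = a, b = bb,
             ELambda = array(diag(q) * (priors$a0 / priors$b0), c(q, q, Kc)),
             Elogdet = rep(q * (digamma(priors$a0) - log(priors$b0)), Kc))
      }
    })
  cp <- chain_priors(config, priors)
  chain <- list(pi_alpha = cp$pi0, theta_alpha = cp$theta0, mask = cp$mask)
  chain <- chain_expectations(chain)
  list(config = config, q = q, obs = obs, cov = cov, chain = chain)
}

chain_expectations <- function(chain) {
  K <- length(chain$pi_alpha)
  chain$Elog_pi <- digamma(chain$pi_alpha) - digamma(sum(chain$pi_alpha))
  El <- matrix(-Inf, K, K)
  for (l in seq_len(K)) {
    a <- chain$theta_alpha[l, ]
    ok <- chain$mask[l, ]
    El[l, ok] <- digamma(a[ok]) - digamma(sum(a[ok]))
  }
  chain$Elog_theta <- El
  chain
}

cov_EL <- function(post, k) {
  i <- min(k, dim(post$cov$ELambda)[3L])
  matrix(post$cov$ELambda[, , i], post$q, post$q)
}
cov_elogdet <- function(post, k) post$cov$Elogdet[min(k, length(post$cov$Elogdet))]

# Assemble the d x q posterior-mean coefficient matrix seen by state k.
assemble_M <- function(post, k, d) {
  M <- matrix(0, d, post$q)
  for (b in seq_along(post$obs$blocks)) {
    blk <- post$obs$blocks[[b]]
    i <- if (blk$mode == "state") k else 1L
    M[blk$cols, ] <- matrix(post$obs$m[[b]][i, , ], blk$nb, post$q)
  }
  M
}

# ---- expected log-likelihood --------------------------------------------

expected_loglik <- function(post, data, meta) {
  K <- post$config$K
  q <- post$q
  L <- matrix(0, data$T, K)
  for (k in seq_len(K)) {
    EL <- cov_EL(post, k)
    if (meta$d > 0L) {
      M <- assemble_M(post, k, meta$d)
      R <- data$Y - meta$D %*% M
    } else R <- data$Y
    quad <- rowSums((R %*% EL) * R)
    u <- 0
    for (b in seq_along(post$obs$blocks)) {
      blk <- post$obs$blocks[[b]]
      i <- if (blk$mode == "state") k else 1L
      Db <- meta$D[, blk$cols, drop = FALSE]
      for (j in seq_len(q)) {
        Sb <- post$obs$S[[b]][[i]][[j]]
        u <- u + EL[j, j] * rowSums((Db %*% Sb) * Db)
      }
    }
    L[, k] <- 0.5 * cov_elogdet(post, k) - 0.5 * q * log(2 * pi) -
      0.5 * (quad + u)
  }
  L
}

# ---- forward-backward ----------------------------------------------------

#' Forward-backward smoothing for one or more segments
#'
#' Scaled forward-backward recursions computing the per-time-point state
#' probabilities `gamma`, the joint probabilities `xi` of consecutive time
#' points, and the per-segment log-evidence, given a T x K matrix of (possibly
#' expected) log-likelihoods and chain parameters in log space. Segments are
#' processed independently.
#'
#' @param loglik T x K matrix of log-likelihoods.
#' @param log_pi length-K initial log-probabilities (may be unnormalised
#'   expected logs).
#' @param log_theta K x K transition log-probabilities (`-Inf` where masked).
#' @param indices segment index matrix (1-based inclusive); default one
#'   segment.
#' @return list with `gamma` (T x K, rows sum to 1), `xi` (list per segment of
#'   (len-1) x K x K arrays, each slice summing to 1), `logZ` (per-segment
#'   log-evidence), `start_counts` (column sums of gamma at segment starts)
#'   and `trans_counts` (sum of all xi slices).
#' @export
forward_backward <- function(loglik, log_pi, log_theta, indices = NULL) {
  loglik <- as_matrix(loglik, "loglik")
  K <- ncol(loglik)
  if (is.null(indices)) indices <- matrix(c(1L, nrow(loglik)), 1L, 2L)
  indices <- matrix(as.integer(indices), ncol = 2L)
  P <- exp(log_theta)
  pi1 <- exp(log_pi)
  gamma <- matrix(0, nrow(loglik), K)
  xi <- vector("list", nrow(indices))
  logZ <- numeric(nrow(indices))
  start_counts <- numeric(K)
  trans_counts <- matrix(0, K, K)
  for (i in seq_len(nrow(indices))) {
    rows <- seq.int(indices[i, 1L], indices[i, 2L])
    L <- loglik[rows, , drop = FALSE]
    Tn <- length(rows)
    shift <- apply(L, 1L, max)
    if (any(!is.finite(shift)))
      stop("All-zero likelihood row: no state can explain some time point.",
           call. = FALSE)
    B <- exp(L - shift)
    alpha <- matrix(0, Tn, K)
    cvec <- numeric(Tn)
    a <- pi1 * B[1L, ]
    cvec[1L] <- sum(a)
    alpha[1L, ] <- a / cvec[1L]
    if (Tn > 1L) for (t in 2L:Tn) {
      a <- as.numeric(alpha[t - 1L, ] %*% P) * B[t, ]
      cvec[t] <- sum(a)
      if (cvec[t] <= 0)
        stop("Forward recursion underflow: no feasible path.", call. = FALSE)
      alpha[t, ] <- a / cvec[t]
    }
    beta <- matrix(0, Tn, K)
    beta[Tn, ] <- 1
    if (Tn > 1L) for (t in (Tn - 1L):1L) {
      beta[t, ] <- as.numeric(P %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
    }
    g <- alpha * beta
    g <- row_normalise(g)
    gamma[rows, ] <- g
    if (Tn > 1L) {
      x <- array(0, c(Tn - 1L, K, K))
      for (t in seq_len(Tn - 1L)) {
        M <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * P / cvec[t + 1L]
        s <- sum(M)
        x[t, , ] <- M / s
      }
      xi[[i]] <- x
      trans_counts <- trans_counts + apply(x, c(2L, 3L), sum)
    } else xi[[i]] <- array(0, c(0L, K, K))
    logZ[i] <- sum(log(cvec)) + sum(shift)
    start_counts <- start_counts + g[1L, ]
  }
  list(gamma = gamma, xi = xi, logZ = logZ,
       start_counts = start_counts, trans_counts = trans_counts)
}

# ---- sufficient statistics ----------------------------------------------

compute_stats <- function(data, meta, fb) {
  K <- ncol(fb$gamma)
  d <- meta$d
  q <- data$q
  n <- colSums(fb$gamma)
  G <- array(0, c(max(d, 1L), max(d, 1L), K))
  H <- array(0, c(max(d, 1L), q, K))
  Q <- array(0, c(q, q, K))
  for (k in seq_len(K)) {
    w <- fb$gamma[, k]
    Yw <- data$Y * w
    Q[, , k] <- crossprod(Yw, data$Y)
    if (d > 0L) {
      Dw <- meta$D * w
      G[, , k] <- crossprod(Dw, meta$D)
      H[, , k] <- crossprod(Dw, data$Y)
    }
  }
  list(n = n, G = G, H = H, Q = Q,
       start = fb$start_counts, trans = fb$trans_counts,
       Ttot = data$T, d = d, q = q, K = K)
}

scale_stats <- function(stats, f) {
  stats$n <- stats$n * f
  stats$G <- stats$G * f
  stats$H <- stats$H * f
  stats$Q <- stats$Q * f
  stats$start <- stats$start * f
  stats$trans <- stats$trans * f
  stats$Ttot <- stats$Ttot * f
  stats
}

blend_stats <- function(old, new, rho) {
  for (nm in c("n", "G", "H", "Q", "start", "trans", "Ttot"))
    old[[nm]] <- (1 - rho) * old[[nm]] + rho * new[[nm]]
  old
}

# ---- M-step: observation model ------------------------------------------

# One exact coordinate-ascent pass over all coefficient blocks and columns,
# then the precision factors. Operates on and returns `post`.
mstep_obs <- function(stats, post, priors, update_cov = TRUE) {
  config <- post$config
  K <- config$K
  q <- post$q
  d <- stats$d
  blocks <- post$obs$blocks
  if (d > 0L) {
    Mfull <- lapply(seq_len(K), function(k) assemble_M(post, k, d))
    EL <- lapply(seq_len(K), function(k) cov_EL(post, k))
    for (j in seq_len(q)) {
      for (b in seq_along(blocks)) {
        blk <- blocks[[b]]
        ks_sets <- if (blk$mode == "state") as.list(seq_len(K)) else list(seq_len(K))
        for (ii in seq_along(ks_sets)) {
          ks <- ks_sets[[ii]]
          prec <- diag(1 / priors$coef_var, blk$nb)
          lin <- numeric(blk$nb)
          for (k in ks) {
            Gk <- matrix(stats$G[, , k], d, d)
            Hk <- matrix(stats$H[, , k], d, q)
            Ejj <- EL[[k]][j, j]
            prec <- prec + Ejj * Gk[blk$cols, blk$cols, drop = FALSE]
            # own-column residual excluding this block's contribution
            mj <- Mfull[[k]][, j]
            mj[blk$cols] <- 0
            lin <- lin + Ejj * (Hk[blk$cols, j] -
                                  as.numeric(Gk[blk$cols, , drop = FALSE] %*% mj))
            for (l in seq_len(q)) if (l != j) {
              Ejl <- EL[[k]][j, l]
              if (Ejl != 0) {
                rl <- Hk[blk$cols, l] -
                  as.numeric(Gk[blk$cols, , drop = FALSE] %*% Mfull[[k]][, l])
                lin <- lin + Ejl * rl
              }
            }
          }
          ch <- tryCatch(chol(prec), error = function(e)
            stop("Singular weighted design in the observation update; ",
                 "consider a stronger coefficient prior.", call. = FALSE))
          Sb <- chol2inv(ch)
          mb <- as.numeric(Sb %*% lin)
          idx <- if (blk$mode == "state") ks[1L] else 1L
          post$obs$m[[b]][idx, , j] <- mb
          post$obs$S[[b]][[idx]][[j]] <- Sb
          for (k in ks) Mfull[[k]][blk$cols, j] <- mb
        }
      }
    }
  } else Mfull <- lapply(seq_len(K), function(k) matrix(0, 0L, q))
  if (update_cov && post$cov$type != "identity")
    post <- mstep_cov(stats, post, priors, Mfull)
  post
}

# Expected weighted residual scatter per state, E[ R' Gamma_k R ].
expected_scatter <- function(stats, post, Mfull, k) {
  d <- stats$d
  q <- post$q
  Qk <- matrix(stats$Q[, , k], q, q)
  if (d == 0L) return(Qk)
  Gk <- matrix(stats$G[, , k], d, d)
  Hk <- matrix(stats$H[, , k], d, q)
  M <- Mfull[[k]]
  ERR <- Qk - crossprod(Hk, M) - crossprod(M, Hk) + crossprod(M, Gk %*% M)
  u <- numeric(q)
  for (b in seq_along(post$obs$blocks)) {
    blk <- post$obs$blocks[[b]]
    i <- if (blk$mode == "state") k else 1L
    Gbb <- Gk[blk$cols, blk$cols, drop = FALSE]
    for (j in seq_len(q)) u[j] <- u[j] + sum(Gbb * post$obs$S[[b]][[i]][[j]])
  }
  ERR + diag(u, q)
}

mstep_cov <- function(stats, post, priors, Mfull) {
  config <- post$config
  K <- config$K
  q <- post$q
  Kc <- if (config$cov_mode == "state") K else 1L
  for (i in seq_len(Kc)) {
    ks <- if (config$cov_mode == "state") i else seq_len(K)
    ERR <- matrix(0, q, q)
    for (k in ks) ERR <- ERR + expected_scatter(stats, post, Mfull, k)
    nobs <- if (config$cov_mode == "state") stats$n[i] else stats$Ttot
    if (post$cov$type == "wishart") {
      Vinv <- priors$V0inv + (ERR + t(ERR)) / 2
      V <- chol2inv(chol(Vinv))
      nu <- priors$nu0 + nobs
      post$cov$V[, , i] <- V
      post$cov$nu[i] <- nu
      post$cov$ELambda[, , i] <- nu * V
      post$cov$Elogdet[i] <- wishart_elogdet(V, nu)
    } else {
      a <- priors$a0 + nobs / 2
      bb <- priors$b0 + pmax(diag(ERR), 0) / 2
      post$cov$a[i, ] <- a
      post$cov$b[i, ] <- bb
      post$cov$ELambda[, , i] <- diag(a / bb, q)
      post$cov$Elogdet[i] <- sum(digamma(a) - log(bb))
    }
  }
  post
}

# ---- M-step: chain -------------------------------------------------------

#' Dirichlet posterior update for initial and transition probabilities
#'
#' Conjugate update: posterior concentration = prior concentration (base mass
#' on every allowed entry, plus the temporal-regularisation mass
#' `dirichlet_diag` on the diagonal of the transition prior) + expected counts
#' (state probabilities at segment starts for \eqn{\pi}; summed joint
#' probabilities `xi` for \eqn{\theta}). Entries forbidden by the transition
#' mask keep zero concentration, hence exactly zero posterior mass.
#'
#' @param start_counts length-K vector of summed state probabilities at
#'   segment starts.
#' @param trans_counts K x K matrix of summed pairwise probabilities.
#' @param config a [glhmm_config()].
#' @return list with `pi_alpha` (length K) and `theta_alpha` (K x K).
#' @export
update_chain <- function(start_counts, trans_counts, config) {
  priors <- build_priors(config, q = 1L)
  cp <- chain_priors(config, priors)
  theta_alpha <- cp$theta0 + trans_counts
  theta_alpha[!cp$mask] <- 0
  list(pi_alpha = cp$pi0 + start_counts, theta_alpha = theta_alpha)
}

mstep_chain <- function(stats, post, priors) {
  cp <- chain_priors(post$config, priors)
  post$chain$pi_alpha <- cp$pi0 + stats$start
  ta <- cp$theta0 + stats$trans
  ta[!cp$mask] <- 0
  post$chain$theta_alpha <- ta
  chain_expectations_into(post)
}

chain_expectations_into <- function(post) {
  post$chain <- chain_expectations(post$chain)
  post
}

# ---- KL divergences and free energy -------------------------------------

posterior_kl <- function(post, priors) {
  config <- post$config
  K <- config$K
  q <- post$q
  kl <- 0
  # coefficients
  for (b in seq_along(post$obs$blocks)) {
    blk <- post$obs$blocks[[b]]
    ns <- if (blk$mode == "state") K else 1L
    for (i in seq_len(ns)) for (j in seq_len(q))
      kl <- kl + kl_gaussian_iso(post$obs$m[[b]][i, , j],
                                 post$obs$S[[b]][[i]][[j]], priors$coef_var)
  }
  # precisions
  if (post$cov$type == "wishart") {
    for (i in seq_along(post$cov$nu))
      kl <- kl + kl_wishart(matrix(post$cov$V[, , i], q, q), post$cov$nu[i],
                            priors$V0, priors$nu0)
  } else if (post$cov$type == "gamma") {
    for (i in seq_len(nrow(post$cov$a))) for (j in seq_len(q))
      kl <- kl + kl_gamma(post$cov$a[i, j], post$cov$b[i, j],
                          priors$a0, priors$b0)
  }
  # chain
  cp <- chain_priors(config, priors)
  kl <- kl + kl_dirichlet(post$chain$pi_alpha, cp$pi0)
  for (l in seq_len(K)) {
    ok <- cp$mask[l, ]
    kl <- kl + kl_dirichlet(post$chain$theta_alpha[l, ok], cp$theta0[l, ok])
  }
  kl
}

#' Variational free energy of a fitted model
#'
#' The negative evidence lower bound: minus the expected log-likelihood and
#' chain entropy terms (equivalently, minus the log-evidence of the
#' expected-parameter chain accumulated by the forward recursions), plus the
#' KL divergences of all posterior factors from their priors. Lower is
#' better; across full variational cycles it never increases.
#'
#' @param model a fitted [glhmm()] object.
#' @return scalar free energy (nats).
#' @export
free_energy <- function(model) {
  stopifnot(inherits(model, "glhmm"))
  model$free_energy
}

fe_value <- function(post, priors, logZ) -sum(logZ) + posterior_kl(post, priors)
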