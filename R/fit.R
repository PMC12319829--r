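#' Control parameters for GLHMM fitting
#'
#' @param max_cycles maximum number of full variational cycles (default 100).
#' @param tol relative free-energy change below which the fit stops
#'   (default 1e-5).
#' @param n_inits number of randomised initialisations; each runs
#'   `init_cycles` cycles and the lowest-free-energy run is continued
#'   (default 5).
#' @param init_cycles cycles per initialisation run (default 10).
#' @param verbose print per-cycle free energy.
#' @return list of class `"glhmm_control"`.
#' @export
glhmm_control <- function(max_cycles = 100L, tol = 1e-5, n_inits = 5L,
                          init_cycles = 10L, verbose = FALSE) {
  structure(list(max_cycles = as.integer(max_cycles), tol = tol,
                 n_inits = as.integer(n_inits),
                 init_cycles = as.integer(init_cycles), verbose = verbose),
            class = "glhmm_control")
}

# Randomised initial state probabilities: k-means-style assignment on Y (or on
# the residuals of Y ~ X when a regression component is present), softened and
# perturbed. Consumes RNG.
init_gamma <- function(data, config) {
  K <- config$K
  Tn <- data$T
  if (K == 1L) return(matrix(1, Tn, 1L))
  target <- data$Y
  if (config$beta_mode != "none" && !is.null(data$X)) {
    Xd <- cbind(1, data$X)
    fit <- stats::lm.fit(Xd, data$Y)
    target <- as.matrix(fit$residuals)
  } else target <- scale(target, center = TRUE, scale = FALSE)
  assign0 <- tryCatch(
    stats::kmeans(jitter(target, amount = 1e-8), centers = K, nstart = 1L,
                  iter.max = 20L)$cluster,
    error = function(e) sample.int(K, Tn, replace = TRUE))
  g <- matrix(0.1 / K, Tn, K)
  g[cbind(seq_len(Tn), assign0)] <- g[cbind(seq_len(Tn), assign0)] + 0.9
  g <- g * matrix(exp(0.25 * stats::rnorm(Tn * K)), Tn, K)
  row_normalise(g)
}

# fb-like structure (start/trans counts) from a soft assignment matrix.
fb_from_gamma <- function(gamma, indices) {
  K <- ncol(gamma)
  start_counts <- numeric(K)
  trans_counts <- matrix(0, K, K)
  for (i in seq_len(nrow(indices))) {
    rows <- seq.int(indices[i, 1L], indices[i, 2L])
    start_counts <- start_counts + gamma[rows[1L], ]
    if (length(rows) > 1L) {
      g1 <- gamma[rows[-length(rows)], , drop = FALSE]
      g2 <- gamma[rows[-1L], , drop = FALSE]
      trans_counts <- trans_counts + crossprod(g1, g2)
    }
  }
  list(gamma = gamma, start_counts = start_counts, trans_counts = trans_counts)
}

# Full VI cycles from a given posterior. Returns post (after a trailing
# M-step), the last E-step output, and the free-energy trace (recorded after
# each E-step, hence non-increasing).
vi_run <- function(data, config, priors, meta, post, max_cycles, tol,
                   verbose = FALSE) {
  fe_trace <- numeric(0)
  fb <- NULL
  for (cyc in seq_len(max(max_cycles, 1L))) {
    L <- expected_loglik(post, data, meta)
    fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                           data$indices)
    fe <- fe_value(post, priors, fb$logZ)
    fe_trace <- c(fe_trace, fe)
    if (verbose) message(sprintf("cycle %d: free energy %.6f", cyc, fe))
    if (cyc > 1L &&
        abs(fe - fe_trace[cyc - 1L]) < tol * abs(fe_trace[cyc - 1L])) break
    stats <- compute_stats(data, meta, fb)
    post <- mstep_obs(stats, post, priors)
    post <- mstep_chain(stats, post, priors)
  }
  # trailing M-step so the stored posterior is the conjugate image of the
  # final responsibilities, then a final E-step so the stored state time
  # courses are exactly the smoothing of the stored posterior
  stats <- compute_stats(data, meta, fb)
  post <- mstep_obs(stats, post, priors)
  post <- mstep_chain(stats, post, priors)
  L <- expected_loglik(post, data, meta)
  fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                         data$indices)
  fe_trace <- c(fe_trace, fe_value(post, priors, fb$logZ))
  list(post = post, fb = fb, fe_trace = fe_trace)
}

#' Fit a Gaussian-linear hidden Markov model
#'
#' Estimates a GLHMM by variational Bayes: the state distribution is
#' \eqn{Y_t \sim N(\mu_k + X_t \beta_k, \Sigma_k)} with Gaussian priors on
#' \eqn{\mu_k}, \eqn{\beta_k}, a Wishart prior on \eqn{\Sigma_k^{-1}} and
#' Dirichlet priors on the initial and transition probabilities (with extra
#' mass `dirichlet_diag` on self-transitions as temporal regularisation).
#' Inference alternates forward-backward smoothing of the state time courses
#' with conjugate updates of the state and chain posteriors until the free
#' energy stabilises; several randomised initialisations are tried and the
#' lowest-free-energy run is continued. `method = "svi"` uses stochastic
#' (mini-batch) updates instead, see [svi_schedule()].
#'
#' @param Y dependent data: T x q matrix, or a [glhmm_data()] object (in which
#'   case `X`, `indices`, `subjects` are taken from it).
#' @param X optional independent data (T x p).
#' @param indices segment matrix (1-based inclusive `[start, end]` rows).
#' @param K number of states.
#' @param config optional [glhmm_config()]; when supplied it overrides the
#'   individual mode arguments.
#' @param mean_mode,beta_mode,cov_mode,cov_shape,dirichlet_diag,mask,prior
#'   passed to [glhmm_config()]; `beta_mode` defaults to `"state"` when `X` is
#'   present and `"none"` otherwise.
#' @param method `"vi"` (full-data variational inference) or `"svi"`
#'   (stochastic mini-batches).
#' @param schedule an [svi_schedule()], used when `method = "svi"`.
#' @param control a [glhmm_control()].
#' @param subjects optional subject id per segment.
#' @param seed optional integer; fixing it makes the fit reproducible.
#' @return An object of class `"glhmm"`; see [coef.glhmm()],
#'   [predict.glhmm()], [summary.glhmm()], [free_energy()].
#' @examples
#' sim <- sample_glhmm(
#'   glhmm_params(glhmm_config(K = 2, cov_mode = "shared"),
#'                mu = rbind(c(-2, 0), c(2, 1)),
#'                Sigma = diag(2),
#'                theta = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)),
#'   segment_lengths = rep(100, 4), seed = 1)
#' fit <- glhmm(sim$data, K = 2, cov_mode = "shared", seed = 1,
#'              control = glhmm_control(max_cycles = 30, n_inits = 2))
#' fit
#' @export
glhmm <- function(Y, X = NULL, indices = NULL, K = 2L, config = NULL,
                  mean_mode = "state", beta_mode = NULL,
                  cov_mode = "shared", cov_shape = "full",
                  dirichlet_diag = 10, mask = NULL, prior = list(),
                  method = c("vi", "svi"), schedule = NULL,
                  control = glhmm_control(), subjects = NULL, seed = NULL) {
  method <- match.arg(method)
  data <- if (inherits(Y, "glhmm_data")) Y
          else glhmm_data(Y, X = X, indices = indices, subjects = subjects)
  if (is.null(config)) {
    if (is.null(beta_mode)) beta_mode <- if (is.null(data$X)) "none" else "state"
    config <- glhmm_config(K = K, mean_mode = mean_mode, beta_mode = beta_mode,
                           cov_mode = cov_mode, cov_shape = cov_shape,
                           dirichlet_diag = dirichlet_diag,
                           transition_mask = mask, prior = prior)
  }
  validate_config(config, has_X = !is.null(data$X))
  meta <- build_design(config, data)
  priors <- build_priors(config, data$q)
  cl <- match.call()
  with_seed(seed, {
    if (method == "svi") {
      fit <- svi_fit(data, config, priors, meta, schedule, control)
    } else {
      # multiple short initialisation runs, continue the best
      best <- NULL
      n_inits <- max(control$n_inits, 1L)
      for (i in seq_len(n_inits)) {
        post0 <- init_posterior(config, priors, data$q, meta)
        g0 <- init_gamma(data, config)
        fb0 <- fb_from_gamma(g0, data$indices)
        stats0 <- compute_stats(data, meta, fb0)
        post0 <- mstep_obs(stats0, post0, priors)
        post0 <- mstep_chain(stats0, post0, priors)
        if (n_inits > 1L && control$init_cycles > 0L) {
          run <- vi_run(data, config, priors, meta, post0,
                        control$init_cycles, tol = 0, verbose = FALSE)
          fe_i <- run$fe_trace[length(run$fe_trace)]
          if (is.null(best) || fe_i < best$fe) best <- list(post = run$post, fe = fe_i)
        } else if (is.null(best)) best <- list(post = post0, fe = Inf)
      }
      run <- vi_run(data, config, priors, meta, best$post, control$max_cycles,
                    control$tol, control$verbose)
      fit <- list(post = run$post, fb = run$fb, fe_trace = run$fe_trace)
    }
    post <- fit$post
    L <- expected_loglik(post, data, meta)
    vpath <- viterbi(L, post$chain$Elog_pi, post$chain$Elog_theta,
                     data$indices, mask = config$transition_mask)
    structure(list(config = config, priors = priors, meta = meta,
                   posterior = post, data = data,
                   gamma = fit$fb$gamma, xi = fit$fb$xi,
                   logZ = fit$fb$logZ, vpath = vpath,
                   fe_trace = fit$fe_trace,
                   free_energy = fit$fe_trace[length(fit$fe_trace)],
                   K = config$K, seed = seed, call = cl),
              class = "glhmm")
  })
}

#' Observation-model posterior from fixed state probabilities
#'
#' Conjugate Bayesian update of the state (and shared) Gaussian regression
#' factors and the precision factors, for fixed state probabilities `gamma`:
#' each state's coefficients get a weighted Bayesian linear-regression
#' posterior with weights `gamma[, k]`; shared components pool all time
#' points; the precision posterior degrees of freedom grow by the summed
#' weights (or by T when shared). Runs a few exact coordinate passes starting
#' from the priors (coefficient and precision factors are coupled), which is
#' enough for the factors to settle at this fixed `gamma`.
#'
#' @param data a [glhmm_data()].
#' @param gamma T x K matrix of state probabilities (rows sum to 1).
#' @param config a [glhmm_config()].
#' @param passes number of coordinate passes (default 3).
#' @return The internal posterior structure (elements `obs`, `cov`), with a
#'   `coefficients` element holding posterior means in user-facing shapes as
#'   in [coef.glhmm()].
#' @export
update_observation_model <- function(data, gamma, config, passes = 3L) {
  stopifnot(inherits(data, "glhmm_data"))
  gamma <- as_matrix(gamma, "gamma")
  if (nrow(gamma) != data$T || ncol(gamma) != config$K)
    stop("`gamma` must be T x K.", call. = FALSE)
  meta <- build_design(config, data)
  priors <- build_priors(config, data$q)
  post <- init_posterior(config, priors, data$q, meta)
  fb0 <- fb_from_gamma(gamma, data$indices)
  stats <- compute_stats(data, meta, fb0)
  for (i in seq_len(passes)) post <- mstep_obs(stats, post, priors)
  post$coefficients <- extract_coefficients(post, meta, data$q)
  post
}

# User-facing posterior means.
extract_coefficients <- function(post, meta, q) {
  config <- post$config
  K <- config$K
  out <- list(mu = NULL, beta = NULL, Sigma = NULL)
  for (b in seq_along(post$obs$blocks)) {
    blk <- post$obs$blocks[[b]]
    ns <- dim(post$obs$m[[b]])[1L]
    if (blk$name == "mu") {
      out$mu <- matrix(post$obs$m[[b]][, 1L, ], ns, q)
    } else {
      out$beta <- array(aperm(post$obs$m[[b]], c(2L, 3L, 1L)), c(blk$nb, q, ns))
    }
  }
  Kc <- dim(post$cov$ELambda)[3L]
  out$Sigma <- array(0, c(q, q, Kc))
  for (i in seq_len(Kc))
    out$Sigma[, , i] <- chol2inv(chol(matrix(post$cov$ELambda[, , i], q, q)))
  out$pi <- post$chain$pi_alpha / sum(post$chain$pi_alpha)
  out$theta <- row_normalise(post$chain$theta_alpha)
  out
}
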