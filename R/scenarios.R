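# Scenario catalogue: scripted generators that tie the whole toolbox together
# for tests and tutorials. Each scenario mirrors a data regime the model is
# used for in practice: unsupervised Gaussian states (fMRI-like),
# regression states (LFP/ECoG-like decoding), sequential-task trials
# (MEG-like), a subject cohort with family structure and a trait effect
# (HCP-like), and a continuous co-recorded signal (pupillometry-like).
# Bundles are regenerable bit-exactly from (name, seed); an effect size of 0
# produces an exact null.

scenario_catalogue <- function() {
  c("gaussian_states", "regression_states", "sequential_task",
    "cohort_traits", "visits_signal")
}

#' Generate a synthetic benchmark scenario
#'
#' Produces a complete, deterministic input bundle with documented ground
#' truth. Available scenarios:
#' * `gaussian_states`: K = 3 well-separated Gaussian states (state means,
#'   shared covariance), several segments — unsupervised modelling.
#' * `regression_states`: K = 3 states differing only in their regression
#'   coefficients (`mean_mode = "none"`, shared diagonal covariance) —
#'   decoding-style modelling; ground-truth `beta` attached.
#' * `sequential_task`: equal-length trials traversing K = 4 states in
#'   strict sequence; a binary condition scales the progression speed by
#'   `effect` (0 = exact null) — across-trials testing.
#' * `cohort_traits`: a cohort of subjects (twin pairs + singletons, family
#'   ids in `blocks`) whose state-1 mean is shifted by `effect * trait`;
#'   `R` holds the trait, `C` a confound uncorrelated with it —
#'   across-subjects testing and prediction.
#' * `visits_signal`: one long recording plus a continuous signal `S` whose
#'   level depends on the active state with strength `effect` —
#'   across-visits testing.
#'
#' @param name scenario name, see above.
#' @param overrides named list overriding scenario defaults (e.g.
#'   `n_subjects`, `seg_len`, `effect`, `n_trials`).
#' @param seed integer seed; the bundle is a deterministic function of
#'   `(name, overrides, seed)`.
#' @return list with elements `name`, `data` ([glhmm_data()]), `states`
#'   (true path), `params` (true [glhmm_params()]), plus scenario-specific
#'   elements (`D`, `R`, `C`, `blocks`, `S`, `trait`, `condition`, `mask`,
#'   `effect`).
#' @export
generate_scenario <- function(name, overrides = list(), seed = 1L) {
  if (!name %in% scenario_catalogue())
    stop(sprintf("Unknown scenario '%s'. Available: %s", name,
                 paste(scenario_catalogue(), collapse = ", ")), call. = FALSE)
  fun <- switch(name,
                gaussian_states = scenario_gaussian_states,
                regression_states = scenario_regression_states,
                sequential_task = scenario_sequential_task,
                cohort_traits = scenario_cohort_traits,
                visits_signal = scenario_visits_signal)
  with_seed(seed, {
    out <- fun(overrides)
    out$name <- name
    out$seed <- seed
    out
  })
}

sticky_theta <- function(K, stay) {
  th <- matrix((1 - stay) / (K - 1), K, K)
  diag(th) <- stay
  th
}

scenario_gaussian_states <- function(ov) {
  o <- utils::modifyList(list(K = 3L, q = 3L, n_segments = 6L, seg_len = 200L,
                              sep = 2, stay = 0.9), ov)
  cfg <- glhmm_config(K = o$K, mean_mode = "state", beta_mode = "none",
                      cov_mode = "shared", cov_shape = "full")
  mu <- matrix(0, o$K, o$q)
  for (k in seq_len(o$K)) mu[k, ] <- o$sep * sin(2 * pi * (k - 1) / o$K + seq_len(o$q))
  Sigma <- diag(o$q) * 1
  params <- glhmm_params(cfg, mu = mu, Sigma = array(Sigma, c(o$q, o$q, 1L)),
                         theta = sticky_theta(o$K, o$stay))
  sim <- sample_glhmm(params, rep(o$seg_len, o$n_segments))
  list(data = sim$data, states = sim$states, params = params, config = cfg)
}

scenario_regression_states <- function(ov) {
  o <- utils::modifyList(list(K = 3L, p = 3L, q = 2L, n_segments = 10L,
                              seg_len = 250L, scale = 2, stay = 0.92,
                              noise_sd = 1), ov)
  cfg <- glhmm_config(K = o$K, mean_mode = "none", beta_mode = "state",
                      cov_mode = "shared", cov_shape = "diagonal")
  beta <- array(stats::rnorm(o$p * o$q * o$K, sd = o$scale), c(o$p, o$q, o$K))
  Sigma <- array(diag(o$noise_sd^2, o$q), c(o$q, o$q, 1L))
  params <- glhmm_params(cfg, beta = beta, Sigma = Sigma,
                         theta = sticky_theta(o$K, o$stay))
  sim <- sample_glhmm(params, rep(o$seg_len, o$n_segments))
  list(data = sim$data, states = sim$states, params = params, config = cfg,
       beta = beta)
}

scenario_sequential_task <- function(ov) {
  o <- utils::modifyList(list(K = 4L, q = 2L, n_trials = 40L, trial_len = 60L,
                              sep = 2, advance = 0.08, effect = 0.1), ov)
  mask <- make_transition_mask("sequential", o$K)
  mu <- matrix(0, o$K, o$q)
  for (k in seq_len(o$K)) mu[k, ] <- o$sep * c(cos(k), sin(k))
  condition <- rep(c(0L, 1L), length.out = o$n_trials)
  Y <- NULL
  states <- integer(0)
  for (tr in seq_len(o$n_trials)) {
    s <- integer(o$trial_len)
    s[1L] <- 1L
    # condition scales the progression rate; effect = 0 is an exact null
    p_adv <- o$advance * (1 + o$effect * condition[tr])
    for (t in 2L:o$trial_len) {
      cur <- s[t - 1L]
      s[t] <- if (cur < o$K && stats::runif(1) < p_adv) cur + 1L else cur
    }
    Y <- rbind(Y, mu[s, ] + matrix(stats::rnorm(o$trial_len * o$q, sd = 1),
                                   o$trial_len, o$q))
    states <- c(states, s)
  }
  idx <- cbind(seq(1L, by = o$trial_len, length.out = o$n_trials),
               seq(o$trial_len, by = o$trial_len, length.out = o$n_trials))
  cfg <- glhmm_config(K = o$K, mean_mode = "state", beta_mode = "none",
                      cov_mode = "shared", cov_shape = "diagonal",
                      transition_mask = mask)
  list(data = glhmm_data(Y, indices = idx), states = states, config = cfg,
       params = NULL, mask = mask, condition = condition, R = cbind(condition),
       effect = o$effect)
}

scenario_cohort_traits <- function(ov) {
  o <- utils::modifyList(list(n_subjects = 24L, n_twin_pairs = 8L,
                              segments_per_subject = 2L, seg_len = 150L,
                              K = 3L, q = 3L, sep = 2, stay = 0.9,
                              effect = 0.5), ov)
  N <- o$n_subjects
  blocks <- integer(N)
  fam <- 1L
  i <- 1L
  while (i <= 2L * o$n_twin_pairs && i < N) {
    blocks[i] <- fam; blocks[i + 1L] <- fam
    fam <- fam + 1L; i <- i + 2L
  }
  while (i <= N) { blocks[i] <- fam; fam <- fam + 1L; i <- i + 1L }
  trait <- stats::rnorm(N)
  confound <- stats::rnorm(N)
  cfg <- glhmm_config(K = o$K, mean_mode = "state", beta_mode = "none",
                      cov_mode = "shared", cov_shape = "full")
  mu0 <- matrix(0, o$K, o$q)
  for (k in seq_len(o$K)) mu0[k, ] <- o$sep * sin(2 * pi * (k - 1) / o$K + seq_len(o$q))
  dir_vec <- rep(1 / sqrt(o$q), o$q)
  Ylist <- list(); states <- integer(0); subjects <- integer(0)
  for (s in seq_len(N)) {
    mu_s <- mu0
    mu_s[1L, ] <- mu_s[1L, ] + o$effect * trait[s] * dir_vec
    params_s <- glhmm_params(cfg, mu = mu_s,
                             Sigma = array(diag(o$q), c(o$q, o$q, 1L)),
                             theta = sticky_theta(o$K, o$stay))
    sim <- sample_glhmm(params_s, rep(o$seg_len, o$segments_per_subject))
    Ylist[[s]] <- sim$data$Y
    states <- c(states, sim$states)
    subjects <- c(subjects, rep(s, o$segments_per_subject))
  }
  Y <- do.call(rbind, Ylist)
  lens <- rep(o$seg_len, N * o$segments_per_subject)
  ends <- cumsum(lens)
  idx <- cbind(ends - lens + 1L, ends)
  params0 <- glhmm_params(cfg, mu = mu0, Sigma = array(diag(o$q), c(o$q, o$q, 1L)),
                          theta = sticky_theta(o$K, o$stay))
  list(data = glhmm_data(Y, indices = idx, subjects = subjects),
       states = states, params = params0, config = cfg,
       trait = trait, R = cbind(trait), C = cbind(confound),
       blocks = blocks, effect = o$effect)
}

scenario_visits_signal <- function(ov) {
  o <- utils::modifyList(list(K = 3L, q = 2L, n_segments = 4L, seg_len = 250L,
                              sep = 2, stay = 0.88, effect = 1,
                              signal_sd = 1), ov)
  cfg <- glhmm_config(K = o$K, mean_mode = "state", beta_mode = "none",
                      cov_mode = "shared", cov_shape = "full")
  mu <- matrix(0, o$K, o$q)
  for (k in seq_len(o$K)) mu[k, ] <- o$sep * sin(2 * pi * (k - 1) / o$K + seq_len(o$q))
  params <- glhmm_params(cfg, mu = mu, Sigma = array(diag(o$q), c(o$q, o$q, 1L)),
                         theta = sticky_theta(o$K, o$stay))
  sim <- sample_glhmm(params, rep(o$seg_len, o$n_segments))
  level <- seq_len(o$K) - mean(seq_len(o$K))
  S <- o$effect * level[sim$states] +
    stats::rnorm(length(sim$states), sd = o$signal_sd)
  list(data = sim$data, states = sim$states, params = params, config = cfg,
       S = S, effect = o$effect)
}
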