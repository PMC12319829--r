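#' Ground-truth or point parameters of a GLHMM
#'
#' Bundles state parameters (\eqn{\mu}, \eqn{\beta}, \eqn{\Sigma}) and chain
#' parameters (initial probabilities \eqn{\pi}, transition matrix
#' \eqn{\theta}) in the shapes implied by a configuration. Shared components
#' are stored with a leading/trailing axis of size 1 and broadcast across
#' states, so downstream code is mode-agnostic.
#'
#' @param config a [glhmm_config()].
#' @param mu K x q matrix (state), 1 x q (shared), or `NULL` (fixed to zero).
#' @param beta p x q x K array (state), p x q x 1 or p x q matrix (shared),
#'   or `NULL` (fixed to zero).
#' @param Sigma q x q x K array (state), q x q x 1 or q x q matrix (shared),
#'   or `NULL` (identity). Must be symmetric positive definite; diagonal
#'   matrices only when `cov_shape = "diagonal"`.
#' @param pi probability vector of length K (per-segment initial-state
#'   distribution).
#' @param theta row-stochastic K x K transition matrix; entries forbidden by
#'   the configuration's transition mask must be zero.
#' @param q number of dependent channels (needed when `Sigma` is `NULL`).
#' @return An object of class `"glhmm_params"`.
#' @export
glhmm_params <- function(config, mu = NULL, beta = NULL, Sigma = NULL,
                         pi = NULL, theta = NULL, q = NULL) {
  K <- config$K
  if (config$mean_mode == "none" && !is.null(mu))
    stop("mean_mode = 'none' but `mu` supplied.", call. = FALSE)
  if (config$beta_mode == "none" && !is.null(beta))
    stop("beta_mode = 'none' but `beta` supplied.", call. = FALSE)
  if (config$cov_mode == "identity" && !is.null(Sigma))
    stop("cov_mode = 'identity' but `Sigma` supplied.", call. = FALSE)
  if (!is.null(mu)) {
    mu <- as_matrix(mu, "mu")
    want <- if (config$mean_mode == "state") K else 1L
    if (nrow(mu) != want)
      stop(sprintf("`mu` must have %d row(s) for mean_mode = '%s'.",
                   want, config$mean_mode), call. = FALSE)
  }
  if (!is.null(beta)) {
    if (is.matrix(beta)) beta <- array(beta, c(nrow(beta), ncol(beta), 1L))
    want <- if (config$beta_mode == "state") K else 1L
    if (dim(beta)[3L] != want)
      stop(sprintf("`beta` must have %d slice(s) for beta_mode = '%s'.",
                   want, config$beta_mode), call. = FALSE)
  }
  if (!is.null(Sigma)) {
    if (is.matrix(Sigma)) Sigma <- array(Sigma, c(nrow(Sigma), ncol(Sigma), 1L))
    want <- if (config$cov_mode == "state") K else 1L
    if (dim(Sigma)[3L] != want)
      stop(sprintf("`Sigma` must have %d slice(s) for cov_mode = '%s'.",
                   want, config$cov_mode), call. = FALSE)
    qS <- dim(Sigma)[1L]
    for (i in seq_len(dim(Sigma)[3L])) {
      Si <- matrix(Sigma[, , i], qS, qS)
      check_spd(Si, sprintf("Sigma[,,%d]", i))
      if (config$cov_shape == "diagonal" &&
          max(abs(Si - diag(diag(Si), qS))) > 1e-12)
        stop("cov_shape = 'diagonal' but `Sigma` has off-diagonal entries.",
             call. = FALSE)
    }
  }
  qq <- q %||% (if (!is.null(Sigma)) nrow(Sigma) else if (!is.null(mu)) ncol(mu)
                else if (!is.null(beta)) dim(beta)[2L] else
                  stop("Supply `q` when all state components are pre-specified.",
                       call. = FALSE))
  pi <- pi %||% rep(1 / K, K)
  theta <- theta %||% matrix(1 / K, K, K)
  if (length(pi) != K || abs(sum(pi) - 1) > 1e-8 || any(pi < 0))
    stop("`pi` must be a probability vector of length K.", call. = FALSE)
  theta <- as_matrix(theta, "theta")
  if (any(dim(theta) != K) || any(abs(rowSums(theta) - 1) > 1e-8) || any(theta < 0))
    stop("`theta` must be a row-stochastic K x K matrix.", call. = FALSE)
  if (!is.null(config$transition_mask)) {
    m <- config$transition_mask
    if (inherits(m, "glhmm_mask")) m <- m$allowed
    if (any(theta[!m] != 0))
      stop("`theta` has positive mass on entries forbidden by the transition mask.",
           call. = FALSE)
  }
  structure(list(config = config, mu = mu, beta = beta, Sigma = Sigma,
                 pi = as.numeric(pi), theta = theta, q = as.integer(qq),
                 p = if (is.null(beta)) 0L else dim(beta)[1L]),
            class = "glhmm_params")
}

# Broadcast helpers: state-k view of each component (point parameters).
param_mu_k <- function(params, k) {
  if (is.null(params$mu)) rep(0, params$q)
  else params$mu[min(k, nrow(params$mu)), ]
}
param_beta_k <- function(params, k) {
  if (is.null(params$beta)) NULL
  else matrix(params$beta[, , min(k, dim(params$beta)[3L])], params$p, params$q)
}
param_Sigma_k <- function(params, k) {
  if (is.null(params$Sigma)) diag(params$q)
  else matrix(params$Sigma[, , min(k, dim(params$Sigma)[3L])], params$q, params$q)
}
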