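#' Model configuration for a Gaussian-linear hidden Markov model
#'
#' A GLHMM state distribution is \eqn{Y_t \sim N(\mu_k + X_t \beta_k, \Sigma_k)}.
#' Each of the three components can be state-dependent, shared across states
#' (global), or pre-specified: a pre-specified \eqn{\mu} or \eqn{\beta} is fixed
#' to zero, a pre-specified \eqn{\Sigma} is the identity. The covariance, when
#' estimated, can be full or diagonal. At least one component must be
#' state-dependent, otherwise the model has no states to speak of and the
#' configuration is rejected.
#'
#' @param K integer, number of states (>= 1).
#' @param mean_mode one of `"state"`, `"shared"`, `"none"`.
#' @param beta_mode one of `"state"`, `"shared"`, `"none"`. Anything but
#'   `"none"` requires independent data `X` at fit time.
#' @param cov_mode one of `"state"`, `"shared"`, `"identity"`.
#' @param cov_shape `"full"` or `"diagonal"`; ignored when
#'   `cov_mode = "identity"`.
#' @param dirichlet_diag positive scalar: extra Dirichlet prior mass on the
#'   self-transition entries, controlling state persistence (temporal
#'   regularisation). Larger values make switching harder and eventually prune
#'   states.
#' @param transition_mask optional K x K logical matrix of allowed transitions
#'   (see [make_transition_mask()]); `NULL` means all transitions allowed.
#' @param prior list of prior hyperparameters, see Details.
#'
#' @details Prior hyperparameters (all overridable through `prior`):
#' * `coef_var`: variance of the zero-mean Gaussian prior on each entry of
#'   \eqn{\mu} and \eqn{\beta} (default 100, weakly informative).
#' * `wishart_dof`, `wishart_scale`: Wishart prior on the precision
#'   \eqn{\Sigma^{-1}} with degrees of freedom `wishart_dof` (default q, set at
#'   fit time) and scale matrix `wishart_scale * I` (default 1/q), so the prior
#'   mean precision is the identity.
#' * `dirichlet_base`: base concentration on every allowed transition /
#'   initial-probability entry (default 1); `dirichlet_diag` is added on the
#'   diagonal of the transition prior.
#'
#' @return An object of class `"glhmm_config"`.
#' @seealso [validate_config()], [enumerate_valid_configs()], [glhmm()]
#' @export
glhmm_config <- function(K = 2L,
                         mean_mode = c("state", "shared", "none"),
                         beta_mode = c("none", "state", "shared"),
                         cov_mode = c("shared", "state", "identity"),
                         cov_shape = c("full", "diagonal"),
                         dirichlet_diag = 10,
                         transition_mask = NULL,
                         prior = list()) {
  cfg <- structure(list(
    K = as.integer(K),
    mean_mode = match.arg(mean_mode),
    beta_mode = match.arg(beta_mode),
    cov_mode = match.arg(cov_mode),
    cov_shape = match.arg(cov_shape),
    dirichlet_diag = as.numeric(dirichlet_diag),
    transition_mask = transition_mask,
    prior = utils::modifyList(list(coef_var = 100,
                                   wishart_dof = NULL,
                                   wishart_scale = NULL,
                                   dirichlet_base = 1), prior)
  ), class = "glhmm_config")
  validate_config(cfg)
}

#' Validate a GLHMM configuration
#'
#' Checks that a configuration describes a proper state model: at least one of
#' the mean, regression and covariance components must be state-dependent
#' (configurations where every component is shared or pre-specified are
#' "trivial" — they contain no state-dependent structure and are rejected), the
#' temporal-regularisation mass must be positive, and a transition mask, when
#' present, must leave every state at least one successor.
#'
#' @param config a [glhmm_config()] object.
#' @param has_X logical: is independent data `X` available? When `FALSE`, a
#'   `beta_mode` other than `"none"` is an error. `NA` (default) skips this
#'   check until fit time.
#' @return `config`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_config <- function(config, has_X = NA) {
  stopifnot(inherits(config, "glhmm_config") || is.list(config))
  if (config$K < 1L) stop("`K` must be >= 1.", call. = FALSE)
  state_dep <- (config$mean_mode == "state") || (config$beta_mode == "state") ||
    (config$cov_mode == "state")
  if (!state_dep)
    stop(sprintf(paste0("Trivial configuration (mean_mode=%s, beta_mode=%s, ",
                        "cov_mode=%s): no component is state-dependent."),
                 config$mean_mode, config$beta_mode, config$cov_mode),
         call. = FALSE)
  if (isFALSE(has_X) && config$beta_mode != "none")
    stop("beta_mode != 'none' requires independent data `X`.", call. = FALSE)
  if (!is.finite(config$dirichlet_diag) || config$dirichlet_diag <= 0)
    stop("`dirichlet_diag` must be a positive number.", call. = FALSE)
  if (!is.null(config$transition_mask)) {
    m <- config$transition_mask
    if (inherits(m, "glhmm_mask")) m <- m$allowed
    if (!is.matrix(m) || nrow(m) != config$K || ncol(m) != config$K)
      stop("`transition_mask` must be a K x K logical matrix.", call. = FALSE)
    if (any(rowSums(m) == 0))
      stop(sprintf("Transition mask leaves state(s) %s with no allowed successor.",
                   paste(which(rowSums(m) == 0), collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

#' Enumerate all valid GLHMM configurations
#'
#' The configuration space is the Cartesian product of three mean modes, three
#' regression modes and five covariance options (state-full, state-diagonal,
#' shared-full, shared-diagonal, identity), i.e. 45 raw combinations; the 12
#' combinations in which no component is state-dependent are excluded, leaving
#' 33 distinct model variants.
#'
#' @return A data frame with columns `mean_mode`, `beta_mode`, `cov_mode`,
#'   `cov_shape`, one row per valid variant.
#' @export
enumerate_valid_configs <- function() {
  cov_opts <- data.frame(
    cov_mode = c("state", "state", "shared", "shared", "identity"),
    cov_shape = c("full", "diagonal", "full", "diagonal", "full"),
    stringsAsFactors = FALSE)
  grid <- expand.grid(mean_mode = c("state", "shared", "none"),
                      beta_mode = c("state", "shared", "none"),
                      cov_opt = seq_len(nrow(cov_opts)),
                      stringsAsFactors = FALSE)
  grid$cov_mode <- cov_opts$cov_mode[grid$cov_opt]
  grid$cov_shape <- cov_opts$cov_shape[grid$cov_opt]
  grid$cov_opt <- NULL
  keep <- grid$mean_mode == "state" | grid$beta_mode == "state" |
    grid$cov_mode == "state"
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.glhmm_config <- function(x, ...) {
  cat(sprintf("GLHMM configuration: K = %d\n", x$K))
  cat(sprintf("  mean: %s | beta: %s | cov: %s (%s)\n",
              x$mean_mode, x$beta_mode, x$cov_mode,
              if (x$cov_mode == "identity") "identity" else x$cov_shape))
  cat(sprintf("  dirichlet_diag: %g | mask: %s\n", x$dirichlet_diag,
              if (is.null(x$transition_mask)) "none" else "yes"))
  invisible(x)
}
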