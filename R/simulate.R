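#' Sample data from a GLHMM
#'
#' Generates a state sequence and dependent data from the generative model:
#' each segment's chain starts from \eqn{\pi} and evolves by \eqn{\theta},
#' and \eqn{Y_t \sim N(\mu_{s_t} + X_t \beta_{s_t}, \Sigma_{s_t})}.
#'
#' @param params a [glhmm_params()] object.
#' @param segment_lengths integer vector of segment lengths.
#' @param X optional (sum of lengths) x p matrix of independent data; required
#'   when the configuration includes a regression component. If the
#'   configuration needs `X` and none is given, standard-normal regressors are
#'   drawn.
#' @param subjects optional subject id per segment (passed through to the data
#'   container).
#' @param seed optional integer seed for reproducibility.
#' @return A list with elements `data` ([glhmm_data()]) and `states`
#'   (integer vector of length T with values in `1..K`).
#' @export
sample_glhmm <- function(params, segment_lengths, X = NULL, subjects = NULL,
                         seed = NULL) {
  stopifnot(inherits(params, "glhmm_params"))
  config <- params$config
  K <- config$K
  segment_lengths <- as.integer(segment_lengths)
  if (any(segment_lengths < 1L)) stop("Segment lengths must be >= 1.", call. = FALSE)
  Tn <- sum(segment_lengths)
  need_X <- config$beta_mode != "none"
  with_seed(seed, {
    if (need_X && is.null(X))
      X <- matrix(stats::rnorm(Tn * params$p), Tn, params$p)
    if (!is.null(X)) {
      X <- as_matrix(X, "X")
      if (nrow(X) != Tn)
        stop("`X` must have sum(segment_lengths) rows.", call. = FALSE)
      if (need_X && ncol(X) != params$p)
        stop("`X` has the wrong number of columns for `beta`.", call. = FALSE)
    }
    # state chains per segment
    s <- integer(Tn)
    pos <- 0L
    for (len in segment_lengths) {
      s[pos + 1L] <- sample.int(K, 1L, prob = params$pi)
      if (len > 1L) for (t in 2L:len)
        s[pos + t] <- sample.int(K, 1L, prob = params$theta[s[pos + t - 1L], ])
      pos <- pos + len
    }
    # emissions
    q <- params$q
    Y <- matrix(0, Tn, q)
    chols <- lapply(seq_len(K), function(k) chol(param_Sigma_k(params, k)))
    for (k in seq_len(K)) {
      rows <- which(s == k)
      if (!length(rows)) next
      mean_k <- matrix(param_mu_k(params, k), length(rows), q, byrow = TRUE)
      if (need_X) mean_k <- mean_k + X[rows, , drop = FALSE] %*% param_beta_k(params, k)
      noise <- matrix(stats::rnorm(length(rows) * q), length(rows), q) %*% chols[[k]]
      Y[rows, ] <- mean_k + noise
    }
    ends <- cumsum(segment_lengths)
    idx <- cbind(ends - segment_lengths + 1L, ends)
    list(data = glhmm_data(Y, X = X, indices = idx, subjects = subjects),
         states = s)
  })
}

#' Per-state Gaussian log-likelihoods
#'
#' Evaluates, for every time point and state, the log-density of \eqn{Y_t}
#' under state k's Gaussian with mean \eqn{\mu_k + X_t \beta_k} and covariance
#' \eqn{\Sigma_k}. Shared components broadcast across states. The result
#' depends only on the rows of the data, not on the segment structure.
#'
#' @param data a [glhmm_data()] object.
#' @param params a [glhmm_params()] object (point parameters).
#' @return T x K matrix of log-densities.
#' @export
state_loglik <- function(data, params) {
  stopifnot(inherits(data, "glhmm_data"), inherits(params, "glhmm_params"))
  K <- params$config$K
  q <- data$q
  if (params$q != q) stop("`params` and `data` disagree on q.", call. = FALSE)
  need_X <- params$config$beta_mode != "none"
  if (need_X && is.null(data$X))
    stop("Configuration includes a regression component but `data` has no X.",
         call. = FALSE)
  L <- matrix(0, data$T, K)
  for (k in seq_len(K)) {
    S <- param_Sigma_k(params, k)
    ch <- check_spd(S, sprintf("Sigma[,,%d]", k))
    R <- data$Y - matrix(param_mu_k(params, k), data$T, q, byrow = TRUE)
    if (need_X) R <- R - data$X %*% param_beta_k(params, k)
    z <- forwardsolve(t(ch), t(R))  # ch is upper Cholesky: S = t(ch) %*% ch
    maha <- colSums(z^2)
    L[, k] <- -0.5 * (q * log(2 * pi) + 2 * sum(log(diag(ch))) + maha)
  }
  L
}
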