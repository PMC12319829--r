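#' @export
print.glhmm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Gaussian-linear HMM (K = %d states)\n", x$K))
  cat(sprintf("  modes: mean %s, beta %s, cov %s (%s)\n",
              cfg$mean_mode, cfg$beta_mode, cfg$cov_mode,
              if (cfg$cov_mode == "identity") "identity" else cfg$cov_shape))
  cat(sprintf("  data: T = %d, q = %d, p = %d, %d segment(s)\n",
              x$data$T, x$data$q, x$data$p, x$data$n_segments))
  if (is.finite(x$free_energy %||% NA))
    cat(sprintf("  free energy: %.4f (%d cycles)\n", x$free_energy,
                length(x$fe_trace)))
  fo <- colMeans(x$gamma)
  cat("  fractional occupancy:", paste(sprintf("%.3f", fo), collapse = " "), "\n")
  invisible(x)
}

#' Posterior-mean parameters of a fitted GLHMM
#'
#' @param object a fitted [glhmm()].
#' @param ... unused.
#' @return list with `mu` (rows = states, or one row when shared; `NULL` when
#'   fixed to zero), `beta` (p x q x states array), `Sigma` (q x q x states,
#'   the inverse expected precision), `pi` and `theta` (posterior-mean chain
#'   probabilities).
#' @export
coef.glhmm <- function(object, ...) {
  extract_coefficients(object$posterior, object$meta, object$data$q)
}

#' @export
summary.glhmm <- function(object, ...) {
  co <- coef.glhmm(object)
  units <- segment_units(object$data)
  ans <- list(config = object$config,
              free_energy = object$free_energy,
              cycles = length(object$fe_trace),
              coef = co,
              FO = fractional_occupancy(object$gamma, object$data$indices,
                                        unit_of_segment = units),
              switching = switching_rate(object$vpath, object$data$indices,
                                         unit_of_segment = units))
  class(ans) <- "summary.glhmm"
  ans
}

#' @export
print.summary.glhmm <- function(x, ...) {
  print(x$config)
  cat(sprintf("Free energy %.4f after %d cycles\n", x$free_energy, x$cycles))
  cat("Transition probabilities (posterior mean):\n")
  print(round(x$coef$theta, 3))
  cat("Fractional occupancy per unit:\n")
  print(round(x$FO, 3))
  invisible(x)
}

#' Fitted state-conditional means and residuals
#'
#' `fitted()` returns the posterior-probability-weighted predicted mean
#' \eqn{\sum_k \gamma_{tk} (\mu_k + X_t \beta_k)}; `residuals()` is `Y` minus
#' that.
#' @param object a fitted [glhmm()].
#' @param ... unused.
#' @export
fitted.glhmm <- function(object, ...) {
  data <- object$data
  q <- data$q
  out <- matrix(0, data$T, q)
  for (k in seq_len(object$K)) {
    M <- if (object$meta$d > 0L)
      object$meta$D %*% assemble_M(object$posterior, k, object$meta$d)
    else matrix(0, data$T, q)
    out <- out + object$gamma[, k] * M
  }
  out
}

#' @rdname fitted.glhmm
#' @export
residuals.glhmm <- function(object, ...) object$data$Y - fitted.glhmm(object)

#' Predict state time courses, Viterbi paths or responses
#'
#' For new data (or the training data when `newdata` is missing) computes the
#' smoothed state probabilities (`type = "gamma"`), the most probable state
#' path (`type = "viterbi"`), or the state-probability-weighted predicted
#' response (`type = "response"`).
#'
#' @param object a fitted [glhmm()].
#' @param newdata a [glhmm_data()] (or matrix Y) with the same q (and p) as
#'   the training data.
#' @param type what to return.
#' @param ... unused.
#' @export
predict.glhmm <- function(object, newdata = NULL,
                          type = c("gamma", "viterbi", "response"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data
          else if (inherits(newdata, "glhmm_data")) newdata
          else glhmm_data(newdata)
  meta <- build_design(object$config, data)
  post <- object$posterior
  L <- expected_loglik(post, data, meta)
  if (type == "viterbi")
    return(viterbi(L, post$chain$Elog_pi, post$chain$Elog_theta, data$indices,
                   mask = object$config$transition_mask))
  fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                         data$indices)
  if (type == "gamma") return(fb$gamma)
  out <- matrix(0, data$T, data$q)
  for (k in seq_len(object$K)) {
    M <- if (meta$d > 0L) meta$D %*% assemble_M(post, k, meta$d)
         else matrix(0, data$T, data$q)
    out <- out + fb$gamma[, k] * M
  }
  out
}

#' Simulate from a fitted GLHMM
#'
#' Draws new data from the generative model at the posterior-mean parameters.
#'
#' @param object a fitted [glhmm()].
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param segment_lengths lengths of the simulated segments (default: those of
#'   the training data).
#' @param ... unused.
#' @return A list of `nsim` results of [sample_glhmm()] (a single result when
#'   `nsim = 1`).
#' @export
simulate.glhmm <- function(object, nsim = 1, seed = NULL,
                           segment_lengths = NULL, ...) {
  co <- coef.glhmm(object)
  cfg <- object$config
  params <- glhmm_params(cfg,
                         mu = co$mu,
                         beta = co$beta,
                         Sigma = if (cfg$cov_mode == "identity") NULL else co$Sigma,
                         pi = co$pi, theta = co$theta, q = object$data$q)
  lens <- segment_lengths %||% seg_lengths(object$data)
  with_seed(seed, {
    sims <- lapply(seq_len(nsim), function(i)
      sample_glhmm(params, lens,
                   X = if (is.null(object$data$X)) NULL else object$data$X))
    if (nsim == 1) sims[[1L]] else sims
  })
}

#' Plot a fitted GLHMM
#'
#' `which = "gamma"`: stacked state probabilities over time;
#' `which = "fe"`: free-energy trace across variational cycles.
#'
#' @param x a fitted [glhmm()].
#' @param which `"gamma"` or `"fe"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.glhmm <- function(x, which = c("gamma", "fe"), ...) {
  which <- match.arg(which)
  if (which == "fe") {
    graphics::plot(seq_along(x$fe_trace), x$fe_trace, type = "b",
                   xlab = "cycle", ylab = "free energy", ...)
    return(invisible(x))
  }
  g <- x$gamma
  K <- ncol(g)
  cum <- t(apply(g, 1L, cumsum))
  cols <- grDevices::hcl.colors(K, "Dark 3", alpha = 0.7)
  graphics::plot(NULL, xlim = c(1, nrow(g)), ylim = c(0, 1),
                 xlab = "time", ylab = "state probability", ...)
  for (k in seq_len(K)) {
    lower <- if (k == 1L) rep(0, nrow(g)) else cum[, k - 1L]
    graphics::polygon(c(seq_len(nrow(g)), rev(seq_len(nrow(g)))),
                      c(lower, rev(cum[, k])), col = cols[k], border = NA)
  }
  graphics::abline(v = x$data$indices[-1L, 1L] - 0.5, col = "grey30", lty = 3)
  invisible(x)
}

#' @export
logLik.glhmm <- function(object, ...) {
  structure(sum(object$logZ), df = NA_integer_, class = "logLik")
}
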