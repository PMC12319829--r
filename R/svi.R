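#' Schedule for stochastic variational inference
#'
#' Each cycle draws a random batch of units (segments, or subjects when a
#' subject map exists), runs the E-step on the batch only, rescales the batch
#' sufficient statistics to the population, and blends them into the running
#' statistics with step size \eqn{\rho_c = (c + delay)^{-forgetting\_rate}}
#' before the conjugate M-step.
#'
#' @param batch_size number of units per batch.
#' @param forgetting_rate exponent of the step-size decay. Values in
#'   (0.5, 1] satisfy the classical stochastic-approximation conditions;
#'   `forgetting_rate = 0` keeps \eqn{\rho_c = 1} (with `delay = 0`), which
#'   makes full-batch runs coincide with plain variational inference.
#' @param delay non-negative offset slowing early steps.
#' @param max_cycles number of stochastic cycles.
#' @param unit `"segment"` or `"subject"`: what a batch is made of.
#' @return list of class `"svi_schedule"`.
#' @export
svi_schedule <- function(batch_size, forgetting_rate = 0.75, delay = 2,
                         max_cycles = 100L, unit = c("segment", "subject")) {
  if (forgetting_rate < 0 || forgetting_rate > 1)
    stop("`forgetting_rate` must be in [0, 1].", call. = FALSE)
  if (delay < 0) stop("`delay` must be >= 0.", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 forgetting_rate = forgetting_rate, delay = delay,
                 max_cycles = as.integer(max_cycles),
                 unit = match.arg(unit)),
            class = "svi_schedule")
}

svi_fit <- function(data, config, priors, meta, schedule, control) {
  if (is.null(schedule)) stop("method = 'svi' needs a `schedule`.", call. = FALSE)
  unit_of_segment <- segment_units(data, by = if (schedule$unit == "subject")
    "subject" else "segment")
  units <- unique(unit_of_segment)
  n_units <- length(units)
  B <- schedule$batch_size
  if (B < 1L || B > n_units)
    stop(sprintf("`batch_size` must be in 1..%d (number of %ss).",
                 n_units, schedule$unit), call. = FALSE)

  batch_data <- function(chosen_units) {
    segs <- which(unit_of_segment %in% chosen_units)
    subset_segments(data, segs)
  }

  # initialisation on one batch
  init_units <- if (B == n_units) units else sample(units, B)
  bd <- batch_data(init_units)
  bmeta <- build_design(config, bd)
  post <- init_posterior(config, priors, data$q, meta)
  g0 <- init_gamma(bd, config)
  fb0 <- fb_from_gamma(g0, bd$indices)
  stats_acc <- scale_stats(compute_stats(bd, bmeta, fb0), n_units / B)
  post <- mstep_obs(stats_acc, post, priors)
  post <- mstep_chain(stats_acc, post, priors)

  fe_trace <- numeric(0)
  for (cyc in seq_len(schedule$max_cycles)) {
    rho <- (cyc + schedule$delay)^(-schedule$forgetting_rate)
    chosen <- if (B == n_units) units else sample(units, B)
    bd <- batch_data(chosen)
    bmeta <- build_design(config, bd)
    L <- expected_loglik(post, bd, bmeta)
    fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                           bd$indices)
    # population-rescaled estimate of the free energy on the batch
    fe_trace <- c(fe_trace,
                  -(n_units / B) * sum(fb$logZ) + posterior_kl(post, priors))
    stats_new <- scale_stats(compute_stats(bd, bmeta, fb), n_units / B)
    stats_acc <- blend_stats(stats_acc, stats_new, rho)
    post <- mstep_obs(stats_acc, post, priors)
    post <- mstep_chain(stats_acc, post, priors)
    if (control$verbose)
      message(sprintf("svi cycle %d (rho %.3f): ~free energy %.4f",
                      cyc, rho, fe_trace[cyc]))
  }
  # final full E-step for exact gamma/xi and free energy
  L <- expected_loglik(post, data, meta)
  fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                         data$indices)
  fe_trace <- c(fe_trace, fe_value(post, priors, fb$logZ))
  list(post = post, fb = fb, fe_trace = fe_trace)
}

#' Dual estimation: subject-level models from a group fit
#'
#' Re-estimates the state and chain posteriors on one subject's (or a set of
#' segments') data with the state time courses frozen at the group-level
#' values: one conjugate M-step pass from the group posterior using the
#' subset's responsibilities, which yields comparable subject-level models in
#' which state k always refers to the group's state k. The state time courses
#' themselves are unchanged.
#'
#' @param model a fitted [glhmm()] object (the group model).
#' @param subject subject id (requires `subjects` in the fitted data), or
#' @param segments integer vector of segment indices; exactly one of the two.
#' @return A `"glhmm"` object for the subset with updated posteriors and the
#'   frozen state time courses.
#' @export
dual_estimate <- function(model, subject = NULL, segments = NULL) {
  stopifnot(inherits(model, "glhmm"))
  data <- model$data
  if (is.null(segments)) {
    if (is.null(subject) || is.null(data$subjects))
      stop("Give `segments`, or `subject` with subject-mapped data.", call. = FALSE)
    segments <- which(data$subjects == subject)
    if (!length(segments)) stop("Unknown subject id.", call. = FALSE)
  }
  if (any(segments < 1L | segments > data$n_segments))
    stop("Segment indices out of range: the group state time courses do not ",
         "cover the requested rows.", call. = FALSE)
  sub <- subset_segments(data, segments)
  rows <- unlist(lapply(sort(unique(segments)), function(i) segment_rows(data, i)))
  gamma <- model$gamma[rows, , drop = FALSE]
  xi <- model$xi[sort(unique(segments))]
  K <- model$K
  start_counts <- numeric(K)
  trans_counts <- matrix(0, K, K)
  pos <- 1L
  for (i in seq_along(xi)) {
    start_counts <- start_counts + gamma[pos, ]
    if (dim(xi[[i]])[1L] > 0L)
      trans_counts <- trans_counts + apply(xi[[i]], c(2L, 3L), sum)
    pos <- pos + dim(xi[[i]])[1L] + 1L
  }
  meta <- build_design(model$config, sub)
  fb <- list(gamma = gamma, start_counts = start_counts,
             trans_counts = trans_counts)
  stats <- compute_stats(sub, meta, fb)
  post <- model$posterior
  post <- mstep_obs(stats, post, priors = model$priors)
  post <- mstep_chain(stats, post, model$priors)
  out <- model
  out$data <- sub
  out$meta <- meta
  out$posterior <- post
  out$gamma <- gamma
  out$xi <- xi
  out$logZ <- NULL
  out$fe_trace <- NULL
  out$free_energy <- NA_real_
  L <- expected_loglik(post, sub, meta)
  out$vpath <- viterbi(L, post$chain$Elog_pi, post$chain$Elog_theta,
                       sub$indices, mask = model$config$transition_mask)
  out$dual <- TRUE
  out
}
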