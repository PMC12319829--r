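# Permutation-based association testing between HMM-derived measures and
# external variables. Observations (rows of D and R) are units: subjects,
# trials or sessions depending on the scheme. Exchangeability constraints are
# encoded by `blocks`:
#   across_subjects: NULL (free exchange) or a family id per subject —
#     members exchange within a family, and whole families of equal size
#     exchange with each other;
#   across_trials:   a session id per trial — trials shuffle within sessions;
#   across_sessions: a session id per trial (equal trial counts) — entire
#     sessions exchange, within-session order kept.
# P-values use the add-one estimator p = (1 + #{null >= obs}) / (1 + n_perm),
# so they lie in [1/(n_perm+1), 1] and are never zero.

#' Scheme-valid permutations
#'
#' Generates row-index permutations respecting the exchangeability structure
#' of the chosen scheme. The first row is always the identity (the observed
#' ordering); the remaining `n_perm - 1` rows are random valid permutations.
#'
#' @param scheme `"across_subjects"`, `"across_trials"` or
#'   `"across_sessions"` (the across-visits scheme permutes state labels, not
#'   rows; see [surrogate_viterbi()]).
#' @param N number of observations.
#' @param blocks see the scheme descriptions above.
#' @param n_perm number of rows returned (including the identity).
#' @param seed optional seed.
#' @return `n_perm` x N integer matrix; each row is a permutation of `1..N`.
#' @export
make_permutations <- function(scheme = c("across_subjects", "across_trials",
                                         "across_sessions"),
                              N, blocks = NULL, n_perm = 1000L, seed = NULL) {
  scheme <- match.arg(scheme)
  N <- as.integer(N)
  if (n_perm < 1L) stop("`n_perm` must be >= 1.", call. = FALSE)
  if (!is.null(blocks) && length(blocks) != N)
    stop("`blocks` must have one entry per observation.", call. = FALSE)
  if (scheme == "across_subjects") {
    one_perm <- function() {
      if (is.null(blocks)) return(sample.int(N))
      fam <- as.integer(factor(blocks, levels = unique(blocks)))
      members <- split(seq_len(N), fam)
      sizes <- lengths(members)
      p <- integer(N)
      for (sz in unique(sizes)) {
        fams <- which(sizes == sz)
        # whole families of equal size may swap; members shuffle within
        target <- if (length(fams) > 1L) fams[sample.int(length(fams))] else fams
        for (i in seq_along(fams)) {
          dest_slots <- members[[fams[i]]]
          src <- members[[target[i]]]
          p[dest_slots] <- src[sample.int(sz)]
        }
      }
      p
    }
  } else if (scheme == "across_trials") {
    if (is.null(blocks))
      stop("across_trials needs session `blocks`.", call. = FALSE)
    one_perm <- function() {
      p <- seq_len(N)
      for (rows in split(seq_len(N), blocks))
        p[rows] <- rows[sample.int(length(rows))]
      p
    }
  } else {
    if (is.null(blocks))
      stop("across_sessions needs session `blocks`.", call. = FALSE)
    sess_list <- split(seq_len(N), factor(blocks, levels = unique(blocks)))
    if (length(unique(lengths(sess_list))) != 1L)
      stop("across_sessions requires equal trial counts per session.",
           call. = FALSE)
    # entire sessions exchanged; within-session order kept: position block i
    # receives the rows of session ord[i] in their original order.
    one_perm <- function() {
      ord <- sample.int(length(sess_list))
      unlist(sess_list[ord], use.names = FALSE)
    }
  }
  with_seed(seed, {
    out <- matrix(0L, n_perm, N)
    out[1L, ] <- seq_len(N)
    if (n_perm > 1L) for (i in 2L:n_perm) out[i, ] <- one_perm()
    out
  })
}

#' Residualise on confounds
#'
#' Returns the residuals of each column of `M` after least-squares projection
#' on the confounds (an intercept is always included), removing the part of
#' `M` linearly explained by `C`.
#'
#' @param M N x m numeric matrix (or vector).
#' @param C N x c confound matrix.
#' @return matrix of residuals with the dimensions of `M`.
#' @export
deconfound <- function(M, C) {
  M <- as.matrix(M)
  C <- as.matrix(C)
  if (nrow(M) != nrow(C)) stop("`M` and `C` must have the same rows.", call. = FALSE)
  Cd <- cbind(1, C)
  qrC <- qr(Cd)
  if (qrC$rank < ncol(Cd))
    stop("Confound matrix is rank deficient (after adding an intercept).",
         call. = FALSE)
  M - Cd %*% qr.coef(qrC, M)
}

#' Multiple-comparison correction
#'
#' Bonferroni or Benjamini-Hochberg adjustment, preserving the shape of the
#' input. A thin wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector or matrix of p-values in (0, 1].
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @export
correct_pvalues <- function(pvals, method = c("bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  adj <- stats::p.adjust(as.numeric(pvals),
                         method = if (method == "bonferroni") "bonferroni" else "BH")
  if (is.matrix(pvals)) matrix(adj, nrow(pvals), ncol(pvals),
                               dimnames = dimnames(pvals)) else adj
}

# intercept-including thin Q of a design
design_q <- function(D) {
  Dd <- cbind(1, as.matrix(D))
  qrD <- qr(Dd)
  if (qrD$rank < ncol(Dd))
    stop("Design matrix `D` is rank deficient.", call. = FALSE)
  qr.Q(qrD)
}

perm_pval <- function(stats_perm, observed) {
  # stats_perm includes the observed statistic in row 1
  n_null <- nrow(stats_perm) - 1L
  if (n_null == 0L) return(rep(1, length(observed)))
  null <- stats_perm[-1L, , drop = FALSE]
  (1 + colSums(null >= matrix(observed, n_null, length(observed),
                              byrow = TRUE))) / (1 + n_null)
}

#' Permutation test: multivariate regression association
#'
#' Tests whether the design `D` linearly predicts each column of `R`. The
#' observed statistic per outcome column is the explained variance of a
#' least-squares regression of that column on `D` (with intercept); the null
#' distribution is built by recomputing it on scheme-valid permutations of
#' the rows of `R`. When confounds `C` are given, both `D` and `R` are
#' residualised on `C` first.
#'
#' @param D N x p design matrix of independent variables.
#' @param R N x q matrix (or vector) of dependent variables.
#' @param C optional N x c confound matrix.
#' @param scheme,blocks exchangeability structure, see [make_permutations()].
#' @param n_perm number of random permutations (default 1000).
#' @param seed optional seed.
#' @param correction optional multiple-comparison correction applied across
#'   the q p-values (see [correct_pvalues()]).
#' @return list of class `"glhmm_test"`: `statistic` (length q explained
#'   variances), `pvals`, `pvals_corrected` (if requested), `n_perm`,
#'   `kind`.
#' @export
permutation_regression_test <- function(D, R, C = NULL,
                                        scheme = "across_subjects",
                                        blocks = NULL, n_perm = 1000L,
                                        seed = NULL, correction = NULL) {
  D <- as.matrix(D)
  R <- as.matrix(R)
  N <- nrow(D)
  if (nrow(R) != N) stop("`D` and `R` must have the same rows.", call. = FALSE)
  if (N <= ncol(D))
    stop("Need more observations than predictors.", call. = FALSE)
  if (!is.null(C)) {
    D <- deconfound(D, C)
    R <- deconfound(R, C)
  }
  Q <- design_q(D)
  perms <- make_permutations(scheme, N, blocks, n_perm + 1L, seed)
  sst <- colSums(scale(R, center = TRUE, scale = FALSE)^2)
  if (any(sst == 0)) stop("Zero-variance outcome column.", call. = FALSE)
  nm2 <- N * colMeans(R)^2
  ev <- matrix(0, nrow(perms), ncol(R))
  for (j in seq_len(ncol(R))) {
    Rp <- matrix(R[t(perms), j], N, nrow(perms))   # N x n_perm+1
    fitsq <- colSums(crossprod(Q, Rp)^2)
    ev[, j] <- (fitsq - nm2[j]) / sst[j]
  }
  pv <- perm_pval(ev, ev[1L, ])
  out <- list(statistic = ev[1L, ], pvals = pv,
              pvals_corrected = if (!is.null(correction))
                correct_pvalues(pv, correction) else NULL,
              correction = correction, n_perm = n_perm,
              kind = "regression (explained variance)", scheme = scheme)
  class(out) <- "glhmm_test"
  out
}

#' Permutation test: univariate correlations
#'
#' Two-sided permutation test on the magnitude of the Pearson correlation
#' between each column of `D` and each column of `R`, returning a p x q
#' matrix of p-values.
#'
#' @inheritParams permutation_regression_test
#' @export
permutation_correlation_test <- function(D, R, C = NULL,
                                         scheme = "across_subjects",
                                         blocks = NULL, n_perm = 1000L,
                                         seed = NULL, correction = NULL) {
  D <- as.matrix(D)
  R <- as.matrix(R)
  N <- nrow(D)
  if (nrow(R) != N) stop("`D` and `R` must have the same rows.", call. = FALSE)
  if (!is.null(C)) {
    D <- deconfound(D, C)
    R <- deconfound(R, C)
  }
  sdD <- apply(D, 2L, stats::sd)
  sdR <- apply(R, 2L, stats::sd)
  if (any(sdD == 0) || any(sdR == 0))
    stop("Zero-variance column in `D` or `R`.", call. = FALSE)
  Dc <- scale(D)
  Rc <- scale(R)
  perms <- make_permutations(scheme, N, blocks, n_perm + 1L, seed)
  p <- ncol(D); q <- ncol(R)
  stats_perm <- matrix(0, nrow(perms), p * q)
  for (i in seq_len(nrow(perms))) {
    cc <- crossprod(Dc, Rc[perms[i, ], , drop = FALSE]) / (N - 1)
    stats_perm[i, ] <- abs(as.numeric(cc))
  }
  pv <- matrix(perm_pval(stats_perm, stats_perm[1L, ]), p, q)
  out <- list(statistic = matrix(stats_perm[1L, ], p, q), pvals = pv,
              pvals_corrected = if (!is.null(correction))
                correct_pvalues(pv, correction) else NULL,
              correction = correction, n_perm = n_perm,
              kind = "correlation (|r|, two-sided)", scheme = scheme)
  class(out) <- "glhmm_test"
  out
}

#' @export
print.glhmm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s, scheme %s, %d permutations\n",
              x$kind, x$scheme %||% "-", x$n_perm))
  cat("statistic:\n"); print(round(x$statistic, 4))
  cat("p-values:\n"); print(round(x$pvals, 4))
  if (!is.null(x$pvals_corrected)) {
    cat(sprintf("corrected (%s):\n", x$correction)); print(round(x$pvals_corrected, 4))
  }
  invisible(x)
}

#' Cluster-based correction for statistic time courses
#'
#' Scores contiguous supra-threshold runs of the observed statistic series by
#' their summed statistic (cluster mass) and compares each mass with the
#' permutation distribution of the maximum cluster mass.
#'
#' @param stat_timecourse observed statistic per time point (length T).
#' @param null_timecourses n_perm x T matrix of the statistic under
#'   permutations.
#' @param cluster_threshold scalar forming threshold.
#' @return list with `clusters` (data frame: start, end, mass, pval) and
#'   `max_null_mass` (the permutation distribution used).
#' @export
cluster_correction <- function(stat_timecourse, null_timecourses,
                               cluster_threshold) {
  stat_timecourse <- as.numeric(stat_timecourse)
  null_timecourses <- as.matrix(null_timecourses)
  if (ncol(null_timecourses) != length(stat_timecourse))
    stop("Observed and null series must have equal length.", call. = FALSE)
  cluster_masses <- function(x) {
    above <- x > cluster_threshold
    if (!any(above)) return(data.frame(start = integer(0), end = integer(0),
                                       mass = numeric(0)))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(which(keep), function(i)
                 sum(x[starts[i]:ends[i]]), numeric(1L)))
  }
  obs <- cluster_masses(stat_timecourse)
  max_null <- apply(null_timecourses, 1L, function(x) {
    cm <- cluster_masses(x)
    if (nrow(cm) == 0L) 0 else max(cm$mass)
  })
  n_perm <- length(max_null)
  obs$pval <- vapply(obs$mass, function(m)
    (1 + sum(max_null >= m)) / (1 + n_perm), numeric(1L))
  list(clusters = obs, max_null_mass = max_null)
}

#' Surrogate Viterbi path
#'
#' Randomises the state identity of each visit while preserving the visit
#' (run-length) structure exactly: within each segment the first visit's
#' label is uniform over the K states and every later visit's label is
#' uniform over the K-1 states different from the previous surrogate visit's
#' label. Surrogates therefore keep the timing statistics of the original
#' path but randomise which states are visited.
#'
#' @param vpath integer state path (values `1..K`).
#' @param indices segment index matrix.
#' @param K number of states (default `max(vpath)`); must be >= 2.
#' @param seed optional seed.
#' @return integer surrogate path of the same length.
#' @export
surrogate_viterbi <- function(vpath, indices = NULL, K = max(vpath),
                              seed = NULL) {
  if (K < 2L)
    stop("Surrogate paths require K >= 2 states.", call. = FALSE)
  if (is.null(indices)) indices <- matrix(c(1L, length(vpath)), 1L, 2L)
  runs <- path_runs(vpath, indices)
  with_seed(seed, {
    out <- integer(length(vpath))
    indices <- matrix(as.integer(indices), ncol = 2L)
    for (i in seq_along(runs)) {
      lens <- runs[[i]]$lengths
      labs <- integer(length(lens))
      if (length(lens)) {
        labs[1L] <- sample.int(K, 1L)
        if (length(lens) > 1L) for (v in 2L:length(lens)) {
          cand <- setdiff(seq_len(K), labs[v - 1L])
          labs[v] <- cand[sample.int(K - 1L, 1L)]
        }
      }
      out[seq.int(indices[i, 1L], indices[i, 2L])] <- rep(labs, lens)
    }
    out
  })
}

#' Across-visits test: state path versus a continuous signal
#'
#' Tests the association between a decoded state path and a simultaneously
#' recorded continuous variable `S` (e.g. pupil size). The observed statistic
#' is, per column of `S`: for `all_states`, the variance of `S` explained by
#' the state indicators; for `one_vs_rest`, the absolute difference between
#' the mean of `S` during visits of state `k` and during all other states;
#' for `state_vs_state`, the absolute difference between the state-k and
#' state-l means. The null is built from surrogate Viterbi paths, which keep
#' the visit timing but randomise state identities.
#'
#' @param vpath integer state path.
#' @param S numeric vector or T x m matrix, same length as `vpath`.
#' @param indices segment index matrix.
#' @param contrast `"all_states"`, `"one_vs_rest"` or `"state_vs_state"`.
#' @param k,l state indices for the pairwise contrasts.
#' @param K number of states (default `max(vpath)`).
#' @param n_perm number of surrogate paths.
#' @param seed optional seed.
#' @return a `"glhmm_test"` object.
#' @export
across_visits_test <- function(vpath, S, indices = NULL,
                               contrast = c("all_states", "one_vs_rest",
                                            "state_vs_state"),
                               k = 1L, l = 2L, K = max(vpath),
                               n_perm = 1000L, seed = NULL) {
  contrast <- match.arg(contrast)
  S <- as.matrix(S)
  if (nrow(S) != length(vpath))
    stop("`S` must have one row per time point of the path.", call. = FALSE)
  if (is.null(indices)) indices <- matrix(c(1L, length(vpath)), 1L, 2L)
  if (contrast == "one_vs_rest" && !any(vpath == k))
    stop("Contrast state is never visited.", call. = FALSE)
  if (contrast == "state_vs_state" && (!any(vpath == k) || !any(vpath == l)))
    stop("Contrast state is never visited.", call. = FALSE)
  stat_fun <- function(path) {
    switch(contrast,
      all_states = {
        f <- factor(path, levels = seq_len(K))
        apply(S, 2L, function(s) {
          mu <- tapply(s, f, mean)
          fit <- mu[as.integer(f)]
          1 - sum((s - fit)^2) / sum((s - mean(s))^2)
        })
      },
      one_vs_rest = apply(S, 2L, function(s)
        abs(mean(s[path == k]) - mean(s[path != k]))),
      state_vs_state = apply(S, 2L, function(s)
        abs(mean(s[path == k]) - mean(s[path == l]))))
  }
  with_seed(seed, {
    obs <- stat_fun(vpath)
    nulls <- matrix(NA_real_, n_perm, ncol(S))
    for (i in seq_len(n_perm)) {
      sp <- surrogate_viterbi(vpath, indices, K = K)
      ok <- switch(contrast,
        all_states = TRUE,
        one_vs_rest = any(sp == k) && any(sp != k),
        state_vs_state = any(sp == k) && any(sp == l))
      nulls[i, ] <- if (ok) stat_fun(sp) else 0
    }
    pv <- (1 + colSums(nulls >= matrix(obs, n_perm, ncol(S), byrow = TRUE))) /
      (1 + n_perm)
    out <- list(statistic = obs, pvals = pv, pvals_corrected = NULL,
                n_perm = n_perm, kind = sprintf("across-visits (%s)", contrast),
                scheme = "across_visits")
    class(out) <- "glhmm_test"
    out
  })
}

#' Per-time-point permutation tests on state time courses
#'
#' Applies the regression engine at every within-trial time point: at time t
#' the design is the state probabilities of all trials at their t-th time
#' point and the outcome is the trial-level variable `R`. All time points
#' share the same permutations, so the returned per-permutation statistics
#' can feed [cluster_correction()]; alternatively standard corrections are
#' applied across time points.
#'
#' @param gamma T x K state probabilities of equal-length trials.
#' @param indices trial index matrix (equal lengths).
#' @param R trial-level outcomes (one row per trial).
#' @param scheme,blocks,n_perm,seed as in [permutation_regression_test()].
#' @param correction correction across time points (see [correct_pvalues()]),
#'   or `NULL`.
#' @return list with `pvals` (T_trial x q), `statistic` (T_trial x q),
#'   `pvals_corrected`, and `null_statistic` (n_perm x T_trial, first outcome
#'   column) for cluster-based use.
#' @export
timecourse_regression_test <- function(gamma, indices, R,
                                       scheme = "across_trials",
                                       blocks = NULL, n_perm = 1000L,
                                       seed = NULL, correction = NULL) {
  indices <- matrix(as.integer(indices), ncol = 2L)
  lens <- indices[, 2L] - indices[, 1L] + 1L
  if (length(unique(lens)) != 1L)
    stop("All trials must have the same length.", call. = FALSE)
  Tt <- lens[1L]
  n_trial <- nrow(indices)
  R <- as.matrix(R)
  if (nrow(R) != n_trial) stop("`R` must have one row per trial.", call. = FALSE)
  if (scheme == "across_trials" && is.null(blocks)) blocks <- rep(1L, n_trial)
  perms <- make_permutations(scheme, n_trial, blocks, n_perm + 1L, seed)
  K <- ncol(gamma)
  pvals <- matrix(NA_real_, Tt, ncol(R))
  statistic <- matrix(NA_real_, Tt, ncol(R))
  null_stat <- matrix(NA_real_, n_perm, Tt)
  for (t in seq_len(Tt)) {
    Dt <- gamma[indices[, 1L] + t - 1L, , drop = FALSE]
    # drop a redundant simplex column to keep the design full rank
    Dt <- Dt[, -K, drop = FALSE]
    Q <- design_q(Dt)
    sst <- colSums(scale(R, center = TRUE, scale = FALSE)^2)
    nm2 <- n_trial * colMeans(R)^2
    ev <- matrix(0, nrow(perms), ncol(R))
    for (j in seq_len(ncol(R))) {
      Rp <- matrix(R[t(perms), j], n_trial, nrow(perms))
      ev[, j] <- (colSums(crossprod(Q, Rp)^2) - nm2[j]) / sst[j]
    }
    pvals[t, ] <- perm_pval(ev, ev[1L, ])
    statistic[t, ] <- ev[1L, ]
    null_stat[, t] <- ev[-1L, 1L]
  }
  list(pvals = pvals, statistic = statistic,
       pvals_corrected = if (!is.null(correction))
         correct_pvalues(pvals, correction) else NULL,
       null_statistic = null_stat)
}
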