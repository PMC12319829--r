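# Out-of-sample prediction of unit-level variables from fitted GLHMMs:
# Fisher-kernel features (gradients of each subject's data log-likelihood
# with respect to the group model's parameters) or summary-metric features,
# with group-aware nested cross-validation and CV-safe deconfounding.

vech_double_offdiag <- function(G) {
  # unique entries of a symmetric gradient; off-diagonals count twice
  q <- nrow(G)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  vals <- G[idx]
  vals[idx[, 1L] != idx[, 2L]] <- 2 * vals[idx[, 1L] != idx[, 2L]]
  vals
}

#' Fisher scores of subjects under a group model
#'
#' For each subject, the gradient of that subject's data log-likelihood with
#' respect to the group model's point parameters (posterior means), evaluated
#' with the subject's own forward-backward responsibilities — how the group
#' model would have to change to best explain the subject. Probability rows
#' (\eqn{\pi}, rows of \eqn{\theta}) are scored in softmax coordinates and
#' diagonal variances in log coordinates, so all gradients live in
#' unconstrained spaces; full covariances are scored on their unique (lower
#' triangular) entries.
#'
#' @param model a fitted [glhmm()] with subject-mapped data (or use
#'   `unit = "segment"` to score segments).
#' @param include character vector of parameter families to include, a subset
#'   of `c("pi", "theta", "mu", "beta", "Sigma")`.
#' @param unit `"subject"` or `"segment"`.
#' @param normalise `"none"` or `"T"` (divide each subject's scores by its
#'   number of time points).
#' @param standardise standardise score columns across subjects (z-scores)?
#'   Default `FALSE`.
#' @return N x m score matrix (one row per unit).
#' @export
fisher_scores <- function(model,
                          include = c("pi", "theta", "mu", "beta", "Sigma"),
                          unit = c("subject", "segment"),
                          normalise = c("none", "T"), standardise = FALSE) {
  stopifnot(inherits(model, "glhmm"))
  unit <- match.arg(unit)
  normalise <- match.arg(normalise)
  include <- match.arg(include, several.ok = TRUE)
  co <- coef.glhmm(model)
  cfg <- model$config
  K <- cfg$K
  q <- model$data$q
  params <- glhmm_params(cfg, mu = co$mu, beta = co$beta,
                         Sigma = if (cfg$cov_mode == "identity") NULL else co$Sigma,
                         pi = co$pi, theta = co$theta, q = q)
  A <- mask_matrix(cfg$transition_mask, K)
  log_theta <- matrix(-Inf, K, K)
  log_theta[A] <- log(co$theta[A])
  Lam <- lapply(seq_len(K), function(k) chol2inv(chol(param_Sigma_k(params, k))))
  units <- segment_units(model$data, by = unit)
  ids <- unique(units)
  rows_list <- lapply(ids, function(u) {
    segs <- which(units == u)
    if (!length(unlist(lapply(segs, function(i) segment_rows(model$data, i)))))
      stop("Empty unit.", call. = FALSE)
    segs
  })
  score_one <- function(segs) {
    sub <- subset_segments(model$data, segs)
    L <- state_loglik(sub, params)
    fb <- forward_backward(L, log(co$pi), log_theta, sub$indices)
    vec <- numeric(0)
    if ("pi" %in% include) {
      s <- fb$start_counts
      vec <- c(vec, s - co$pi * sum(s))
    }
    if ("theta" %in% include) {
      cc <- fb$trans_counts
      g <- cc - co$theta * rowSums(cc)
      vec <- c(vec, g[A])
    }
    n_k <- colSums(fb$gamma)
    resid_k <- lapply(seq_len(K), function(k) {
      R <- sub$Y - matrix(param_mu_k(params, k), sub$T, q, byrow = TRUE)
      if (cfg$beta_mode != "none") R <- R - sub$X %*% param_beta_k(params, k)
      R
    })
    if ("mu" %in% include && cfg$mean_mode != "none") {
      g_k <- lapply(seq_len(K), function(k)
        as.numeric(Lam[[k]] %*% colSums(resid_k[[k]] * fb$gamma[, k])))
      if (cfg$mean_mode == "state") vec <- c(vec, unlist(g_k))
      else vec <- c(vec, Reduce(`+`, g_k))
    }
    if ("beta" %in% include && cfg$beta_mode != "none") {
      g_k <- lapply(seq_len(K), function(k)
        crossprod(sub$X * fb$gamma[, k], resid_k[[k]] %*% Lam[[k]]))
      if (cfg$beta_mode == "state") vec <- c(vec, unlist(lapply(g_k, as.numeric)))
      else vec <- c(vec, as.numeric(Reduce(`+`, g_k)))
    }
    if ("Sigma" %in% include && cfg$cov_mode != "identity") {
      g_k <- lapply(seq_len(K), function(k) {
        Rw <- resid_k[[k]] * fb$gamma[, k]
        Sc <- crossprod(Rw, resid_k[[k]])         # sum gamma r r'
        if (cfg$cov_shape == "diagonal") {
          # d / d log sigma^2_j
          -n_k[k] / 2 + diag(Lam[[k]]) * diag(Sc) / 2
        } else {
          vech_double_offdiag((Lam[[k]] %*% Sc %*% Lam[[k]] - n_k[k] * Lam[[k]]) / 2)
        }
      })
      if (cfg$cov_mode == "state") vec <- c(vec, unlist(g_k))
      else vec <- c(vec, Reduce(`+`, g_k))
    }
    if (normalise == "T") vec <- vec / sub$T
    vec
  }
  scores <- t(vapply(rows_list, score_one, score_one(rows_list[[1L]])))
  if (standardise) {
    scores <- scale(scores)
    scores[, attr(scores, "scaled:scale") == 0] <- 0
    scores <- matrix(as.numeric(scores), length(ids))
  }
  rownames(scores) <- ids
  scores
}

#' Kernel matrix from score (or feature) rows
#'
#' `linear`: inner products of rows; `gaussian`:
#' \eqn{\exp(-\|d_i - d_j\|^2 / (2 b^2))} with bandwidth `b` defaulting to
#' the median pairwise distance.
#'
#' @param scores N x m matrix.
#' @param kind `"linear"` or `"gaussian"`.
#' @param bandwidth positive scalar for the gaussian kernel; `NULL` uses the
#'   median pairwise-distance heuristic.
#' @return N x N symmetric positive semidefinite matrix.
#' @export
build_kernel <- function(scores, kind = c("linear", "gaussian"),
                         bandwidth = NULL) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("Scores must be finite.", call. = FALSE)
  if (kind == "linear") return(tcrossprod(scores))
  d2 <- as.matrix(stats::dist(scores))^2
  if (is.null(bandwidth)) {
    dvals <- sqrt(d2[upper.tri(d2)])
    bandwidth <- stats::median(dvals[dvals > 0])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("`bandwidth` must be positive.", call. = FALSE)
  exp(-d2 / (2 * bandwidth^2))
}

#' Summary-metric feature matrix
#'
#' Concatenates, per unit, the time-aggregated statistics: fractional
#' occupancies (K), mean dwell times (K; missing entries from unvisited
#' states imputed by 0 with a companion missingness indicator), switching
#' rate (1) and occupancy entropy (1).
#'
#' @param model a fitted [glhmm()].
#' @param by `"subject"` or `"segment"`.
#' @return N x (3K + 2) feature matrix.
#' @export
summary_features <- function(model, by = c("subject", "segment")) {
  ag <- aggregate_stats(model, by = match.arg(by))
  dwell <- ag$dwell
  miss <- is.na(dwell) + 0
  dwell[is.na(dwell)] <- 0
  cbind(FO = ag$FO, dwell = dwell, dwell_missing = miss,
        switch = ag$switch_rate, entropy = ag$entropy)
}

#' Group-aware cross-validation folds
#'
#' Assigns units to folds so that no group (e.g. family) is split across
#' folds, balancing fold sizes; with singleton groups this is ordinary random
#' K-fold assignment.
#'
#' @param N number of units.
#' @param n_folds number of folds (must not exceed the number of groups).
#' @param groups optional group id per unit (default: all singletons).
#' @param seed optional seed.
#' @return list of class `"fold_plan"`: `fold` (length-N fold id),
#'   `n_folds`, `groups`.
#' @export
make_folds <- function(N, n_folds, groups = NULL, seed = NULL) {
  if (is.null(groups)) groups <- seq_len(N)
  if (length(groups) != N) stop("`groups` must have length N.", call. = FALSE)
  gid <- as.integer(factor(groups, levels = unique(groups)))
  n_groups <- length(unique(gid))
  if (n_folds > n_groups)
    stop("More folds than groups: a group would have to be split.", call. = FALSE)
  with_seed(seed, {
    members <- split(seq_len(N), gid)
    ord <- sample(seq_along(members))            # random tie-breaking
    members <- members[ord]
    members <- members[order(-lengths(members))] # biggest groups first
    fold_sizes <- numeric(n_folds)
    fold <- integer(N)
    for (g in members) {
      f <- which.min(fold_sizes)
      fold[g] <- f
      fold_sizes[f] <- fold_sizes[f] + length(g)
    }
    structure(list(fold = fold, n_folds = as.integer(n_folds), groups = gid),
              class = "fold_plan")
  })
}

# kernel ridge solution on a training kernel; returns a predictor
krr_train <- function(Ktr, ytr, lambda) {
  n <- nrow(Ktr)
  mu <- mean(ytr)
  alpha <- solve(Ktr + diag(lambda, n), ytr - mu)
  list(alpha = alpha, mu = mu)
}
krr_predict <- function(fit, Kte_tr) as.numeric(Kte_tr %*% fit$alpha + fit$mu)

#' Nested cross-validated kernel ridge regression
#'
#' Outer folds (from a group-aware [make_folds()] plan) are held out in turn;
#' an inner cross-validation on the training folds picks the ridge penalty;
#' predictions for the held-out units come from the closed-form kernel-ridge
#' solution. Confound effects are estimated on training folds only and
#' applied to the test folds (CV-safe deconfounding); the explained variance
#' is computed on the deconfounded outcome.
#'
#' @param K_mat N x N kernel matrix (positive semidefinite).
#' @param y length-N outcome.
#' @param folds a [make_folds()] plan.
#' @param ridge_grid candidate ridge penalties.
#' @param confounds optional N x c confound matrix.
#' @param inner_folds number of inner folds (default up to 5).
#' @param seed seed for the inner fold assignment.
#' @return list with `predictions` (length N, held-out), `observed` (the
#'   possibly deconfounded outcome), `fold_ev` (per-outer-fold held-out
#'   explained variance), `ev` (their mean), `lambda` (chosen penalty per
#'   fold).
#' @export
kernel_ridge_cv <- function(K_mat, y, folds, ridge_grid = 10^seq(-4, 3),
                            confounds = NULL, inner_folds = 5L, seed = NULL) {
  K_mat <- as.matrix(K_mat)
  N <- nrow(K_mat)
  y <- as.numeric(y)
  if (length(y) != N) stop("`y` must have length N.", call. = FALSE)
  stopifnot(inherits(folds, "fold_plan"))
  preds <- numeric(N)
  yres <- y
  fold_ev <- numeric(folds$n_folds)
  lambda_sel <- numeric(folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    te <- which(folds$fold == f)
    tr <- setdiff(seq_len(N), te)
    ytr <- y[tr]; yte <- y[te]
    if (!is.null(confounds)) {
      C <- as.matrix(confounds)
      Cd <- cbind(1, C)
      bc <- qr.coef(qr(Cd[tr, , drop = FALSE]), ytr)
      bc[is.na(bc)] <- 0
      ytr <- ytr - as.numeric(Cd[tr, , drop = FALSE] %*% bc)
      yte <- yte - as.numeric(Cd[te, , drop = FALSE] %*% bc)
    }
    # inner CV over the ridge grid, group-aware within the training set
    n_inner <- max(2L, min(inner_folds, length(unique(folds$groups[tr]))))
    inner <- make_folds(length(tr), n_inner, groups = folds$groups[tr],
                        seed = if (is.null(seed)) NULL else seed + f)
    inner_err <- vapply(ridge_grid, function(lam) {
      err <- 0
      for (g in seq_len(n_inner)) {
        ite <- which(inner$fold == g)
        itr <- setdiff(seq_along(tr), ite)
        fit <- krr_train(K_mat[tr[itr], tr[itr], drop = FALSE], ytr[itr], lam)
        pr <- krr_predict(fit, K_mat[tr[ite], tr[itr], drop = FALSE])
        err <- err + sum((ytr[ite] - pr)^2)
      }
      err
    }, numeric(1L))
    lam <- ridge_grid[which.min(inner_err)]
    lambda_sel[f] <- lam
    fit <- krr_train(K_mat[tr, tr, drop = FALSE], ytr, lam)
    pr <- krr_predict(fit, K_mat[te, tr, drop = FALSE])
    preds[te] <- pr
    yres[te] <- yte
    sse <- sum((yte - pr)^2)
    sst <- sum((yte - mean(ytr))^2)
    fold_ev[f] <- 1 - sse / sst
  }
  list(predictions = preds, observed = yres, fold_ev = fold_ev,
       ev = mean(fold_ev), lambda = lambda_sel)
}

# ridge-penalised kernel logistic regression via IRLS
klr_train <- function(Ktr, ypm, lambda, max_iter = 50L, tol = 1e-8) {
  n <- nrow(Ktr)
  alpha <- rep(0, n)
  b <- 0
  for (it in seq_len(max_iter)) {
    f <- as.numeric(Ktr %*% alpha + b)
    p <- 1 / (1 + exp(-f))
    w <- pmax(p * (1 - p), 1e-6)
    z <- f + (((ypm + 1) / 2) - p) / w
    # penalised IRLS; solving (W K + lambda I) alpha = W (z - b) keeps the
    # system nonsingular even for rank-deficient kernels, and is equivalent
    # to the Newton step on the range of K
    new_alpha <- solve(Ktr * w + diag(lambda, n), w * (z - b))
    new_b <- sum(w * (z - as.numeric(Ktr %*% new_alpha))) / sum(w)
    if (max(abs(new_alpha - alpha)) + abs(new_b - b) < tol) {
      alpha <- new_alpha; b <- new_b; break
    }
    alpha <- new_alpha; b <- new_b
  }
  list(alpha = alpha, b = b)
}
klr_predict <- function(fit, Kte_tr) as.numeric(Kte_tr %*% fit$alpha + fit$b)

#' Nested cross-validated kernel classification
#'
#' Binary classification from a precomputed kernel with a ridge-penalised
#' kernel logistic decision rule; nested CV selects the penalty on training
#' folds only, honouring the group structure of the fold plan.
#'
#' @param K_mat N x N kernel matrix.
#' @param labels binary labels (two levels).
#' @param folds a [make_folds()] plan.
#' @param C_grid candidate penalties.
#' @param inner_folds,seed as in [kernel_ridge_cv()].
#' @return list with `predicted` (labels), `accuracy`, `fold_accuracy`.
#' @export
kernel_classify_cv <- function(K_mat, labels, folds, C_grid = 10^seq(-3, 2),
                               inner_folds = 5L, seed = NULL) {
  K_mat <- as.matrix(K_mat)
  N <- nrow(K_mat)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("`labels` must be binary.", call. = FALSE)
  ypm <- ifelse(labels == lev[1L], -1, 1)
  stopifnot(inherits(folds, "fold_plan"))
  pred <- numeric(N)
  fold_acc <- numeric(folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    te <- which(folds$fold == f)
    tr <- setdiff(seq_len(N), te)
    if (length(unique(ypm[tr])) < 2L)
      stop("Single-class training fold.", call. = FALSE)
    n_inner <- max(2L, min(inner_folds, length(unique(folds$groups[tr]))))
    inner <- make_folds(length(tr), n_inner, groups = folds$groups[tr],
                        seed = if (is.null(seed)) NULL else seed + f)
    inner_err <- vapply(C_grid, function(lam) {
      err <- 0
      for (g in seq_len(n_inner)) {
        ite <- which(inner$fold == g)
        itr <- setdiff(seq_along(tr), ite)
        if (length(unique(ypm[tr[itr]])) < 2L) { err <- err + length(ite); next }
        fit <- klr_train(K_mat[tr[itr], tr[itr], drop = FALSE], ypm[tr[itr]], lam)
        pr <- klr_predict(fit, K_mat[tr[ite], tr[itr], drop = FALSE])
        err <- err + sum(sign(pr) != ypm[tr[ite]])
      }
      err
    }, numeric(1L))
    lam <- C_grid[which.min(inner_err)]
    fit <- klr_train(K_mat[tr, tr, drop = FALSE], ypm[tr], lam)
    pr <- klr_predict(fit, K_mat[te, tr, drop = FALSE])
    pred[te] <- pr
    fold_acc[f] <- mean(sign(pr) == ypm[te])
  }
  predicted <- ifelse(pred < 0, lev[1L], lev[2L])
  list(predicted = predicted, accuracy = mean(predicted == labels),
       fold_accuracy = fold_acc)
}
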