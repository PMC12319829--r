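#' Constrained transition structures
#'
#' Builds a K x K logical matrix of allowed transitions (rows = from-state,
#' columns = to-state). Self-transitions are always allowed. Kinds:
#' * `free`: all transitions allowed.
#' * `sequential`: states strictly follow the sequence 1, 2, ..., K within a
#'   segment — only k -> k and k -> k+1 allowed.
#' * `circular`: sequential plus the wrap-around K -> 1.
#' * `forward_only`: k -> j allowed only for j >= k.
#' * `blocks`: transitions allowed within blocks of states; transitions
#'   between blocks only through explicitly listed gate pairs.
#' * `custom`: a user-supplied logical matrix (self-transitions enforced).
#'
#' @param kind one of `"free"`, `"sequential"`, `"circular"`,
#'   `"forward_only"`, `"blocks"`, `"custom"`.
#' @param K number of states (>= 2 for non-free kinds).
#' @param blocks for `kind = "blocks"`: a list of integer vectors partitioning
#'   `1..K`.
#' @param gates for `kind = "blocks"`: a 2-column matrix (or list of pairs) of
#'   additionally allowed from -> to transitions between blocks.
#' @param allowed for `kind = "custom"`: the K x K logical matrix.
#' @return An object of class `"glhmm_mask"`: list with `allowed` (K x K
#'   logical) and `kind`.
#' @export
make_transition_mask <- function(kind = c("free", "sequential", "circular",
                                          "forward_only", "blocks", "custom"),
                                 K, blocks = NULL, gates = NULL, allowed = NULL) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  if (kind != "free" && K < 2L)
    stop("Non-free transition structures need K >= 2.", call. = FALSE)
  A <- switch(kind,
    free = matrix(TRUE, K, K),
    sequential = {
      A <- diag(K) > 0
      A[cbind(seq_len(K - 1L), seq_len(K - 1L) + 1L)] <- TRUE
      A
    },
    circular = {
      A <- diag(K) > 0
      A[cbind(seq_len(K - 1L), seq_len(K - 1L) + 1L)] <- TRUE
      A[K, 1L] <- TRUE
      A
    },
    forward_only = outer(seq_len(K), seq_len(K), `<=`),
    blocks = {
      if (is.null(blocks)) stop("`blocks` required for kind = 'blocks'.", call. = FALSE)
      members <- sort(unlist(blocks))
      if (!identical(as.integer(members), seq_len(K)))
        stop("`blocks` must partition 1..K.", call. = FALSE)
      A <- matrix(FALSE, K, K)
      for (b in blocks) A[b, b] <- TRUE
      if (!is.null(gates)) {
        g <- if (is.list(gates)) do.call(rbind, gates) else as.matrix(gates)
        if (ncol(g) != 2L || any(g < 1L) || any(g > K))
          stop("`gates` must be pairs of state indices in 1..K.", call. = FALSE)
        A[g] <- TRUE
      }
      diag(A) <- TRUE
      A
    },
    custom = {
      if (is.null(allowed)) stop("`allowed` required for kind = 'custom'.", call. = FALSE)
      A <- matrix(as.logical(allowed), K, K)
      diag(A) <- TRUE
      A
    })
  if (any(rowSums(A) == 0))
    stop("Mask leaves some state with no allowed successor.", call. = FALSE)
  structure(list(allowed = A, kind = kind, K = K), class = "glhmm_mask")
}

mask_matrix <- function(mask, K) {
  if (is.null(mask)) return(matrix(TRUE, K, K))
  if (inherits(mask, "glhmm_mask")) mask$allowed else matrix(as.logical(mask), K, K)
}

#' @export
print.glhmm_mask <- function(x, ...) {
  cat(sprintf("Transition mask (%s), K = %d, %d allowed transitions\n",
              x$kind, x$K, sum(x$allowed)))
  invisible(x)
}

#' Most probable state path (Viterbi decoding)
#'
#' Computes, per segment, the maximum a-posteriori state sequence given a
#' T x K matrix of per-state log-likelihoods and chain parameters. Computed in
#' log space; ties in the backtrack break toward the lowest state index.
#' Transitions forbidden by the mask get log-probability `-Inf`, so decoded
#' paths never violate the mask; if no feasible path exists an error is
#' raised.
#'
#' @param loglik T x K matrix of per-state log-likelihoods (e.g.
#'   [state_loglik()] output or expected log-likelihoods from a fitted model).
#' @param log_pi,log_theta chain parameters in log space (length-K vector and
#'   K x K matrix). Probabilities are accepted and logged via `log = TRUE`.
#' @param indices segment index matrix (1-based inclusive); default one
#'   segment.
#' @param mask optional transition mask ([make_transition_mask()] or logical
#'   matrix).
#' @param log are `log_pi` / `log_theta` already in log space? Default `TRUE`.
#' @return Integer vector of length T with values in `1..K`.
#' @export
viterbi <- function(loglik, log_pi, log_theta, indices = NULL, mask = NULL,
                    log = TRUE) {
  loglik <- as_matrix(loglik, "loglik")
  K <- ncol(loglik)
  if (!log) { log_pi <- base::log(log_pi); log_theta <- base::log(log_theta) }
  log_pi <- as.numeric(log_pi)
  log_theta <- matrix(as.numeric(log_theta), K, K)
  A <- mask_matrix(mask, K)
  log_theta[!A] <- -Inf
  if (is.null(indices)) indices <- matrix(c(1L, nrow(loglik)), 1L, 2L)
  indices <- matrix(as.integer(indices), ncol = 2L)
  path <- integer(nrow(loglik))
  for (i in seq_len(nrow(indices))) {
    rows <- seq.int(indices[i, 1L], indices[i, 2L])
    L <- loglik[rows, , drop = FALSE]
    Tn <- length(rows)
    delta <- matrix(-Inf, Tn, K)
    back <- matrix(1L, Tn, K)
    delta[1L, ] <- log_pi + L[1L, ]
    if (Tn > 1L) for (t in 2L:Tn) {
      cand <- delta[t - 1L, ] + log_theta       # K x K: from row, to col
      best <- apply(cand, 2L, which.max)        # first max -> lowest index
      delta[t, ] <- cand[cbind(best, seq_len(K))] + L[t, ]
      back[t, ] <- best
    }
    if (!any(is.finite(delta[Tn, ])))
      stop("No feasible state path under the transition mask.", call. = FALSE)
    seg_path <- integer(Tn)
    seg_path[Tn] <- which.max(delta[Tn, ])
    if (Tn > 1L) for (t in (Tn - 1L):1L)
      seg_path[t] <- back[t + 1L, seg_path[t + 1L]]
    path[rows] <- seg_path
  }
  path
}
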