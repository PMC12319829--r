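# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards. seed = NULL runs as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number.", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(x, name = deparse(substitute(x))) {
  if (is.null(x)) return(NULL)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop(sprintf("`%s` contains missing values.", name), call. = FALSE)
  x
}

# Symmetric positive-definite check via Cholesky; tolerance on asymmetry.
check_spd <- function(S, name = "Sigma", sym_tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop(sprintf("`%s` must be a square matrix.", name), call. = FALSE)
  if (max(abs(S - t(S))) > sym_tol * max(1, max(abs(S))))
    stop(sprintf("`%s` is not symmetric.", name), call. = FALSE)
  ch <- tryCatch(chol((S + t(S)) / 2), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("`%s` is not positive definite.", name), call. = FALSE)
  invisible(ch)
}

logdet_spd <- function(S) 2 * sum(log(diag(chol((S + t(S)) / 2))))

# log multivariate gamma function
lmvgamma <- function(a, p) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# E[log|Lambda|] for Lambda ~ Wishart(V, nu), scale/dof parameterisation,
# E[Lambda] = nu V.
wishart_elogdet <- function(V, nu) {
  q <- nrow(V)
  sum(digamma((nu + 1 - seq_len(q)) / 2)) + q * log(2) + logdet_spd(V)
}

# KL( Wishart(V1, nu1) || Wishart(V0, nu0) ), scale/dof parameterisation.
kl_wishart <- function(V1, nu1, V0, nu0) {
  q <- nrow(V1)
  V0inv <- chol2inv(chol(V0))
  el1 <- wishart_elogdet(V1, nu1)
  # log normaliser: log B(V, nu) = -(nu/2)log|V| - (nu q/2)log 2 - lmvgamma(nu/2, q)
  logB1 <- -(nu1 / 2) * logdet_spd(V1) - (nu1 * q / 2) * log(2) - lmvgamma(nu1 / 2, q)
  logB0 <- -(nu0 / 2) * logdet_spd(V0) - (nu0 * q / 2) * log(2) - lmvgamma(nu0 / 2, q)
  ((nu1 - nu0) / 2) * el1 + (nu1 / 2) * (sum(V0inv * V1) - q) + logB1 - logB0
}

# KL( Gamma(a1, b1) || Gamma(a0, b0) ), shape/rate.
kl_gamma <- function(a1, b1, a0, b0) {
  (a1 - a0) * digamma(a1) - lgamma(a1) + lgamma(a0) +
    a0 * (log(b1) - log(b0)) + a1 * (b0 - b1) / b1
}

# KL( Dirichlet(a1) || Dirichlet(a0) ) over the same support.
kl_dirichlet <- function(a1, a0) {
  s1 <- sum(a1)
  sum(lgamma(a0)) - lgamma(sum(a0)) - sum(lgamma(a1)) + lgamma(s1) +
    sum((a1 - a0) * (digamma(a1) - digamma(s1)))
}

# KL( N(m, S) || N(0, s0 I) )
kl_gaussian_iso <- function(m, S, s0) {
  d <- length(m)
  0.5 * (sum(diag(S)) / s0 + sum(m^2) / s0 - d -
           determinant(S, logarithm = TRUE)$modulus[1] + d * log(s0))
}

# All permutations of 1..n (n small); used for exact state matching.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out <- rbind(out, block)
  }
  out
}

#' Match estimated states to reference states
#'
#' Finds the state permutation that maximises the total similarity between two
#' sets of state-specific quantities, by exhaustive search over permutations
#' (intended for the small state numbers this package targets).
#'
#' @param similarity K x K matrix; entry (i, j) scores matching reference state
#'   i to estimated state j.
#' @return Integer vector `perm` of length K: estimated state `perm[i]`
#'   corresponds to reference state `i`.
#' @export
match_states <- function(similarity) {
  similarity <- as.matrix(similarity)
  K <- nrow(similarity)
  if (K > 8L) stop("match_states() enumerates permutations; K too large.", call. = FALSE)
  perms <- all_permutations(K)
  scores <- apply(perms, 1L, function(p) sum(similarity[cbind(seq_len(K), p)]))
  as.integer(perms[which.max(scores), ])
}

row_normalise <- function(M) M / pmax(rowSums(M), .Machine$double.xmin)
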