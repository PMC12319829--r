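# Readers and writers. Matrices travel as comma-separated text (header
# optional); segment index files use the 0-based half-open [start, end)
# convention common to HMM toolboxes and are converted to the in-memory
# 1-based inclusive form on load. Fitted models serialise to a single
# hierarchical JSON container.

read_num_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(as.numeric(
    strsplit(first, ",", fixed = TRUE)[[1L]]))))
  m <- as.matrix(utils::read.csv(path, header = has_header))
  storage.mode(m) <- "double"
  m
}

write_num_matrix <- function(m, path, col_names = FALSE) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = col_names)
}

#' Load time-series data from delimited files
#'
#' Reads `Y` (and optionally `X`), a segment index file and an optional
#' subject file into a validated [glhmm_data()]. Index files are 0-based
#' half-open `[start, end)` rows. Any missing value is rejected: the model
#' cannot handle missing values in `X` or `Y` unless they occur in both time
#' series at the same time, so rows with missing values must be removed (and
#' segments adjusted) before loading.
#'
#' @param y_path path to the T x q dependent-data file.
#' @param x_path optional path to the T x p independent-data file.
#' @param indices_path optional path to the 0-based half-open segment file.
#' @param subjects_path optional path to a one-column subject-per-segment
#'   file.
#' @return a [glhmm_data()].
#' @export
load_timeseries <- function(y_path, x_path = NULL, indices_path = NULL,
                            subjects_path = NULL) {
  Y <- as.matrix(utils::read.csv(y_path, header = FALSE))
  storage.mode(Y) <- "double"
  if (anyNA(Y))
    stop("Missing values in Y: the model cannot handle missing values in X ",
         "or Y unless they occur in both time series at the same time; ",
         "remove those rows before loading.", call. = FALSE)
  X <- NULL
  if (!is.null(x_path)) {
    X <- as.matrix(utils::read.csv(x_path, header = FALSE))
    storage.mode(X) <- "double"
    if (anyNA(X))
      stop("Missing values in X: the model cannot handle missing values in X ",
           "or Y unless they occur in both time series at the same time; ",
           "remove those rows before loading.", call. = FALSE)
  }
  indices <- NULL
  if (!is.null(indices_path)) {
    idx0 <- as.matrix(utils::read.csv(indices_path, header = FALSE))
    # 0-based half-open -> 1-based inclusive
    indices <- cbind(idx0[, 1L] + 1L, idx0[, 2L])
  }
  subjects <- NULL
  if (!is.null(subjects_path))
    subjects <- as.integer(utils::read.csv(subjects_path, header = FALSE)[[1L]])
  glhmm_data(Y, X = X, indices = indices, subjects = subjects)
}

#' Write time-series data to delimited files
#'
#' Inverse of [load_timeseries()]; the index file is written 0-based
#' half-open.
#'
#' @param data a [glhmm_data()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_timeseries <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_matrix(data$Y, file.path(dir, "Y.csv"))
  if (!is.null(data$X)) write_num_matrix(data$X, file.path(dir, "X.csv"))
  idx0 <- cbind(data$indices[, 1L] - 1L, data$indices[, 2L])
  write_num_matrix(idx0, file.path(dir, "indices.csv"))
  if (!is.null(data$subjects))
    write_num_matrix(cbind(data$subjects), file.path(dir, "subjects.csv"))
  invisible(dir)
}

# nested-list view of the posterior for JSON round-tripping
posterior_to_list <- function(post) {
  list(q = post$q,
       obs = list(
         blocks = lapply(post$obs$blocks, function(b)
           list(name = b$name, cols = b$cols, mode = b$mode, nb = b$nb)),
         m = lapply(post$obs$m, function(a) list(dim = dim(a), values = as.numeric(a))),
         S = lapply(post$obs$S, function(st)
           lapply(st, function(byq) lapply(byq, function(S)
             list(dim = dim(S), values = as.numeric(S)))))),
       cov = {
         cv <- post$cov
         cv$ELambda <- list(dim = dim(cv$ELambda), values = as.numeric(cv$ELambda))
         if (!is.null(cv$V)) cv$V <- list(dim = dim(cv$V), values = as.numeric(cv$V))
         if (!is.null(cv$a)) cv$a <- list(dim = dim(cv$a), values = as.numeric(cv$a))
         if (!is.null(cv$b)) cv$b <- list(dim = dim(cv$b), values = as.numeric(cv$b))
         cv
       },
       chain = list(pi_alpha = post$chain$pi_alpha,
                    theta_alpha = as.numeric(post$chain$theta_alpha),
                    mask = as.numeric(post$chain$mask)))
}

posterior_from_list <- function(pl, config) {
  restore <- function(x) array(as.numeric(x$values), unlist(x$dim))
  K <- config$K
  obs <- list(
    blocks = lapply(pl$obs$blocks, function(b)
      list(name = b$name, cols = as.integer(unlist(b$cols)), mode = b$mode,
           nb = as.integer(b$nb))),
    m = lapply(pl$obs$m, restore),
    S = lapply(pl$obs$S, function(st)
      lapply(st, function(byq) lapply(byq, function(S)
        matrix(restore(S), unlist(S$dim)[1L], unlist(S$dim)[2L])))))
  cv <- pl$cov
  cv$type <- as.character(cv$type)
  cv$ELambda <- restore(cv$ELambda)
  cv$Elogdet <- as.numeric(unlist(cv$Elogdet))
  if (!is.null(cv$V)) cv$V <- restore(cv$V)
  if (!is.null(cv$nu)) cv$nu <- as.numeric(unlist(cv$nu))
  if (!is.null(cv$a)) cv$a <- matrix(restore(cv$a), unlist(pl$cov$a$dim)[1L])
  if (!is.null(cv$b)) cv$b <- matrix(restore(cv$b), unlist(pl$cov$b$dim)[1L])
  chain <- list(pi_alpha = as.numeric(unlist(pl$chain$pi_alpha)),
                theta_alpha = matrix(as.numeric(unlist(pl$chain$theta_alpha)), K, K),
                mask = matrix(as.logical(as.numeric(unlist(pl$chain$mask))), K, K))
  chain <- chain_expectations(chain)
  list(config = config, q = as.integer(pl$q), obs = obs, cov = cv, chain = chain)
}

#' Save / load a fitted GLHMM
#'
#' Serialises the configuration, prior hyperparameters and all posterior
#' factors of a fitted model to a single hierarchical JSON file. The data
#' are not stored; supply them again on load to restore a fully functional
#' model object.
#'
#' @param model a fitted [glhmm()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_glhmm <- function(model, path) {
  stopifnot(inherits(model, "glhmm"))
  cfg <- model$config
  obj <- list(
    package = "glhmmr",
    config = list(K = cfg$K, mean_mode = cfg$mean_mode,
                  beta_mode = cfg$beta_mode, cov_mode = cfg$cov_mode,
                  cov_shape = cfg$cov_shape, dirichlet_diag = cfg$dirichlet_diag,
                  prior = cfg$prior,
                  transition_mask = if (is.null(cfg$transition_mask)) NULL
                  else as.numeric(mask_matrix(cfg$transition_mask, cfg$K))),
    posterior = posterior_to_list(model$posterior),
    free_energy = model$free_energy,
    fe_trace = model$fe_trace,
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_glhmm
#' @param data optional [glhmm_data()] to reattach (enables the data-dependent
#'   methods and summaries).
#' @export
load_glhmm <- function(path, data = NULL) {
  obj <- jsonlite::read_json(path)
  cl <- obj$config
  mask <- NULL
  if (!is.null(cl$transition_mask))
    mask <- matrix(as.numeric(unlist(cl$transition_mask)) > 0, cl$K, cl$K)
  config <- glhmm_config(K = cl$K, mean_mode = cl$mean_mode,
                         beta_mode = cl$beta_mode, cov_mode = cl$cov_mode,
                         cov_shape = cl$cov_shape,
                         dirichlet_diag = cl$dirichlet_diag,
                         transition_mask = mask,
                         prior = lapply(cl$prior, function(x)
                           if (is.null(x)) NULL else as.numeric(x)))
  post <- posterior_from_list(obj$posterior, config)
  out <- list(config = config, posterior = post,
              priors = build_priors(config, post$q),
              free_energy = as.numeric(obj$free_energy %||% NA),
              fe_trace = as.numeric(unlist(obj$fe_trace)),
              K = config$K, seed = obj$seed)
  class(out) <- "glhmm"
  if (!is.null(data)) {
    out$data <- data
    out$meta <- build_design(config, data)
    L <- expected_loglik(post, data, out$meta)
    fb <- forward_backward(L, post$chain$Elog_pi, post$chain$Elog_theta,
                           data$indices)
    out$gamma <- fb$gamma
    out$xi <- fb$xi
    out$logZ <- fb$logZ
    out$vpath <- viterbi(L, post$chain$Elog_pi, post$chain$Elog_theta,
                         data$indices, mask = config$transition_mask)
  }
  out
}

#' Write a decoded state path
#'
#' Single-column delimited text with a header line recording K and the
#' 0-based half-open segment boundaries.
#'
#' @param vpath integer state path.
#' @param indices segment index matrix (1-based inclusive).
#' @param K number of states.
#' @param path output file.
#' @export
write_vpath <- function(vpath, indices, K, path) {
  idx0 <- cbind(indices[, 1L] - 1L, indices[, 2L])
  header <- sprintf("# K=%d segments=%s", K,
                    paste(apply(idx0, 1L, paste, collapse = ":"), collapse = ","))
  writeLines(c(header, as.character(vpath)), path)
  invisible(path)
}
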