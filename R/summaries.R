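# Time-aggregated statistics of the latent state dynamics: fractional
# occupancy, dwell times, switching rates and occupancy entropy, computed per
# unit (subject, session or trial). Units are given as one id per segment;
# statistics are invariant to unit relabelling.

unit_split <- function(indices, unit_of_segment) {
  indices <- matrix(as.integer(indices), ncol = 2L)
  if (is.null(unit_of_segment)) unit_of_segment <- seq_len(nrow(indices))
  if (length(unit_of_segment) != nrow(indices))
    stop("`unit_of_segment` must have one entry per segment.", call. = FALSE)
  ids <- unique(unit_of_segment)
  lapply(ids, function(u) which(unit_of_segment == u))
}

#' Fractional occupancy per unit
#'
#' The proportion of time each unit spends in each state: the per-unit mean
#' of the state-probability rows.
#'
#' @param gamma T x K matrix of state probabilities (rows sum to 1), e.g. a
#'   fitted model's `$gamma`. A categorical path is accepted and one-hot
#'   encoded.
#' @param indices segment index matrix (1-based inclusive).
#' @param unit_of_segment unit id per segment (default: each segment its own
#'   unit).
#' @return N x K matrix of fractional occupancies; rows sum to 1.
#' @export
fractional_occupancy <- function(gamma, indices, unit_of_segment = NULL) {
  if (is.null(dim(gamma))) stop("`gamma` must be a matrix.", call. = FALSE)
  groups <- unit_split(indices, unit_of_segment)
  indices <- matrix(as.integer(indices), ncol = 2L)
  out <- t(vapply(groups, function(segs) {
    rows <- unlist(lapply(segs, function(i) seq.int(indices[i, 1L], indices[i, 2L])))
    if (!length(rows)) stop("Empty unit.", call. = FALSE)
    colMeans(gamma[rows, , drop = FALSE])
  }, numeric(ncol(gamma))))
  matrix(out, length(groups), ncol(gamma))
}

#' Entropy of a fractional-occupancy vector
#'
#' \eqn{H = -\sum_k FO_k \log FO_k} in nats, with \eqn{0 \log 0 = 0}. Zero
#' when a single state is visited; \eqn{\log K} at uniform occupancy. A
#' summary of the temporal complexity of the state dynamics.
#'
#' @param fo probability vector (or N x K matrix, one row per unit).
#' @return scalar (or length-N vector) entropy in nats.
#' @export
fo_entropy <- function(fo) {
  ent <- function(p) {
    p <- p[p > 0]
    max(0, -sum(p * log(p)))
  }
  if (is.matrix(fo)) apply(fo, 1L, ent) else ent(as.numeric(fo))
}

# maximal runs of a path restricted to one segment
path_runs <- function(vpath, indices) {
  indices <- matrix(as.integer(indices), ncol = 2L)
  runs <- list()
  for (i in seq_len(nrow(indices))) {
    seg <- vpath[seq.int(indices[i, 1L], indices[i, 2L])]
    r <- rle(seg)
    runs[[i]] <- list(states = r$values, lengths = r$lengths)
  }
  runs
}

#' Mean dwell times per unit and state
#'
#' The average length (in time points) of maximal constant runs ("visits") of
#' each state in the decoded path. Visits are truncated at segment
#' boundaries, i.e. a state active at the end of one segment and the start of
#' the next counts as two visits. States never visited by a unit get `NA`
#' (not zero), so unvisited states do not bias downstream tests.
#'
#' @param vpath integer state path (values `1..K`).
#' @param indices segment index matrix.
#' @param K number of states (default `max(vpath)`).
#' @param unit_of_segment unit id per segment.
#' @return N x K matrix of mean visit durations (NA where unvisited).
#' @export
dwell_times <- function(vpath, indices, K = max(vpath), unit_of_segment = NULL) {
  groups <- unit_split(indices, unit_of_segment)
  runs <- path_runs(vpath, indices)
  out <- matrix(NA_real_, length(groups), K)
  for (u in seq_along(groups)) {
    st <- unlist(lapply(runs[groups[[u]]], `[[`, "states"))
    len <- unlist(lapply(runs[groups[[u]]], `[[`, "lengths"))
    for (k in seq_len(K)) if (any(st == k)) out[u, k] <- mean(len[st == k])
  }
  out
}

#' Switching rate per unit
#'
#' The fraction of within-segment consecutive time-point pairs at which the
#' decoded state changes; equivalently one minus the mean self-transition
#' indicator.
#'
#' @inheritParams dwell_times
#' @return length-N vector in `[0, 1)`.
#' @export
switching_rate <- function(vpath, indices, unit_of_segment = NULL) {
  groups <- unit_split(indices, unit_of_segment)
  indices <- matrix(as.integer(indices), ncol = 2L)
  vapply(groups, function(segs) {
    changes <- 0L
    pairs <- 0L
    for (i in segs) {
      seg <- vpath[seq.int(indices[i, 1L], indices[i, 2L])]
      if (length(seg) > 1L) {
        changes <- changes + sum(seg[-1L] != seg[-length(seg)])
        pairs <- pairs + length(seg) - 1L
      }
    }
    if (pairs == 0L)
      stop("Unit with fewer than 2 time points: switching rate undefined.",
           call. = FALSE)
    changes / pairs
  }, numeric(1L))
}

#' State-evoked response across equal-length trials
#'
#' The average state probabilities across trials, per within-trial time
#' point: the state-space analogue of an evoked response.
#'
#' @param gamma T x K state probabilities.
#' @param indices trial index matrix; all trials must have equal length.
#' @return T_trial x K matrix; rows still sum to 1.
#' @export
state_evoked_response <- function(gamma, indices) {
  indices <- matrix(as.integer(indices), ncol = 2L)
  lens <- indices[, 2L] - indices[, 1L] + 1L
  if (length(unique(lens)) != 1L)
    stop("All trials must have the same length.", call. = FALSE)
  Tt <- lens[1L]
  out <- matrix(0, Tt, ncol(gamma))
  for (i in seq_len(nrow(indices)))
    out <- out + gamma[seq.int(indices[i, 1L], indices[i, 2L]), , drop = FALSE]
  out / nrow(indices)
}

#' All aggregated statistics for a fitted model
#'
#' Convenience wrapper computing fractional occupancy (from the state
#' probabilities), mean dwell times and switching rate (from the Viterbi
#' path) and occupancy entropy, per unit.
#'
#' @param model a fitted [glhmm()].
#' @param by `"subject"` (when a subject map exists) or `"segment"`.
#' @return list with `FO` (N x K), `dwell` (N x K, NA where unvisited),
#'   `switch_rate` (N), `entropy` (N).
#' @export
aggregate_stats <- function(model, by = c("subject", "segment")) {
  stopifnot(inherits(model, "glhmm"))
  units <- segment_units(model$data, by = match.arg(by))
  idx <- model$data$indices
  FO <- fractional_occupancy(model$gamma, idx, units)
  list(FO = FO,
       dwell = dwell_times(model$vpath, idx, K = model$K, unit_of_segment = units),
       switch_rate = switching_rate(model$vpath, idx, units),
       entropy = fo_entropy(FO))
}
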