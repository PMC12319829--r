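#' Concatenated multivariate time series for GLHMM modelling
#'
#' Container for the dependent series `Y` (T x q), the optional independent
#' series `X` (T x p) and the segment structure. Segments (sessions, trials,
#' or any continuous streams) are rows of `indices`: a two-column matrix of
#' 1-based inclusive `[start, end]` row ranges that must be disjoint, ordered
#' and tile `1..T`. `X`, when present, must have exactly the same number of
#' rows as `Y`: the two series must be simultaneously sampled, so missing
#' values cannot occur in one series without occurring in the other — any
#' missing value is rejected.
#'
#' On-disk index files use the 0-based half-open `[start, end)` convention
#' common to HMM toolboxes; [load_timeseries()] and [write_timeseries()]
#' convert at the boundary.
#'
#' @param Y numeric matrix (or vector) of dependent data, T x q.
#' @param X optional numeric matrix of independent data, T x p.
#' @param indices optional segment matrix (n_segments x 2, 1-based inclusive);
#'   default: a single segment spanning all rows.
#' @param subjects optional integer/factor vector of length `n_segments`
#'   assigning each segment to a subject (used for batching, dual estimation
#'   and per-subject summaries).
#' @return An object of class `"glhmm_data"` with elements `Y`, `X`,
#'   `indices`, `subjects`, `T`, `q`, `p`, `n_segments`.
#' @export
glhmm_data <- function(Y, X = NULL, indices = NULL, subjects = NULL) {
  Y <- as_matrix(Y, "Y")
  Tn <- nrow(Y)
  if (Tn < 1L || ncol(Y) < 1L) stop("`Y` must have at least one row and column.",
                                    call. = FALSE)
  if (!is.null(X)) {
    X <- as_matrix(X, "X")
    if (nrow(X) != Tn)
      stop(sprintf(paste0("`X` has %d rows but `Y` has %d: X and Y must have the ",
                          "same length and be simultaneously sampled."),
                   nrow(X), Tn), call. = FALSE)
  }
  if (is.null(indices)) indices <- matrix(c(1L, Tn), 1L, 2L)
  indices <- matrix(as.integer(as.matrix(indices)), ncol = 2L)
  if (any(indices[, 2L] < indices[, 1L]))
    stop("Each segment must satisfy start <= end.", call. = FALSE)
  # disjoint, ordered, tiling 1..T
  expected_start <- c(1L, indices[-nrow(indices), 2L] + 1L)
  if (any(indices[, 1L] != expected_start) || indices[nrow(indices), 2L] != Tn)
    stop("Segments must be disjoint, ordered and tile rows 1..T exactly.",
         call. = FALSE)
  if (!is.null(subjects)) {
    if (length(subjects) != nrow(indices))
      stop("`subjects` must have one entry per segment.", call. = FALSE)
    subjects <- as.integer(factor(subjects, levels = unique(subjects)))
  }
  structure(list(Y = Y, X = X, indices = indices, subjects = subjects,
                 T = Tn, q = ncol(Y), p = if (is.null(X)) 0L else ncol(X),
                 n_segments = nrow(indices)),
            class = "glhmm_data")
}

#' @export
print.glhmm_data <- function(x, ...) {
  cat(sprintf("GLHMM data: T = %d, q = %d, p = %d, %d segment(s)%s\n",
              x$T, x$q, x$p, x$n_segments,
              if (is.null(x$subjects)) ""
              else sprintf(", %d subject(s)", length(unique(x$subjects)))))
  invisible(x)
}

# Rows belonging to segment i
segment_rows <- function(data, i) seq.int(data$indices[i, 1L], data$indices[i, 2L])

# Segment lengths
seg_lengths <- function(data) data$indices[, 2L] - data$indices[, 1L] + 1L

# Restrict a glhmm_data object to a subset of segments (keeps order).
subset_segments <- function(data, segs) {
  segs <- sort(unique(as.integer(segs)))
  rows <- unlist(lapply(segs, function(i) segment_rows(data, i)))
  lens <- seg_lengths(data)[segs]
  ends <- cumsum(lens)
  idx <- cbind(ends - lens + 1L, ends)
  glhmm_data(data$Y[rows, , drop = FALSE],
             X = if (is.null(data$X)) NULL else data$X[rows, , drop = FALSE],
             indices = idx,
             subjects = if (is.null(data$subjects)) NULL else data$subjects[segs])
}

# Map each segment to a unit id (subject if available, else the segment itself).
segment_units <- function(data, by = c("subject", "segment")) {
  by <- match.arg(by)
  if (by == "subject" && !is.null(data$subjects)) data$subjects
  else seq_len(data$n_segments)
}
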