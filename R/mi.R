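# plug-in mutual information (in bits by default) from 2x2 joint counts;
# vectorised over pairs, with the 0 log 0 = 0 convention
.mi_from_counts <- function(n11, n10, n01, n00, base = 2) {
  tt <- n11 + n10 + n01 + n00
  p11 <- n11 / tt; p10 <- n10 / tt; p01 <- n01 / tt; p00 <- n00 / tt
  p1i <- p11 + p10; p1j <- p11 + p01
  p0i <- 1 - p1i; p0j <- 1 - p1j
  term <- function(p, qi, qj) {
    out <- p * log(p / (qi * qj))
    out[!is.finite(out) | p == 0] <- 0
    out
  }
  mi <- term(p11, p1i, p1j) + term(p10, p1i, p0j) +
    term(p01, p0i, p1j) + term(p00, p0i, p0j)
  mi / log(base)
}

#' Pairwise mutual information between node occupancies
#'
#' Plug-in (empirical frequency) estimator of the mutual information between
#' every pair of binary occupancy variables over a window of frames:
#' `MI(I_i, I_j) = sum P_ij log( P_ij / (P_i P_j) )`, with marginals and
#' joint taken as the empirical 2x2 frequencies in the window and zero-count
#' cells contributing zero.
#'
#' @param occupancy an `occupancy_matrix`.
#' @param frame_window integer vector of frame indices (0-based) to use;
#'   default all frames.
#' @param base logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @return An object of class `mi_matrix`: list with `values` (N x N
#'   symmetric non-negative matrix, zero diagonal), `node_ids`, `window_s`,
#'   `base`.
#' @export
pairwise_mi <- function(occupancy, frame_window = NULL, base = 2) {
  stopifnot(inherits(occupancy, "occupancy_matrix"))
  X <- occupancy$values
  if (!is.null(frame_window)) X <- X[frame_window + 1L, , drop = FALSE]
  tt <- nrow(X)
  if (tt < 2L) stop("window must contain at least 2 frames")
  storage.mode(X) <- "double"
  c1 <- colSums(X)
  n11 <- crossprod(X)
  n10 <- matrix(c1, nrow = length(c1), ncol = length(c1)) - n11
  n01 <- t(n10)
  n00 <- tt - n11 - n10 - n01
  mi <- .mi_from_counts(n11, n10, n01, n00, base)
  mi[mi < 0] <- 0                       # clip tiny negative rounding noise
  diag(mi) <- 0
  fr <- occupancy$frame_rate_hz
  win <- if (is.null(frame_window)) c(0, (nrow(occupancy$values) - 1) / fr)
    else range(frame_window) / fr
  structure(list(values = mi, node_ids = occupancy$node_ids,
                 window_s = win, base = base),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("Pairwise MI matrix: ", nrow(x$values), " nodes, window [",
      round(x$window_s[1]), ", ", round(x$window_s[2]), "] s, <MI> = ",
      signif(average_mi(x), 4),
      if (x$base == 2) " bits" else " nats", "\n", sep = "")
  invisible(x)
}

#' Average pairwise mutual information
#'
#' The mean of `MI(I_i, I_j)` over the `N (N - 1) / 2` unordered node pairs
#' (equivalently `2 / (N (N - 1))` times the sum over ordered pairs).
#'
#' @param mi_matrix an `mi_matrix` (or a plain symmetric matrix).
#' @return Scalar average MI.
#' @export
average_mi <- function(mi_matrix) {
  m <- if (inherits(mi_matrix, "mi_matrix")) mi_matrix$values else mi_matrix
  n <- nrow(m)
  if (n < 2L) stop("average MI needs at least 2 nodes")
  sum(m[upper.tri(m)]) / (n * (n - 1) / 2)
}

#' Nearest-neighbour mutual information map
#'
#' For each node, the mean MI with its channel-adjacent neighbours — the
#' local quantity mapped as spatial MI heatmaps.
#'
#' @param mi_matrix an `mi_matrix`.
#' @param arena the `hex_arena` defining adjacency.
#' @return Numeric vector (one value per node, `NA` for isolated nodes)
#'   named by node id.
#' @export
neighbor_mi_map <- function(mi_matrix, arena) {
  stopifnot(inherits(mi_matrix, "mi_matrix"), inherits(arena, "hex_arena"))
  ids <- mi_matrix$node_ids
  col_of <- match(seq_len(nrow(arena$nodes)), ids)
  out <- vapply(seq_along(ids), function(k) {
    nb <- arena$adj[[ids[k]]]
    nbc <- col_of[nb]
    nbc <- nbc[!is.na(nbc)]
    if (!length(nbc)) return(NA_real_)
    mean(mi_matrix$values[k, nbc])
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Moving-window average mutual information series
#'
#' Computes `average_mi(pairwise_mi(window))` for a moving window across the
#' trial. The defaults (15 min window, 2.5 min step) mitigate estimator
#' noise while resolving the foraging phases.
#'
#' @param occupancy an `occupancy_matrix`.
#' @param window_s window length in seconds (default 900).
#' @param step_s step between window centers in seconds (default 150).
#' @param base logarithm base for the MI.
#' @return An object of class `mi_series`: data frame `center_s`,
#'   `avg_mi`, with attributes `window_s`, `step_s`.
#' @export
windowed_average_mi <- function(occupancy, window_s = 900, step_s = 150,
                                base = 2) {
  stopifnot(inherits(occupancy, "occupancy_matrix"), step_s > 0)
  fr <- occupancy$frame_rate_hz
  n_frames <- nrow(occupancy$values)
  win_f <- as.integer(round(window_s * fr))
  step_f <- as.integer(round(step_s * fr))
  if (win_f > n_frames) stop("window longer than the trial")
  starts <- seq.int(0L, n_frames - win_f, by = step_f)
  vals <- vapply(starts, function(s) {
    average_mi(pairwise_mi(occupancy, frame_window = s:(s + win_f - 1L),
                           base = base))
  }, numeric(1))
  out <- data.frame(center_s = (starts + (win_f - 1) / 2) / fr,
                    avg_mi = vals)
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  class(out) <- c("mi_series", "data.frame")
  out
}

#' @export
plot.mi_series <- function(x, ...) {
  plot(x$center_s / 60, x$avg_mi, type = "b", pch = 16,
       xlab = "time (min)", ylab = expression(group("<", MI, ">")), ...)
  invisible(x)
}

#' Lag times between average-MI turning points and the transition points
#'
#' The series is smoothed with a 3-point moving mean; the rise onset is the
#' time of the series minimum between the start and the global maximum, and
#' the fall onset is the time of the global maximum after TP1. `T1` is the
#' rise onset minus TP1 and `T2` the fall onset minus TP2; negative values
#' mean the collective response anticipates the transition point, positive
#' values a delayed response.
#'
#' @param mi_series an `mi_series`.
#' @param phases a `phase_bounds` with both transition points present.
#' @return List of class `lag_times` with `T1_s`, `T2_s` (seconds; `NA`
#'   when the series has no turning point).
#' @export
lag_times <- function(mi_series, phases) {
  if (is.na(phases$TP1_s) || is.na(phases$TP2_s))
    stop("lag times require both transition points")
  t <- mi_series$center_s
  v <- mi_series$avg_mi
  if (length(v) >= 3)
    v <- stats::filter(v, rep(1 / 3, 3), sides = 2) |> as.numeric()
  ok <- !is.na(v)
  t2 <- t[ok]; v2 <- v[ok]
  if (length(v2) < 3 || diff(range(v2)) == 0)
    return(structure(list(T1_s = NA_real_, T2_s = NA_real_),
                     class = "lag_times"))
  after_tp1 <- which(t2 >= phases$TP1_s)
  if (!length(after_tp1)) after_tp1 <- seq_along(t2)
  i_max <- after_tp1[which.max(v2[after_tp1])]
  pre <- seq_len(i_max)
  i_min <- pre[which.min(v2[pre])]
  # a series still rising at the end (or falling throughout) has no
  # usable turning points
  if (i_min == i_max || i_max == length(t2))
    return(structure(list(T1_s = NA_real_, T2_s = NA_real_),
                     class = "lag_times"))
  structure(list(T1_s = t2[i_min] - phases$TP1_s,
                 T2_s = t2[i_max] - phases$TP2_s),
            class = "lag_times")
}

#' @export
print.lag_times <- function(x, ...) {
  cat("MI lag times: T1 = ", x$T1_s, " s, T2 = ", x$T2_s, " s\n", sep = "")
  invisible(x)
}
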