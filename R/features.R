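#' Convert track detections to a binary node-occupancy matrix
#'
#' Each detection is snapped to its nearest arena node if that node lies
#' within `snap_radius_mm`; detections further than the radius are dropped.
#' A node with at least one assigned detection in a frame is occupied
#' (`I_i(t) = 1`), otherwise empty. Columns follow `arena$active_nodes`.
#'
#' @param tracks a track data frame (`frame`, `ant_id`, `x_mm`, `y_mm`;
#'   a `node_id` column, if present, is ignored in favour of coordinates).
#' @param arena a `hex_arena`.
#' @param snap_radius_mm assignment radius in mm; default 25 (half a
#'   channel) prevents cross-node misassignment.
#' @param n_frames total number of frames of the trial; defaults to
#'   `max(frame) + 1`.
#' @param frame_rate_hz frame rate stored with the matrix.
#' @return An object of class `occupancy_matrix`: list with `values`
#'   (n_frames x N integer 0/1 matrix), `node_ids`, `frame_rate_hz`.
#' @export
binarize_tracks <- function(tracks, arena, snap_radius_mm = 25,
                            n_frames = NULL, frame_rate_hz = 2) {
  stopifnot(inherits(arena, "hex_arena"), snap_radius_mm > 0)
  node_ids <- arena$active_nodes
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  vals <- matrix(0L, nrow = n_frames, ncol = length(node_ids))
  if (nrow(tracks)) {
    if (any(tracks$frame < 0L) || any(tracks$frame >= n_frames))
      stop("track frames outside [0, n_frames)")
    # nearest node per detection; detections repeat coordinates heavily
    # (node-snapped tracks), so query only the unique coordinate pairs
    nx <- arena$nodes$x; ny <- arena$nodes$y
    key <- paste(tracks$x_mm, tracks$y_mm)
    uq <- which(!duplicated(key))
    near_uq <- vapply(uq, function(i) {
      d2 <- (nx - tracks$x_mm[i])^2 + (ny - tracks$y_mm[i])^2
      j <- which.min(d2)
      if (d2[j] <= snap_radius_mm^2) j else NA_integer_
    }, integer(1))
    near <- near_uq[match(key, key[uq])]
    keep <- !is.na(near)
    col <- match(near[keep], node_ids)
    vals[cbind(tracks$frame[keep] + 1L, col)] <- 1L
  }
  structure(list(values = vals, node_ids = node_ids,
                 frame_rate_hz = frame_rate_hz),
            class = "occupancy_matrix")
}

# fast path used by the pipeline when tracks already carry node ids
occupancy_from_nodes <- function(tracks, arena, n_frames = NULL,
                                 frame_rate_hz = 2) {
  node_ids <- arena$active_nodes
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  vals <- matrix(0L, nrow = n_frames, ncol = length(node_ids))
  if (nrow(tracks))
    vals[cbind(tracks$frame + 1L, match(tracks$node_id, node_ids))] <- 1L
  structure(list(values = vals, node_ids = node_ids,
                 frame_rate_hz = frame_rate_hz),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Binary occupancy matrix: ", nrow(x$values), " frames x ",
      ncol(x$values), " nodes at ", x$frame_rate_hz, " Hz; fill ",
      signif(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Per-frame ant activity
#'
#' Activity is the number of distinct individuals present in the arena at
#' each frame.
#'
#' @param tracks a track data frame.
#' @param n_frames total number of frames; defaults to `max(frame) + 1`.
#' @return Data frame `frame`, `n_ants`.
#' @export
activity_series <- function(tracks, n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  if (nrow(tracks) &&
      anyDuplicated(paste(tracks$frame, tracks$ant_id)))
    stop("an ant appears more than once in a frame")
  counts <- tabulate(tracks$frame + 1L, nbins = n_frames)
  data.frame(frame = seq_len(n_frames) - 1L, n_ants = counts)
}

#' Per-frame ant-ant encounters and their cumulative count
#'
#' Every unordered pair of ants closer than one body length in a frame
#' contributes one encounter to that frame (no debouncing across frames).
#'
#' @param tracks a track data frame with `x_mm`, `y_mm`.
#' @param body_length_mm encounter radius, default 10 mm (worker scale of
#'   *Aphaenogaster senilis*).
#' @param n_frames total number of frames.
#' @return Data frame `frame`, `encounters`, `cumulative`.
#' @export
interaction_series <- function(tracks, body_length_mm = 10, n_frames = NULL) {
  stopifnot(body_length_mm > 0)
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 0L
  enc <- integer(n_frames)
  if (nrow(tracks)) {
    xs <- split(tracks$x_mm, tracks$frame)
    ys <- split(tracks$y_mm, tracks$frame)
    fr <- as.integer(names(xs))
    for (k in seq_along(fr)) {
      m <- length(xs[[k]])
      if (m >= 2L) {
        d <- stats::dist(cbind(xs[[k]], ys[[k]]))
        enc[fr[k] + 1L] <- sum(d < body_length_mm)
      }
    }
  }
  data.frame(frame = seq_len(n_frames) - 1L, encounters = enc,
             cumulative = cumsum(enc))
}

#' Transition points bounding the three foraging phases
#'
#' TP1 is the time of the first `food_found` event (first item discovered);
#' TP2 the time of the last `food_collected` event (last item brought home).
#' Trials without food events (no-food condition) have both markers absent
#' (`NA`), and the whole trial counts as exploration.
#'
#' @param events an event data frame (`time_s`, `kind`, ...).
#' @param duration_s trial length; defaults to the last event time.
#' @return A list of class `phase_bounds` with `TP1_s`, `TP2_s`,
#'   `duration_s`.
#' @export
transition_points <- function(events, duration_s = NULL) {
  if (is.unsorted(events$time_s)) stop("events must be time-ordered")
  found <- events$time_s[events$kind == "food_found"]
  coll <- events$time_s[events$kind == "food_collected"]
  if (length(coll) && (!length(found) || min(coll) < min(found)))
    stop("inconsistent log: food_collected before any food_found")
  if (is.null(duration_s))
    duration_s <- if (nrow(events)) max(events$time_s) else 0
  structure(list(
    TP1_s = if (length(found)) min(found) else NA_real_,
    TP2_s = if (length(coll)) max(coll) else NA_real_,
    duration_s = duration_s
  ), class = "phase_bounds")
}

#' @export
print.phase_bounds <- function(x, ...) {
  cat("Phase bounds: TP1 = ",
      if (is.na(x$TP1_s)) "absent" else paste0(x$TP1_s, " s"),
      ", TP2 = ",
      if (is.na(x$TP2_s)) "absent" else paste0(x$TP2_s, " s"),
      " (trial ", x$duration_s, " s)\n", sep = "")
  invisible(x)
}

#' Phase label of each frame
#'
#' Partitions `[0, duration)` into exploration `[0, TP1)`, exploitation
#' `[TP1, TP2)` and relaxation `[TP2, duration)`. With absent transition
#' points every frame is exploration.
#'
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate.
#' @param phases a `phase_bounds`.
#' @return Factor of length `n_frames` with levels exploration,
#'   exploitation, relaxation.
#' @export
phase_of_frames <- function(n_frames, frame_rate_hz, phases) {
  t_s <- (seq_len(n_frames) - 1L) / frame_rate_hz
  lab <- rep("exploration", n_frames)
  if (!is.na(phases$TP1_s)) {
    lab[t_s >= phases$TP1_s] <- "exploitation"
    if (!is.na(phases$TP2_s)) lab[t_s >= phases$TP2_s] <- "relaxation"
  }
  factor(lab, levels = c("exploration", "exploitation", "relaxation"))
}

#' Per-capita occupancy by foraging phase
#'
#' For each frame, the number of occupied nodes divided by the number of
#' ants in the arena; frames with no ants are excluded, and the ratio is
#' averaged within each phase.
#'
#' @param occupancy an `occupancy_matrix`.
#' @param activity an activity data frame aligned to the same frames.
#' @param phases a `phase_bounds`.
#' @return Named numeric vector (exploration, exploitation, relaxation);
#'   `NaN` marks phases with no populated frames.
#' @export
per_capita_occupancy <- function(occupancy, activity, phases) {
  stopifnot(inherits(occupancy, "occupancy_matrix"))
  n_frames <- nrow(occupancy$values)
  if (nrow(activity) != n_frames)
    stop("occupancy and activity frame axes differ")
  occ <- rowSums(occupancy$values)
  lab <- phase_of_frames(n_frames, occupancy$frame_rate_hz, phases)
  keep <- activity$n_ants > 0L
  ratio <- occ[keep] / activity$n_ants[keep]
  out <- tapply(ratio, lab[keep], mean)
  res <- stats::setNames(rep(NaN, 3),
                         c("exploration", "exploitation", "relaxation"))
  res[names(out)] <- out
  res[is.na(res)] <- NaN
  res
}
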