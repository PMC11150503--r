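# Serialization: plain-text CSV/JSON round trips for every pipeline artifact.
# Integers and ids round-trip exactly; reals to full double precision.

#' Write / read an arena as JSON
#'
#' @param arena a `hex_arena`.
#' @param path file path.
#' @return `read_arena` returns a `hex_arena` equal to the one written
#'   (graph and adjacency rebuilt from the edge list).
#' @export
write_arena <- function(arena, path) {
  stopifnot(inherits(arena, "hex_arena"))
  obj <- list(width_mm = arena$width_mm, height_mm = arena$height_mm,
              edge_mm = arena$edge_mm,
              nodes = arena$nodes,
              edges = unname(arena$edges),
              faces = unname(arena$faces),
              nest_node = arena$nest_node,
              active_nodes = arena$active_nodes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed arena JSON '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("width_mm", "height_mm", "edge_mm", "nodes", "edges", "faces",
              "nest_node"))
    if (is.null(obj[[f]])) stop("arena JSON missing field '", f, "'")
  edges <- matrix(as.integer(obj$edges), ncol = 2)
  nodes <- as.data.frame(obj$nodes)
  structure(list(
    width_mm = obj$width_mm, height_mm = obj$height_mm,
    edge_mm = obj$edge_mm,
    nodes = nodes, edges = edges,
    faces = matrix(as.integer(obj$faces), ncol = 6),
    face_centers = NULL,
    nest_node = as.integer(obj$nest_node),
    active_nodes = as.integer(obj$active_nodes),
    graph = igraph::graph_from_edgelist(edges, directed = FALSE),
    adj = .adjacency_list(edges, nrow(nodes))
  ), class = "hex_arena")
}

#' Write / read track and event tables as CSV
#'
#' Track CSV columns: `frame, ant_id, node_id, x_mm, y_mm`; event CSV
#' columns: `time_s, kind, ant_id, node_id`.
#'
#' @param tracks,events data frames as produced by [simulate_trial()].
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "ant_id", "node_id", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("malformed track CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  df
}

#' @rdname write_tracks
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "kind", "ant_id", "node_id")
  if (!all(need %in% names(df)))
    stop("malformed event CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  df
}

#' Write / read an occupancy matrix (sparse long CSV + JSON sidecar)
#'
#' The CSV lists the occupied cells as `frame,node_id`; the sidecar JSON
#' (`<path>.json`) stores the frame count, frame rate and node order so the
#' dense matrix round-trips exactly.
#'
#' @param occupancy an `occupancy_matrix`.
#' @param path CSV file path (sidecar written next to it).
#' @export
write_occupancy <- function(occupancy, path) {
  stopifnot(inherits(occupancy, "occupancy_matrix"))
  w <- which(occupancy$values == 1L, arr.ind = TRUE)
  df <- data.frame(frame = w[, 1] - 1L,
                   node_id = occupancy$node_ids[w[, 2]])
  df <- df[order(df$frame, df$node_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_frames = nrow(occupancy$values),
                            frame_rate_hz = occupancy$frame_rate_hz,
                            node_ids = occupancy$node_ids),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("frame", "node_id") %in% names(df)))
    stop("malformed occupancy CSV '", path, "'")
  vals <- matrix(0L, nrow = meta$n_frames, ncol = length(meta$node_ids))
  if (nrow(df))
    vals[cbind(df$frame + 1L, match(df$node_id, meta$node_ids))] <- 1L
  structure(list(values = vals, node_ids = as.integer(meta$node_ids),
                 frame_rate_hz = meta$frame_rate_hz),
            class = "occupancy_matrix")
}

#' Write / read an MI matrix (dense CSV with node-id header) or series
#'
#' @param mi an `mi_matrix` or `mi_series`.
#' @param path file path.
#' @export
write_mi_matrix <- function(mi, path) {
  stopifnot(inherits(mi, "mi_matrix"))
  m <- mi$values
  dimnames(m) <- list(mi$node_ids, mi$node_ids)
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  structure(list(values = unname(m),
                 node_ids = as.integer(rownames(m)),
                 window_s = c(NA_real_, NA_real_), base = 2),
            class = "mi_matrix")
}

#' @rdname write_mi_matrix
#' @export
write_mi_series <- function(mi, path) {
  utils::write.csv(data.frame(center_s = mi$center_s,
                              avg_mi_bits = mi$avg_mi),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("center_s", "avg_mi_bits") %in% names(df)))
    stop("malformed MI series CSV '", path, "'")
  out <- data.frame(center_s = df$center_s, avg_mi = df$avg_mi_bits)
  class(out) <- c("mi_series", "data.frame")
  out
}

#' Write / read a replica model as JSON
#'
#' Couplings are stored as sparse `[i, j, value]` triplets (upper triangle);
#' the round trip is exact to double precision.
#'
#' @param model an `ant_replica`.
#' @param path file path.
#' @export
write_replica <- function(model, path) {
  stopifnot(inherits(model, "ant_replica"))
  ut <- which(upper.tri(model$J) & model$J != 0, arr.ind = TRUE)
  obj <- list(beta = model$beta,
              node_ids = model$node_ids,
              h = model$h,
              J = if (nrow(ut)) cbind(ut[, 1], ut[, 2],
                                      model$J[ut]) else matrix(0, 0, 3),
              is_null = model$is_null,
              fit_meta = model$fit_meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_replica
#' @export
read_replica <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed model JSON '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("beta", "node_ids", "h", "is_null"))
    if (is.null(obj[[f]])) stop("model JSON missing field '", f, "'")
  n <- length(obj$h)
  J <- matrix(0, n, n)
  trip <- obj$J
  if (length(trip)) {
    trip <- matrix(as.numeric(trip), ncol = 3)
    if (nrow(trip)) {
      J[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
      J[cbind(trip[, 2], trip[, 1])] <- trip[, 3]
    }
  }
  fm <- as.list(obj$fit_meta)
  .new_replica(obj$h, J, obj$beta, obj$node_ids, isTRUE(obj$is_null), fm)
}

#' Write / read detection results as CSV
#'
#' Columns: `realization, model, scenario, time_sweeps, censored`.
#'
#' @param result a `detection_result`.
#' @param path file path.
#' @export
write_detection <- function(result, path) {
  stopifnot(inherits(result, "detection_result"))
  df <- data.frame(realization = seq_along(result$times),
                   model = result$model_desc,
                   scenario = result$scenario_desc,
                   time_sweeps = result$times,
                   censored = result$censored)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(max_sweeps = result$max_sweeps,
                            metric = result$metric),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_detection
#' @export
read_detection <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("realization", "time_sweeps", "censored") %in% names(df)))
    stop("malformed detection CSV '", path, "'")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(times = as.integer(df$time_sweeps),
                 censored = as.logical(df$censored),
                 max_sweeps = as.integer(meta$max_sweeps),
                 foods = NULL, metric = meta$metric,
                 model_desc = as.character(df$model[1]),
                 scenario_desc = as.character(df$scenario[1])),
            class = "detection_result")
}
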