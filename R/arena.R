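#' Reference constants of the experimental foraging system
#'
#' Printed geometric and protocol constants of the laboratory system the
#' package emulates: a 2 x 2 m Teflon honeycomb arena of 5 cm channels
#' (572 hexagons; 1192 ternary Y-maze crossings, 1240 nodes counting the
#' peripheral binary ones), split into two 2 x 1 m halves per colony
#' (286 hexagons, 596 interior crossings, 620 occupancy nodes), trials of
#' 3 h recorded at 2 Hz with colonies of about 750 *Aphaenogaster senilis*
#' workers and 12 food items per trial.
#'
#' The half-arena node counts are stored for ingesting externally produced
#' data sets; a clean honeycomb cut yields a different peripheral-node tally,
#' so [build_arena()] is validated by internal consistency (Euler relation,
#' degree structure) rather than against these integers.
#'
#' @format A named list with elements `full`, `half` (each with `hexagons`,
#'   `y_nodes`, `nodes`), `colony_size`, `duration_s`, `frame_rate_hz`,
#'   `food_items`.
#' @export
colony_constants <- list(
  full = list(hexagons = 572L, y_nodes = 1192L, nodes = 1240L),
  half = list(hexagons = 286L, y_nodes = 596L, nodes = 620L),
  colony_size = 750L,
  duration_s = 10800,
  frame_rate_hz = 2,
  food_items = 12L
)

#' Base-10 logarithm of the occupancy state-space size
#'
#' A system of `n_nodes` binary occupancy variables can take `2^n_nodes`
#' configurations; this returns `n_nodes * log10(2)`, the order of magnitude
#' of that state space (e.g. 620 nodes span about `10^186` states).
#'
#' @param n_nodes number of binary occupancy nodes.
#' @return `n_nodes * log10(2)`.
#' @export
state_space_log10 <- function(n_nodes) n_nodes * log10(2)

# Internal lattice units: x in multiples of w/2 (w = sqrt(3)*edge is the
# hexagon width), y in multiples of edge/2. All pointy-top hexagon vertices
# fall on integer (ux, uy) pairs, which makes vertex de-duplication exact.
.hex_vertex_offsets <- matrix(
  c(1, 1, 0, 2, -1, 1, -1, -1, 0, -2, 1, -1),
  ncol = 2, byrow = TRUE
)

#' Build a hexagonal channel arena
#'
#' Tiles a rectangular box with the maximal number of whole pointy-top
#' regular hexagons of edge `edge_mm`, rows offset by half a hexagon width
#' and all rows the same length. Every hexagon vertex is a decision node;
#' every hexagon side is a channel of length `edge_mm`. With the
#' experimental dimensions (2000 x 2000 mm box, 50 mm edges) the tiling has
#' 572 faces, and 286 for the 2000 x 1000 mm half explored by one colony.
#'
#' @param width_mm,height_mm bounding box of the arena, in mm.
#' @param edge_mm hexagon edge (channel) length in mm, default 50.
#' @param nest_xy optional length-2 vector: the nest connects to the arena at
#'   the node nearest this point. Default is the midpoint of the lower edge.
#' @return An object of class `hex_arena`: a list with `nodes` (data frame
#'   `id`, `x`, `y`, `degree`, `peripheral`), `edges` (two-column integer
#'   matrix of node ids), `faces` (n x 6 integer matrix of vertex ids, in
#'   cyclic order), `face_centers` (data frame `x`, `y`), `nest_node`,
#'   `active_nodes`, the box dimensions, and an igraph channel graph.
#' @examples
#' a <- build_arena(900, 700, 50)
#' nrow(a$faces)
#' @export
build_arena <- function(width_mm, height_mm, edge_mm = 50, nest_xy = NULL) {
  stopifnot(width_mm > 0, height_mm > 0, edge_mm > 0)
  w <- sqrt(3) * edge_mm                   # hexagon width (flat extent)
  n_cols <- floor((width_mm - w / 2) / w)
  n_rows <- if (height_mm < 2 * edge_mm) 0L else
    floor((height_mm - 2 * edge_mm) / (1.5 * edge_mm)) + 1L
  if (n_cols < 1L || n_rows < 1L)
    stop("empty tiling: box ", width_mm, " x ", height_mm,
         " mm cannot hold one whole hexagon of edge ", edge_mm, " mm")

  rc <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  # centers in lattice units (x: w/2, y: edge/2)
  cx_u <- 2L * rc$col + 1L + rc$row %% 2L
  cy_u <- 2L + 3L * rc$row
  n_faces <- nrow(rc)

  off <- .hex_vertex_offsets
  vx <- outer(cx_u, off[, 1], `+`)         # n_faces x 6
  vy <- outer(cy_u, off[, 2], `+`)
  key <- paste(vx, vy, sep = ",")
  ord <- order(as.vector(vy), as.vector(vx))
  ukey <- unique(key[ord])
  node_id <- match(key, ukey)              # n_faces*6 vector, column-major
  faces <- matrix(node_id, nrow = n_faces, ncol = 6)

  uxy <- do.call(rbind, strsplit(ukey, ",", fixed = TRUE))
  ux <- as.integer(uxy[, 1]); uy <- as.integer(uxy[, 2])
  nodes <- data.frame(
    id = seq_along(ukey),
    x = ux * w / 2,
    y = uy * edge_mm / 2
  )

  # edges: consecutive vertices of each face, deduplicated
  e_from <- as.vector(faces)
  e_to <- as.vector(faces[, c(2:6, 1)])
  lo <- pmin(e_from, e_to); hi <- pmax(e_from, e_to)
  edges <- unique(cbind(lo, hi))
  dimnames(edges) <- NULL

  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(nodes))
  nodes$degree <- deg
  nodes$peripheral <- deg <= 2L

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)

  if (is.null(nest_xy)) nest_xy <- c(width_mm / 2, 0)
  nest_node <- which.min((nodes$x - nest_xy[1])^2 + (nodes$y - nest_xy[2])^2)

  arena <- structure(list(
    width_mm = width_mm, height_mm = height_mm, edge_mm = edge_mm,
    nodes = nodes, edges = edges, faces = faces,
    face_centers = data.frame(x = cx_u * w / 2, y = cy_u * edge_mm / 2),
    nest_node = as.integer(nest_node),
    active_nodes = nodes$id,
    graph = g,
    adj = .adjacency_list(edges, nrow(nodes))
  ), class = "hex_arena")
  arena
}

.adjacency_list <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  fr <- c(edges[, 1], edges[, 2]); to <- c(edges[, 2], edges[, 1])
  o <- order(fr)
  split_to <- split(to[o], fr[o])
  adj[as.integer(names(split_to))] <- lapply(split_to, as.integer)
  adj
}

#' @export
print.hex_arena <- function(x, ...) {
  cat("Hexagonal channel arena: ", x$width_mm, " x ", x$height_mm,
      " mm, edge ", x$edge_mm, " mm\n", sep = "")
  cat("  faces: ", nrow(x$faces),
      "  nodes: ", nrow(x$nodes),
      " (", sum(!x$nodes$peripheral), " interior Y-nodes)",
      "  channels: ", nrow(x$edges), "\n", sep = "")
  cat("  nest node: ", x$nest_node, " at (",
      round(x$nodes$x[x$nest_node], 1), ", ",
      round(x$nodes$y[x$nest_node], 1), ") mm\n", sep = "")
  invisible(x)
}

#' @export
plot.hex_arena <- function(x, highlight = integer(), ...) {
  plot(x$nodes$x, x$nodes$y, asp = 1, pch = 16, cex = 0.3,
       xlab = "x (mm)", ylab = "y (mm)", ...)
  segments(x$nodes$x[x$edges[, 1]], x$nodes$y[x$edges[, 1]],
           x$nodes$x[x$edges[, 2]], x$nodes$y[x$edges[, 2]],
           col = "grey70")
  if (length(highlight))
    points(x$nodes$x[highlight], x$nodes$y[highlight], col = "red", pch = 16)
  points(x$nodes$x[x$nest_node], x$nodes$y[x$nest_node],
         pch = 17, col = "purple", cex = 1.2)
  invisible(x)
}

#' Channel-adjacent neighbours of a node
#'
#' @param arena a `hex_arena`.
#' @param node_id a node id present in the arena.
#' @return Integer vector of adjacent node ids (3 for interior Y-maze
#'   crossings, at most 2 for peripheral nodes).
#' @export
node_neighbors <- function(arena, node_id) {
  stopifnot(inherits(arena, "hex_arena"))
  if (length(node_id) != 1L || is.na(node_id) ||
      node_id < 1L || node_id > nrow(arena$nodes))
    stop("unknown node id: ", node_id)
  nb <- arena$adj[[node_id]]
  if (is.null(nb)) integer() else nb
}

#' Euclidean and graph distances between two arena nodes
#'
#' @param arena a `hex_arena`.
#' @param a,b node ids.
#' @return A named list `euclidean_mm` (straight-line distance of the node
#'   coordinates) and `graph_hops` (minimal number of channels between the
#'   nodes; `Inf` if disconnected).
#' @export
node_distances <- function(arena, a, b) {
  stopifnot(inherits(arena, "hex_arena"))
  n <- nrow(arena$nodes)
  if (any(c(a, b) < 1L) || any(c(a, b) > n)) stop("unknown node id")
  eu <- sqrt((arena$nodes$x[a] - arena$nodes$x[b])^2 +
               (arena$nodes$y[a] - arena$nodes$y[b])^2)
  hops <- igraph::distances(arena$graph, v = a, to = b)[1, 1]
  list(euclidean_mm = eu, graph_hops = hops)
}

.face_dist_to_nest <- function(arena) {
  nx <- arena$nodes$x[arena$nest_node]; ny <- arena$nodes$y[arena$nest_node]
  sqrt((arena$face_centers$x - nx)^2 + (arena$face_centers$y - ny)^2)
}

# the two default deterministic food faces: vertex-disjoint faces whose
# centers are nearest target_mm from the nest, one on each side of the
# nest's vertical axis when possible
.default_food_faces <- function(arena, target_mm = 500) {
  d <- .face_dist_to_nest(arena)
  nx <- arena$nodes$x[arena$nest_node]
  score <- abs(d - target_mm)
  left <- which(arena$face_centers$x < nx)
  right <- which(arena$face_centers$x >= nx)
  pick <- integer()
  if (length(left) && length(right)) {
    f1 <- left[which.min(score[left])]
    cand <- right[order(score[right])]
    disj <- cand[vapply(cand, function(f)
      !any(arena$faces[f, ] %in% arena$faces[f1, ]), logical(1))]
    if (length(disj)) pick <- c(f1, disj[1])
  }
  if (length(pick) < 2L) {
    ord <- order(score)
    f1 <- ord[1]
    disj <- ord[-1][vapply(ord[-1], function(f)
      !any(arena$faces[f, ] %in% arena$faces[f1, ]), logical(1))]
    if (!length(disj)) stop("arena too small for two vertex-disjoint faces")
    pick <- c(f1, disj[1])
  }
  sort(pick)
}

.sample_disjoint_faces <- function(arena, eligible) {
  if (length(eligible) < 2L)
    stop("infeasible scenario: fewer than two eligible faces")
  for (k in 1:1000) {
    f <- sample(eligible, 2L)
    if (!any(arena$faces[f[1], ] %in% arena$faces[f[2], ]))
      return(sort(f))
  }
  stop("infeasible scenario: no vertex-disjoint face pair among eligible faces")
}

#' Place a food scenario on the arena
#'
#' Food is placed on the 12 vertices of two vertex-disjoint hexagon faces
#' (one item per node by default). Four generating conditions are supported:
#' `deterministic` (the same two faces every time; by default the faces whose
#' centers are nearest 500 mm from the nest, on symmetric sides),
#' `stochastic` (two faces drawn uniformly at random), `p_mixture` (the
#' deterministic faces with probability `p`, otherwise a stochastic draw),
#' `radial` (a stochastic draw restricted to faces whose center lies within
#' `R_mm` of the nest) and `no_food` (empty food set).
#'
#' @param arena a `hex_arena`.
#' @param condition one of `"deterministic"`, `"stochastic"`, `"no_food"`,
#'   `"p_mixture"`, `"radial"`.
#' @param seed integer seed; the same seed and arguments reproduce the
#'   scenario exactly.
#' @param p probability of the deterministic placement (`p_mixture` only).
#' @param R_mm radius around the nest eligible for food faces (`radial` only).
#' @param fixed_faces optional integer pair overriding the default
#'   deterministic faces.
#' @param items_per_node food items at each food node (default 1, so 12 in
#'   total).
#' @param det_target_mm nest-to-face-center distance targeted by the default
#'   deterministic placement (mm).
#' @return An object of class `food_scenario` with fields `food_nodes`,
#'   `faces`, `condition`, `p`, `R_mm`, `items_per_node`, `seed`.
#' @export
place_food <- function(arena, condition = c("deterministic", "stochastic",
                                            "no_food", "p_mixture", "radial"),
                       seed = 1L, p = NULL, R_mm = NULL, fixed_faces = NULL,
                       items_per_node = 1L, det_target_mm = 500) {
  stopifnot(inherits(arena, "hex_arena"))
  condition <- match.arg(condition)
  if (condition == "p_mixture") {
    if (is.null(p) || p < 0 || p > 1) stop("p_mixture requires p in [0, 1]")
  }
  if (condition == "radial") {
    if (is.null(R_mm) || R_mm <= 0) stop("radial requires R_mm > 0")
  }
  faces <- integer()
  if (condition != "no_food") {
    det_faces <- if (!is.null(fixed_faces)) sort(as.integer(fixed_faces)) else
      .default_food_faces(arena, det_target_mm)
    faces <- local({
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
      switch(condition,
        deterministic = det_faces,
        stochastic = .sample_disjoint_faces(arena, seq_len(nrow(arena$faces))),
        p_mixture = if (stats::runif(1) < p) det_faces else
          .sample_disjoint_faces(arena, seq_len(nrow(arena$faces))),
        radial = {
          d <- .face_dist_to_nest(arena)
          elig <- which(d <= R_mm)
          .sample_disjoint_faces(arena, elig)
        })
    })
  }
  food_nodes <- if (length(faces)) sort(unique(as.vector(arena$faces[faces, ])))
    else integer()
  structure(list(
    food_nodes = as.integer(food_nodes),
    faces = as.integer(faces),
    condition = condition,
    p = p, R_mm = R_mm,
    items_per_node = as.integer(items_per_node),
    seed = as.integer(seed)
  ), class = "food_scenario")
}

#' @export
print.food_scenario <- function(x, ...) {
  cat("Food scenario (", x$condition, "): ", length(x$food_nodes),
      " food nodes on faces {", paste(x$faces, collapse = ", "), "}",
      if (!is.null(x$p)) paste0(", p = ", x$p),
      if (!is.null(x$R_mm)) paste0(", R = ", x$R_mm, " mm"),
      "\n", sep = "")
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
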