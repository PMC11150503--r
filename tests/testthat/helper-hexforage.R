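# Shared fixtures, built in code. The "test arena" is a small honeycomb used
# where geometry is all that matters; the "half arena" (2000 x 1000 mm, the
# experimental unit explored by one colony) is used for generator-scale
# checks and is cached across test files.

test_arena <- function() build_arena(500, 400, 50)

.fixture_env <- new.env(parent = emptyenv())

half_arena <- function() {
  if (is.null(.fixture_env$half)) .fixture_env$half <- build_arena(2000, 1000, 50)
  .fixture_env$half
}

# wrap a plain 0/1 matrix as an occupancy_matrix
as_occ <- function(m, node_ids = seq_len(ncol(m)), frame_rate_hz = 2) {
  structure(list(values = m, node_ids = as.integer(node_ids),
                 frame_rate_hz = frame_rate_hz),
            class = "occupancy_matrix")
}

# short-trial generator configuration for cheap dynamic checks
quick_config <- function(...) sim_config(duration_s = 1800, ...)

# pooled exploitation-phase occupancy of a simulated series
exploitation_occupancy <- function(arena, series, max_frames = 2500,
                                   n_frames = 21600) {
  frames <- lapply(series, function(tr) {
    occ <- binarize_tracks(tr$tracks, arena, n_frames = n_frames)
    tp <- transition_points(tr$events, duration_s = n_frames / 2)
    lab <- phase_of_frames(n_frames, 2, tp)
    occ$values[lab == "exploitation", , drop = FALSE]
  })
  pooled <- do.call(rbind, frames)
  keep <- hexforage:::.subsample_rows(nrow(pooled), max_frames)
  as_occ(pooled[keep, , drop = FALSE], arena$active_nodes)
}

# replicas of both conditions fitted on generator data at the half-arena
# study scale; expensive, so built once and reused by the acceptance tests
colony_replicas <- function() {
  if (!is.null(.fixture_env$replicas)) return(.fixture_env$replicas)
  arena <- half_arena()
  cfg <- sim_config()
  pairs2 <- adjacency_pairs(arena, 2)
  fit_cond <- function(cond, seed) {
    ser <- simulate_series(arena, cond, 3, cfg, seed = seed)
    occ <- exploitation_occupancy(arena, ser)
    full <- fit_replica(occ, "pseudolikelihood", pairs = pairs2)
    null <- fit_replica(occ, "independent")
    null$beta <- calibrate_beta(null, mean(sample_replica(full, 3000, seed = 8)),
                                seed = 9)
    list(occ = occ, full = full, null = null, series = ser)
  }
  .fixture_env$replicas <- list(arena = arena,
                                det = fit_cond("deterministic", 101),
                                sto = fit_cond("stochastic", 202))
  .fixture_env$replicas
}
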