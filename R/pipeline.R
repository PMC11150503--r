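#' Declarative configuration of the full analysis pipeline
#'
#' Collects every stage's parameters with full defaulting. The master seed
#' fans out deterministically to per-stage seeds, so two runs with an
#' identical configuration produce identical artifacts.
#'
#' @param arena list: `width_mm`, `height_mm`, `edge_mm`.
#' @param generator a [sim_config()] or list of overrides for it.
#' @param n_trials trials per condition.
#' @param features list: `snap_radius_mm`, `body_length_mm`.
#' @param mi list: `window_s`, `step_s`, `base`.
#' @param fit list: `lambda`, `pseudocount`, `max_train_frames` (exploitation
#'   frames kept for training, subsampled evenly when more are available),
#'   `max_hops` (coupling support: node pairs within this channel-graph
#'   distance; `NULL` fits all pairs).
#' @param efficiency list: `n_realizations`, `max_sweeps`, `p_grid`,
#'   `R_grid`, `null_beta` (`"calibrate"` or a number).
#' @param seed master seed.
#' @param out_dir artifact directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(arena = list(width_mm = 2000, height_mm = 1000,
                                         edge_mm = 50),
                            generator = sim_config(),
                            n_trials = 3L,
                            features = list(snap_radius_mm = 25,
                                            body_length_mm = 10),
                            mi = list(window_s = 900, step_s = 150, base = 2),
                            fit = list(lambda = 0.01, pseudocount = 1,
                                       max_train_frames = 3000L,
                                       max_hops = 2),
                            efficiency = list(n_realizations = 200L,
                                              max_sweeps = 10000L,
                                              p_grid = c(0, 0.5, 1),
                                              R_grid = c(250, 550, 750),
                                              null_beta = "calibrate"),
                            conditions = c("deterministic", "stochastic"),
                            seed = 1L,
                            out_dir = "hexforage_run") {
  if (!inherits(generator, "sim_config"))
    generator <- do.call(sim_config, generator)
  stopifnot(all(conditions %in% c("deterministic", "stochastic", "no_food")))
  cfg <- list(arena = arena, generator = generator,
              n_trials = as.integer(n_trials),
              features = features, mi = mi, fit = fit,
              efficiency = efficiency, conditions = conditions,
              seed = as.integer(seed),
              out_dir = out_dir)
  stopifnot(cfg$n_trials >= 1L, cfg$features$snap_radius_mm > 0,
            cfg$features$body_length_mm > 0, cfg$mi$step_s > 0,
            cfg$fit$lambda >= 0, cfg$efficiency$n_realizations >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$generator <- unclass(cfg$generator)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config YAML '", path,
                                           "': ", conditionMessage(e)))
  do.call(pipeline_config, obj)
}

.stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

# even subsample of row indices down to at most n_max
.subsample_rows <- function(n, n_max) {
  if (n <= n_max) seq_len(n)
  else unique(as.integer(round(seq(1, n, length.out = n_max))))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (both conditions) -> binarize -> activity features ->
#' mutual information -> replica fits (full and null per condition) ->
#' in-silico efficiency suites, writing every artifact plus a manifest with
#' seeds, parameters and file hashes to the output directory. Runs with
#' only a no-food condition skip the efficiency stage with a log notice.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  stage_seeds <- as.list(sample.int(.Machine$integer.max, 8))
  names(stage_seeds) <- c("sim_det", "sim_sto", "fit", "cal", "eff_trained",
                          "eff_p", "eff_R", "misc")
  .restore_rng(old)

  .stage_log("arena", "building ", config$arena$width_mm, " x ",
             config$arena$height_mm, " mm arena")
  arena <- build_arena(config$arena$width_mm, config$arena$height_mm,
                       config$arena$edge_mm)
  write_arena(arena, file.path(config$out_dir, "arena.json"))

  conditions <- config$conditions
  occs <- list(); models <- list(); nulls <- list()
  for (cond in conditions) {
    .stage_log("simulate", cond, " condition, ", config$n_trials, " trials")
    cond_seed <- stage_seeds[[c(deterministic = "sim_det",
                                stochastic = "sim_sto",
                                no_food = "misc")[cond]]]
    series <- if (cond == "no_food") {
      scen <- place_food(arena, "no_food")
      lapply(seq_len(config$n_trials), function(i)
        simulate_trial(arena, scen, config$generator,
                       seed = cond_seed %% 1000000000L + i))
    } else simulate_series(arena, cond, config$n_trials, config$generator,
                           seed = cond_seed)
    expl_frames <- list()
    for (i in seq_along(series)) {
      tr <- series[[i]]
      tag <- paste0(substr(cond, 1, 3), i)
      write_tracks(tr$tracks, file.path(config$out_dir,
                                        paste0("tracks_", tag, ".csv")))
      write_events(tr$events, file.path(config$out_dir,
                                        paste0("events_", tag, ".csv")))
      occ <- binarize_tracks(tr$tracks, arena,
                             config$features$snap_radius_mm,
                             n_frames = round(config$generator$duration_s *
                                                config$generator$frame_rate_hz),
                             frame_rate_hz = config$generator$frame_rate_hz)
      tp <- transition_points(tr$events,
                              duration_s = config$generator$duration_s)
      lab <- phase_of_frames(nrow(occ$values), occ$frame_rate_hz, tp)
      expl_frames[[i]] <- occ$values[lab == "exploitation", , drop = FALSE]
      if (i == 1L) {
        .stage_log("features", cond, ": occupancy, activity, MI series")
        write_occupancy(occ, file.path(config$out_dir,
                                       paste0("occupancy_", tag, ".csv")))
        act <- activity_series(tr$tracks, n_frames = nrow(occ$values))
        utils::write.csv(act, file.path(config$out_dir,
                                        paste0("activity_", tag, ".csv")),
                         row.names = FALSE)
        mi_s <- windowed_average_mi(occ, config$mi$window_s, config$mi$step_s,
                                    config$mi$base)
        write_mi_series(mi_s, file.path(config$out_dir,
                                        paste0("mi_series_", tag, ".csv")))
      }
    }
    pooled <- do.call(rbind, expl_frames)
    if (is.null(pooled) || nrow(pooled) < 2L) {
      .stage_log("fit", "skipping ", cond, ": no exploitation frames")
      next
    }
    keep <- .subsample_rows(nrow(pooled), config$fit$max_train_frames)
    occ_train <- structure(list(values = pooled[keep, , drop = FALSE],
                                node_ids = arena$active_nodes,
                                frame_rate_hz =
                                  config$generator$frame_rate_hz),
                           class = "occupancy_matrix")
    .stage_log("fit", cond, ": pseudolikelihood replica on ",
               length(keep), " exploitation frames")
    pr <- if (is.null(config$fit$max_hops)) NULL else
      adjacency_pairs(arena, config$fit$max_hops)
    models[[cond]] <- fit_replica(occ_train, "pseudolikelihood",
                                  lambda = config$fit$lambda,
                                  pseudocount = config$fit$pseudocount,
                                  pairs = pr)
    nulls[[cond]] <- fit_replica(occ_train, "independent",
                                 pseudocount = config$fit$pseudocount)
    write_replica(models[[cond]],
                  file.path(config$out_dir, paste0("replica_",
                                                   substr(cond, 1, 3),
                                                   ".json")))
    write_replica(nulls[[cond]],
                  file.path(config$out_dir, paste0("replica_null_",
                                                   substr(cond, 1, 3),
                                                   ".json")))
    occs[[cond]] <- occ_train
  }

  suites <- list()
  if (length(models) == 2L) {
    nb <- config$efficiency$null_beta
    if (identical(nb, "calibrate")) {
      .stage_log("calibrate", "matching null replicas' occupancy")
      for (cond in conditions) {
        target <- mean(sample_replica(models[[cond]], 1500,
                                      seed = stage_seeds$cal))
        nulls[[cond]]$beta <- calibrate_beta(nulls[[cond]], target,
                                             seed = stage_seeds$cal)
      }
    } else {
      for (cond in conditions) nulls[[cond]]$beta <- nb
    }
    .stage_log("efficiency", "trained-condition suite")
    suites$trained <- scenario_suite(
      models$deterministic, models$stochastic,
      nulls$deterministic, nulls$stochastic, arena, "trained",
      n_realizations = config$efficiency$n_realizations,
      max_sweeps = config$efficiency$max_sweeps,
      seed = stage_seeds$eff_trained)
    .stage_log("efficiency", "p-mixture suite")
    suites$p_grid <- scenario_suite(
      models$deterministic, models$stochastic,
      nulls$deterministic, nulls$stochastic, arena, "p_grid",
      n_realizations = config$efficiency$n_realizations,
      max_sweeps = config$efficiency$max_sweeps,
      p_grid = config$efficiency$p_grid,
      seed = stage_seeds$eff_p)
    for (nm in names(suites))
      for (cell in names(suites[[nm]]$cells))
        write_detection(suites[[nm]]$cells[[cell]],
                        file.path(config$out_dir,
                                  paste0("detection_", nm, "_",
                                         gsub("[@=]", "_", cell), ".csv")))
  } else {
    .stage_log("efficiency",
               "skipped: needs replicas for both food conditions")
  }

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("hexforage")),
    seed = config$seed,
    stage_seeds = stage_seeds,
    parameters = list(arena = config$arena, n_trials = config$n_trials,
                      features = config$features, mi = config$mi,
                      fit = config$fit, efficiency = config$efficiency),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log("done", length(files), " artifacts in ", config$out_dir)
  invisible(manifest)
}
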