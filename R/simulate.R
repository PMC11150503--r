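#' Configuration of the synthetic colony generator
#'
#' Bundles the behavioural parameters of the agent-based foraging generator.
#' Defaults reproduce the experimental protocol scales: 3-hour trials
#' (10800 s) sampled at 2 Hz, colonies of 750 workers, group recruitment of
#' 3-5 nestmates per successful forager, a 5-10 fold rise in arena
#' population after the first food discovery, and relaxation towards 5-10
#' resident ants with superimposed departure bursts once the last item is
#' collected.
#'
#' @param duration_s trial length in seconds.
#' @param frame_rate_hz camera frame rate (frames per second).
#' @param colony_size number of workers available in the nest.
#' @param scout_emission_rate nest exits per second during exploration.
#' @param recruit_count_range integer interval of nestmates recruited per
#'   collected item.
#' @param recruit_speedup multiplier on the emission rate after the first
#'   food discovery; together with the recruit flux it sets the 5-10 fold
#'   population rise.
#' @param food_handling_s seconds an ant spends at a food node picking up an
#'   item before heading home.
#' @param food_detect_prob probability that a searching scout stepping on a
#'   food node notices the item on that visit; recruits led to the patch
#'   always collect.
#' @param relax_floor target range of resident ants after the last item is
#'   collected.
#' @param burst_rate rate (events per second) of departure bursts during
#'   relaxation.
#' @param burst_size ants leaving the nest per burst.
#' @param wave_rate rate (events per second) of group departure waves during
#'   exploration and exploitation: a leader and followers leave together and
#'   wander as a train, the collective movement mode that generates positive
#'   same-frame co-occupancy of nearby nodes away from the trails.
#' @param wave_size_range integer interval of ants per wave (leader
#'   included).
#' @param step_frames frames per node-to-node move (4 frames = 2 s per 5 cm
#'   channel, about 2.5 cm/s).
#' @param persistence_weight log-weight bonus for not reversing direction.
#' @param trail_weight log-weight per unit of trail score on a candidate
#'   node (the recruitment-trail coupling).
#' @param thigmotaxis_weight log-weight bonus for peripheral (boundary)
#'   candidate nodes.
#' @param trail_decay exponential decay rate of trail scores, per second.
#' @param trail_persistence logical; `TRUE` carries (decayed) trail scores
#'   across the trials of a series (deterministic condition, arena never
#'   cleaned), `FALSE` resets them (stochastic condition, arena cleaned).
#' @param trail_cap cap on the effective trail score entering the move
#'   choice, for numerical stability of the softmax.
#' @param mean_excursion_s mean time a scout stays out before heading home.
#' @param recruit_noise probability a travelling recruit takes a random
#'   neighbour instead of the next node towards its target.
#' @param intertrial_retain fraction of the trail score retained between
#'   consecutive trials when `trail_persistence` is `TRUE`.
#' @param experienced_frac fraction of scouts that are experienced foragers
#'   when remembered food locations are available (deterministic series,
#'   trials after the first): they head straight back to a remembered food
#'   node instead of searching — forager site fidelity, the individual-level
#'   carrier of colony preconditioning.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 10800,
                       frame_rate_hz = 2,
                       colony_size = 750L,
                       scout_emission_rate = 0.0075,
                       recruit_count_range = c(3L, 5L),
                       recruit_speedup = 5,
                       relax_floor = c(5, 10),
                       food_handling_s = 300,
                       food_detect_prob = 0.05,
                       burst_rate = 1 / 900,
                       burst_size = 4L,
                       wave_rate = 1 / 230,
                       wave_size_range = c(3L, 5L),
                       step_frames = 4L,
                       persistence_weight = 0.6,
                       trail_weight = 1.0,
                       thigmotaxis_weight = 0.6,
                       trail_decay = 1 / 7200,
                       trail_persistence = TRUE,
                       trail_cap = 8,
                       mean_excursion_s = 400,
                       recruit_noise = 0.1,
                       intertrial_retain = 0.5,
                       experienced_frac = 0.3) {
  cfg <- list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
              colony_size = as.integer(colony_size),
              scout_emission_rate = scout_emission_rate,
              recruit_count_range = as.integer(recruit_count_range),
              recruit_speedup = recruit_speedup,
              relax_floor = relax_floor,
              food_handling_s = food_handling_s,
              food_detect_prob = food_detect_prob,
              burst_rate = burst_rate, burst_size = as.integer(burst_size),
              wave_rate = wave_rate,
              wave_size_range = as.integer(wave_size_range),
              step_frames = as.integer(step_frames),
              persistence_weight = persistence_weight,
              trail_weight = trail_weight,
              thigmotaxis_weight = thigmotaxis_weight,
              trail_decay = trail_decay,
              trail_persistence = isTRUE(trail_persistence),
              trail_cap = trail_cap,
              mean_excursion_s = mean_excursion_s,
              recruit_noise = recruit_noise,
              intertrial_retain = intertrial_retain,
              experienced_frac = experienced_frac)
  stopifnot(cfg$duration_s > 0, cfg$frame_rate_hz > 0,
            cfg$colony_size >= 1L,
            length(cfg$recruit_count_range) == 2L,
            cfg$recruit_count_range[1] >= 1L,
            cfg$recruit_count_range[2] <= cfg$colony_size,
            cfg$recruit_count_range[1] <= cfg$recruit_count_range[2],
            cfg$scout_emission_rate >= 0, cfg$recruit_speedup >= 0,
            cfg$burst_rate >= 0, cfg$wave_rate >= 0,
            length(cfg$wave_size_range) == 2L, cfg$trail_decay >= 0,
            cfg$step_frames >= 1L, cfg$mean_excursion_s > 0,
            cfg$food_handling_s >= 0,
            cfg$food_detect_prob > 0, cfg$food_detect_prob <= 1,
            cfg$recruit_noise >= 0, cfg$recruit_noise <= 1,
            cfg$experienced_frac >= 0, cfg$experienced_frac <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# breadth-first parents: parent[v] is the neighbour of v one hop closer to
# root (0 for the root and for unreached nodes)
.bfs_parents <- function(adj, root, n) {
  parent <- integer(n)
  visited <- logical(n)
  queue <- integer(n)
  visited[root] <- TRUE
  queue[1] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  parent
}

#' Simulate one synthetic foraging trial
#'
#' Agent-based generator of a single trial on a hexagonal arena. Scouts leave
#' the nest at a Poisson rate and perform a correlated random walk over the
#' channel graph, choosing among the (at most three) adjacent nodes with a
#' softmax over direction persistence, trail score and a thigmotactic bonus.
#' A scout stepping on a food item triggers a `food_found` event, carries the
#' item back to the nest along the shortest path while reinforcing the trail,
#' and on arrival (`food_collected`) dispatches 3-5 recruits towards the
#' food patch. After the last item is collected the emission rate drops and
#' the arena population relaxes, with Poisson departure bursts superimposed.
#' The first `food_found` and last `food_collected` times bound the
#' exploration / exploitation / relaxation phases.
#'
#' @param arena a `hex_arena`.
#' @param scenario a `food_scenario` placed on the same arena.
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param trail_init optional numeric vector (one score per arena node) of
#'   trail state carried in from a previous trial.
#' @param known_food optional integer vector of food-node ids remembered
#'   from a previous successful trial; a fraction `experienced_frac` of
#'   scouts then head straight to one of them.
#' @return A list of class `foraging_trial` with `tracks` (data frame
#'   `frame`, `ant_id`, `node_id`, `x_mm`, `y_mm`), `events` (data frame
#'   `time_s`, `kind`, `ant_id`, `node_id`), and `trail` (effective trail
#'   score per node at the end of the trial).
#' @export
simulate_trial <- function(arena, scenario, config = sim_config(), seed = 1L,
                           trail_init = NULL, known_food = NULL) {
  stopifnot(inherits(arena, "hex_arena"), inherits(scenario, "food_scenario"),
            inherits(config, "sim_config"))
  n_nodes <- nrow(arena$nodes)
  if (length(scenario$food_nodes) && max(scenario$food_nodes) > n_nodes)
    stop("scenario does not match arena: unknown food node id")
  if (config$scout_emission_rate == 0)
    warning("zero scout emission rate: trial will produce an empty track")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  fr <- config$frame_rate_hz
  T_frames <- as.integer(round(config$duration_s * fr))
  step <- config$step_frames
  decay <- config$trail_decay
  nest <- arena$nest_node
  adj <- arena$adj
  peripheral <- arena$nodes$peripheral
  parent_nest <- .bfs_parents(adj, nest, n_nodes)
  parent_to <- vector("list", n_nodes)      # BFS parents toward food targets

  items <- integer(n_nodes)
  items[scenario$food_nodes] <- scenario$items_per_node
  items_left <- sum(items)
  discovered <- logical(n_nodes)

  # trail stored in time-inflated units: effective(t) = raw * exp(-decay * t)
  raw_trail <- if (is.null(trail_init)) numeric(n_nodes) else {
    stopifnot(length(trail_init) == n_nodes)
    as.numeric(trail_init)
  }

  n_max <- max(4L * config$colony_size, 64L)
  node <- integer(n_max); prev <- integer(n_max)
  role <- integer(n_max)                    # 1 scout, 2 homing, 3 carrier, 4 recruit
  target <- integer(n_max)
  deadline <- integer(n_max)
  pred <- integer(n_max)                    # predecessor in a wave train
  wait_until <- integer(n_max)
  phase <- integer(n_max)
  next_id <- 1L
  active <- integer(0)                      # ids currently in arena
  pool <- config$colony_size

  ev_t <- numeric(0); ev_k <- character(0); ev_a <- integer(0); ev_n <- integer(0)
  push_event <- function(t, k, a, n) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_k[length(ev_k) + 1L] <<- k
    ev_a[length(ev_a) + 1L] <<- a
    ev_n[length(ev_n) + 1L] <<- n
  }

  tp1_seen <- FALSE
  # relaxation emission: target the relax_floor resident level net of the
  # expected burst inflow
  relax_rate <- max(0, mean(config$relax_floor) -
                      config$burst_rate * config$burst_size *
                      config$mean_excursion_s) / config$mean_excursion_s

  trk_ids <- vector("list", T_frames)
  trk_nodes <- vector("list", T_frames)

  pw <- config$persistence_weight
  tw <- config$trail_weight
  hw <- config$thigmotaxis_weight
  tc <- config$trail_cap
  noise <- config$recruit_noise
  rng_lo <- config$recruit_count_range[1]
  rng_hi <- config$recruit_count_range[2]

  emit <- function(f, n_new, new_role = 1L, new_target = 0L) {
    n_new <- min(n_new, pool, n_max - next_id + 1L)
    if (n_new <= 0L) return(invisible())
    for (k in seq_len(n_new)) {
      id <- next_id
      next_id <<- next_id + 1L
      node[id] <<- nest; prev[id] <<- 0L
      role[id] <<- new_role; target[id] <<- new_target
      deadline[id] <<- f +
        as.integer(stats::rexp(1, 1 / config$mean_excursion_s) * fr)
      phase[id] <<- f %% step
      active[length(active) + 1L] <<- id
      pool <<- pool - 1L
      push_event(f / fr, "exit_nest", id, nest)
    }
    invisible()
  }

  parents_toward <- function(tg) {
    if (is.null(parent_to[[tg]]))
      parent_to[[tg]] <<- .bfs_parents(adj, tg, n_nodes)
    parent_to[[tg]]
  }

  # experienced foragers: a fraction of freshly emitted solo scouts head
  # straight back to a remembered food node (site fidelity)
  mark_experienced <- function(first_new) {
    if (!length(known_food) || config$experienced_frac <= 0) return(invisible())
    for (id_new in seq.int(first_new, length.out = next_id - first_new)) {
      if (stats::runif(1) < config$experienced_frac) {
        role[id_new] <<- 4L
        target[id_new] <<- known_food[sample.int(length(known_food), 1L)]
      }
    }
    invisible()
  }

  # the nest opens at t = 0: release the steady-state exploration cohort
  # (solo scouts plus the wave-mode equivalent) at once so exploration
  # starts at its stationary activity level
  n0 <- as.integer(round((config$scout_emission_rate +
                            config$wave_rate * mean(config$wave_size_range)) *
                           config$mean_excursion_s))
  if (n0 > 0L) {
    first_new <- next_id
    emit(0L, n0)
    mark_experienced(first_new)
  }

  for (f in seq_len(T_frames) - 1L) {
    t_s <- f / fr
    # emission: exploration rate, boosted after TP1, relax rate after TP2
    rate <- if (!tp1_seen) config$scout_emission_rate
      else if (items_left > 0L) config$scout_emission_rate * config$recruit_speedup
      else relax_rate
    n_new <- stats::rpois(1, rate / fr)
    if (n_new > 0L) {
      first_new <- next_id
      emit(f, n_new)
      mark_experienced(first_new)
    }
    # group departure waves: trains of a leader plus followers; during
    # relaxation these are the departure bursts
    relaxing <- tp1_seen && items_left == 0L
    w_rate <- if (relaxing) config$burst_rate
      else if (tp1_seen) config$wave_rate * config$recruit_speedup
      else config$wave_rate
    if (w_rate > 0) {
      n_wave <- stats::rpois(1, w_rate / fr)
      for (wv in seq_len(n_wave)) {
        sz <- if (relaxing) config$burst_size else
          sample(config$wave_size_range[1]:config$wave_size_range[2], 1L)
        first_new <- next_id
        emit(f, sz)
        made <- next_id - first_new
        if (made >= 2L) for (m in 2:made) {
          pred[first_new + m - 1L] <- first_new + m - 2L
          role[first_new + m - 1L] <- 5L
        }
      }
    }

    if (length(active)) {
      due <- active[(f %% step) == phase[active]]
      if (length(due)) {
        ef <- exp(-decay * t_s)      # effective-trail factor at this time
        inf_w <- 1 / ef              # inflation for reinforcements now
        for (id in due) {
          if (f < wait_until[id]) next
          r <- role[id]
          if (r %in% c(1L, 5L) && f >= deadline[id]) { r <- 2L; role[id] <- 2L }
          if (r == 5L) {
            # wave follower: step into the spot its predecessor just left,
            # so the train occupies consecutive nodes in the same frame
            p <- pred[id]
            if (p > 0L && role[p] %in% c(1L, 5L)) {
              nxt <- prev[p]
              if (nxt == 0L) nxt <- node[id]
              prev[id] <- node[id]; node[id] <- nxt
            } else { r <- 1L; role[id] <- 1L }
          }
          if (r == 5L) {
            # follower moved with its train; fall through to the food check
          } else if (r == 1L) {
            nb <- adj[[node[id]]]
            if (length(nb) > 1L) {
              lw <- pw * (nb != prev[id]) +
                tw * pmin(raw_trail[nb] * ef, tc) +
                hw * peripheral[nb]
              w <- exp(lw - max(lw))
              nxt <- nb[sample.int(length(nb), 1L, prob = w)]
            } else nxt <- nb[1L]
            prev[id] <- node[id]; node[id] <- nxt
          } else if (r == 4L) {
            tg <- target[id]
            if (node[id] == tg) nxt <- tg
            else if (stats::runif(1) < noise) {
              nb <- adj[[node[id]]]
              nxt <- nb[sample.int(length(nb), 1L)]
            } else {
              nxt <- parents_toward(tg)[node[id]]
              if (nxt == 0L) nxt <- node[id]
            }
            prev[id] <- node[id]; node[id] <- nxt
            if (node[id] == tg) {            # reached the food patch
              if (items[tg] > 0L) {
                # handled by the food check below
              } else { role[id] <- 1L; deadline[id] <- f +
                as.integer(0.25 * config$mean_excursion_s * fr) }
            }
          } else {                            # homing (2) or carrying (3)
            if (r == 3L) raw_trail[node[id]] <- raw_trail[node[id]] + inf_w
            if (node[id] == nest) {
              push_event(t_s, "enter_nest", id, nest)
              if (r == 3L) {
                push_event(t_s, "food_collected", id, nest)
                if (items_left > 0L && pool > 0L) {
                  k <- sample(rng_lo:rng_hi, 1L)
                  with_items <- which(items > 0L)
                  if (length(with_items)) {
                    tgts <- with_items[sample.int(length(with_items), k,
                                                  replace = TRUE)]
                    first_new <- next_id
                    emit(f, k, new_role = 4L)
                    made <- seq_len(next_id - first_new)
                    for (m in made) {
                      target[first_new + m - 1L] <- tgts[m]
                      push_event(t_s, "recruit_dispatch",
                                 first_new + m - 1L, tgts[m])
                    }
                  }
                }
              }
              active <- active[active != id]
              pool <- pool + 1L
              next
            }
            prev[id] <- node[id]
            node[id] <- parent_nest[node[id]]
            if (node[id] == 0L) node[id] <- nest   # disconnected safeguard
          }
          # food pickup check (scouts and recruits)
          cur <- node[id]
          if (items_left > 0L && items[cur] > 0L &&
              role[id] %in% c(1L, 4L, 5L) &&
              (role[id] == 4L || stats::runif(1) < config$food_detect_prob)) {
            if (!discovered[cur]) {
              discovered[cur] <- TRUE
              push_event(t_s, "food_found", id, cur)
              tp1_seen <- TRUE
            }
            items[cur] <- items[cur] - 1L
            items_left <- items_left - 1L
            role[id] <- 3L
            wait_until[id] <- f +
              as.integer(round(config$food_handling_s * fr))
            raw_trail[cur] <- raw_trail[cur] + inf_w
          }
        }
      }
      if (length(active)) {
        trk_ids[[f + 1L]] <- active
        trk_nodes[[f + 1L]] <- node[active]
      }
    }
  }

  counts <- lengths(trk_ids)
  frames <- rep.int(seq_len(T_frames) - 1L, counts)
  ids <- unlist(trk_ids, use.names = FALSE)
  nds <- unlist(trk_nodes, use.names = FALSE)
  if (is.null(ids)) { ids <- integer(0); nds <- integer(0) }
  tracks <- data.frame(frame = frames, ant_id = ids, node_id = nds,
                       x_mm = arena$nodes$x[nds], y_mm = arena$nodes$y[nds])
  events <- data.frame(time_s = ev_t, kind = ev_k, ant_id = ev_a,
                       node_id = ev_n, stringsAsFactors = FALSE)
  structure(list(tracks = tracks, events = events,
                 trail = raw_trail * exp(-decay * config$duration_s),
                 scenario = scenario, config = config, seed = seed),
            class = "foraging_trial")
}

#' @export
print.foraging_trial <- function(x, ...) {
  tp <- transition_points(x$events)
  cat("Synthetic foraging trial (", x$scenario$condition, " food, seed ",
      x$seed, ")\n", sep = "")
  cat("  ", nrow(x$tracks), " detections, ", nrow(x$events), " events\n",
      sep = "")
  cat("  TP1 = ", if (is.na(tp$TP1_s)) "absent" else paste0(tp$TP1_s, " s"),
      ", TP2 = ", if (is.na(tp$TP2_s)) "absent" else paste0(tp$TP2_s, " s"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a series of foraging trials under one food condition
#'
#' In the deterministic condition the same two food faces are used in every
#' trial and the trail field is carried over (decayed) from trial to trial,
#' emulating an arena that is never cleaned; in the stochastic condition the
#' food faces are redrawn at random and the trail is reset to zero before
#' each trial, emulating cleaning between trials.
#'
#' @param arena a `hex_arena`.
#' @param condition `"deterministic"` or `"stochastic"`.
#' @param n_trials number of consecutive trials.
#' @param config a [sim_config()]; `trail_persistence` is set from
#'   `condition`.
#' @param seed master seed from which per-trial seeds are drawn.
#' @param ... further arguments passed to [place_food()] (e.g.
#'   `fixed_faces`, `det_target_mm`).
#' @return A list of `foraging_trial` objects (each carrying its scenario),
#'   of class `foraging_series`.
#' @export
simulate_series <- function(arena, condition = c("deterministic", "stochastic"),
                            n_trials = 1L, config = sim_config(), seed = 1L,
                            ...) {
  condition <- match.arg(condition)
  stopifnot(n_trials >= 1L)
  config$trail_persistence <- condition == "deterministic"
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  scen_seeds <- sample.int(.Machine$integer.max, n_trials)
  .restore_rng(old)

  trail <- NULL
  known <- NULL
  n_success <- 0L
  base_frac <- config$experienced_frac
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    scen <- place_food(arena, condition, seed = scen_seeds[i], ...)
    # the share of experienced foragers compounds over successful trials
    config$experienced_frac <- 1 - (1 - base_frac)^n_success
    tr <- simulate_trial(arena, scen, config, seed = trial_seeds[i],
                         trail_init = trail, known_food = known)
    out[[i]] <- tr
    if (config$trail_persistence) {
      trail <- tr$trail * config$intertrial_retain
      found <- tr$events$node_id[tr$events$kind == "food_found"]
      if (length(found)) { known <- unique(c(known, found)); n_success <- n_success + 1L }
    } else { trail <- NULL; known <- NULL; n_success <- 0L }
  }
  structure(out, class = "foraging_series", condition = condition)
}
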