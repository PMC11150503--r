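#' First-passage food-detection time of a replica
#'
#' Runs Glauber dynamics from the all-empty state and returns the first
#' sweep by which every food node (or, with `metric = "first"`, at least one
#' food node) has registered a transition from empty to occupied. Time is
#' measured in Monte Carlo sweeps; realisations not detected within
#' `max_sweeps` are censored (`NA`).
#'
#' @param model an `ant_replica`.
#' @param food_nodes node ids holding food (must be in the model's node
#'   set).
#' @param max_sweeps censoring cap, default 10000 sweeps.
#' @param seed integer seed.
#' @param metric `"all"` (default; all food nodes detected — combines
#'   exploration with a significant part of gathering) or `"first"` (first
#'   food node reached).
#' @param init `"empty"` (default) or `"nest"` to start with only the nest
#'   node occupied; `nest_node` must then be supplied.
#' @param nest_node node id occupied at start when `init = "nest"`.
#' @return Integer sweep count, or `NA` if censored.
#' @export
detection_time <- function(model, food_nodes, max_sweeps = 10000L, seed = 1L,
                           metric = c("all", "first"),
                           init = c("empty", "nest"), nest_node = NULL) {
  stopifnot(inherits(model, "ant_replica"))
  metric <- match.arg(metric)
  init <- match.arg(init)
  if (!length(food_nodes)) stop("empty food set: detection task undefined")
  pos <- match(food_nodes, model$node_ids)
  if (anyNA(pos)) stop("food nodes not in the model's node set")
  sigma0 <- rep(-1L, length(model$h))
  if (init == "nest") {
    if (is.null(nest_node)) stop("init = 'nest' requires nest_node")
    np <- match(nest_node, model$node_ids)
    if (is.na(np)) stop("nest node not in the model's node set")
    sigma0[np] <- 1L
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  .detection_time_cpp(model$h, model$J, model$beta, as.integer(pos - 1L),
                      as.integer(max_sweeps), metric == "first", sigma0)
}

#' Run a batch of in-silico detection realisations
#'
#' Draws a food scenario per realisation (fresh seed stream), measures the
#' detection time under the model, and collects the results with explicit
#' censoring. Deterministic samplers (a fixed node vector) reuse the same
#' food set in every realisation.
#'
#' @param model an `ant_replica`.
#' @param scenario_sampler either a fixed integer vector of food nodes, a
#'   list of per-realisation food-node vectors, or a `function(seed)`
#'   returning a food-node vector.
#' @param n_realizations number of realisations.
#' @param max_sweeps censoring cap.
#' @param seed master seed; fans out to per-realisation scenario and
#'   dynamics seeds.
#' @param metric passed to [detection_time()].
#' @param model_desc,scenario_desc labels stored in the result.
#' @return An object of class `detection_result`: list with `times`
#'   (integer, `NA` = censored), `censored`, `max_sweeps`, `foods`,
#'   `model_desc`, `scenario_desc`.
#' @export
run_experiment <- function(model, scenario_sampler, n_realizations,
                           max_sweeps = 10000L, seed = 1L,
                           metric = c("all", "first"),
                           model_desc = "", scenario_desc = "") {
  stopifnot(n_realizations >= 1)
  metric <- match.arg(metric)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  dyn_seeds <- sample.int(.Machine$integer.max, n_realizations)
  scen_seeds <- sample.int(.Machine$integer.max, n_realizations)
  .restore_rng(old)

  foods <- if (is.function(scenario_sampler))
    lapply(seq_len(n_realizations), function(i) scenario_sampler(scen_seeds[i]))
  else if (is.list(scenario_sampler)) {
    stopifnot(length(scenario_sampler) >= n_realizations)
    scenario_sampler[seq_len(n_realizations)]
  } else replicate(n_realizations, as.integer(scenario_sampler),
                   simplify = FALSE)

  times <- vapply(seq_len(n_realizations), function(i)
    detection_time(model, foods[[i]], max_sweeps, seed = dyn_seeds[i],
                   metric = metric), integer(1))
  structure(list(times = times, censored = is.na(times),
                 max_sweeps = as.integer(max_sweeps), foods = foods,
                 metric = metric,
                 model_desc = model_desc, scenario_desc = scenario_desc),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("Detection experiment", if (nzchar(x$model_desc))
    paste0(" [", x$model_desc, " | ", x$scenario_desc, "]"), ":\n", sep = "")
  cat("  ", length(x$times), " realisations, ", sum(x$censored),
      " censored at ", x$max_sweeps, " sweeps\n", sep = "")
  if (any(!x$censored))
    cat("  median ", stats::median(x$times, na.rm = TRUE), " sweeps, P90 ",
        tryCatch(percentile_time(x, 90), error = function(e) NA),
        " sweeps\n", sep = "")
  invisible(x)
}

#' Survival curve of the detection process
#'
#' `S(t)` is the fraction of realisations whose detection time exceeds `t`
#' sweeps (censored realisations count as exceeding the cap), i.e. the
#' probability that the food has not yet been fully detected at time `t`.
#'
#' @param result a `detection_result`.
#' @param t times at which to evaluate; default the step positions
#'   (0, the observed times, and the cap).
#' @return Data frame `t`, `S` of class `survival_curve`.
#' @export
survival_curve <- function(result, t = NULL) {
  stopifnot(inherits(result, "detection_result"),
            length(result$times) >= 1)
  times <- ifelse(result$censored, Inf, result$times)
  if (is.null(t))
    t <- sort(unique(c(0, result$times[!result$censored], result$max_sweeps)))
  S <- vapply(t, function(tt) mean(times > tt), numeric(1))
  structure(data.frame(t = t, S = S), class = c("survival_curve",
                                                "data.frame"))
}

#' @export
plot.survival_curve <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$t, x$S, type = "s", ...)
  else plot(x$t, x$S, type = "s", xlab = "time (sweeps)",
            ylab = "S(t)", ylim = c(0, 1), ...)
  invisible(x)
}

#' Nearest-rank percentile of detection times
#'
#' The rank is computed over all realisations (censored ones sit above every
#' finite time); an error is raised if the rank falls among the censored
#' realisations, in which case the percentile is undefined at this cap.
#'
#' @param result a `detection_result`.
#' @param q percentile in (0, 100], default 90.
#' @return The `ceiling(q/100 * n)`-th order statistic of the times.
#' @export
percentile_time <- function(result, q = 90) {
  stopifnot(inherits(result, "detection_result"), q > 0, q <= 100)
  n <- length(result$times)
  rank <- ceiling(q / 100 * n)
  finite <- sort(result$times[!result$censored])
  if (rank > length(finite))
    stop("percentile ", q, " undefined: ", sum(result$censored), "/", n,
         " realisations censored")
  finite[rank]
}

# bootstrap percentile CI for P90(a) - P90(b), resampling realisation
# indices jointly (paired realisations)
p90_diff_ci <- function(result_a, result_b, q = 90, n_boot = 500,
                        seed = 1L, conf = 0.95) {
  na <- length(result_a$times); nb <- length(result_b$times)
  ta <- ifelse(result_a$censored, Inf, result_a$times)
  tb <- ifelse(result_b$censored, Inf, result_b$times)
  p90 <- function(x) {
    r <- ceiling(q / 100 * length(x))
    v <- sort(x)[r]
    if (is.infinite(v)) NA_real_ else v
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  paired <- na == nb
  diffs <- vapply(seq_len(n_boot), function(b) {
    if (paired) {
      idx <- sample.int(na, na, replace = TRUE)
      p90(ta[idx]) - p90(tb[idx])
    } else {
      p90(ta[sample.int(na, na, replace = TRUE)]) -
        p90(tb[sample.int(nb, nb, replace = TRUE)])
    }
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  alpha <- (1 - conf) / 2
  list(diff = p90(ta) - p90(tb),
       ci = unname(stats::quantile(diffs, c(alpha, 1 - alpha))),
       n_boot_effective = length(diffs))
}

#' Comparative in-silico efficiency suites
#'
#' Runs the in-silico detection experiments comparing replicas trained
#' under deterministic and stochastic food conditions, with their null
#' (J = 0) counterparts. Three suites are available:
#' \describe{
#'   \item{`trained`}{each replica under its own trained food condition
#'     (deterministic replica with the fixed food faces, stochastic replica
#'     with random faces).}
#'   \item{`p_grid`}{food follows the deterministic placement with
#'     probability `p`, otherwise a random draw, for each `p` in `p_grid`
#'     (default 0, 0.5, 1).}
#'   \item{`radial_grid`}{food drawn at random among faces within `R` mm of
#'     the nest, for each `R` in `R_grid` (default 250, 550, 750 mm).}
#' }
#' Food draws and dynamics seeds are shared across models within a scenario
#' (paired realisations). Null models should be supplied at their
#' occupancy-calibrated beta (see [calibrate_beta()]; the full models run at
#' beta = 1, the nulls near beta = 0.9).
#'
#' @param det_model,sto_model full replicas trained on the deterministic /
#'   stochastic condition.
#' @param null_det,null_sto their J = 0 counterparts.
#' @param arena the `hex_arena` shared by all four models.
#' @param suite one of `"trained"`, `"p_grid"`, `"radial_grid"`.
#' @param n_realizations realisations per cell (hundreds suffice for the
#'   orderings).
#' @param max_sweeps censoring cap.
#' @param seed master seed.
#' @param p_grid,R_grid scenario grids for the respective suites.
#' @param det_faces optional fixed faces of the deterministic placement.
#' @param q percentile reported, default 90.
#' @param n_boot bootstrap resamples for the ordering confidence intervals.
#' @return An object of class `scenario_suite`: list with `cells` (named
#'   `detection_result`s), `p90` (data frame), `orderings` (bootstrap
#'   comparisons for the trained suite), `suite`.
#' @export
scenario_suite <- function(det_model, sto_model, null_det, null_sto, arena,
                           suite = c("trained", "p_grid", "radial_grid"),
                           n_realizations = 200, max_sweeps = 10000L,
                           seed = 1L, p_grid = c(0, 0.5, 1),
                           R_grid = c(250, 550, 750), det_faces = NULL,
                           q = 90, n_boot = 500) {
  suite <- match.arg(suite)
  stopifnot(inherits(arena, "hex_arena"))
  models <- list(det = det_model, sto = sto_model,
                 null_det = null_det, null_sto = null_sto)
  for (m in models) stopifnot(inherits(m, "ant_replica"))

  sampler_for <- function(condition, p = NULL, R_mm = NULL) {
    force(condition); force(p); force(R_mm)
    function(s) place_food(arena, condition, seed = s, p = p, R_mm = R_mm,
                           fixed_faces = det_faces)$food_nodes
  }
  draw_foods <- function(sampler, master_seed) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(master_seed)
    ss <- sample.int(.Machine$integer.max, n_realizations)
    lapply(ss, sampler)
  }

  cells <- list()
  p90_rows <- list()
  run_cell <- function(model, foods, cell_seed, model_name, scen_name) {
    res <- run_experiment(model, foods, n_realizations, max_sweeps,
                          seed = cell_seed, model_desc = model_name,
                          scenario_desc = scen_name)
    cells[[paste(model_name, scen_name, sep = "@")]] <<- res
    p90_rows[[length(p90_rows) + 1L]] <<- data.frame(
      model = model_name, scenario = scen_name,
      p90 = tryCatch(percentile_time(res, q), error = function(e) NA_real_),
      censored = sum(res$censored))
    res
  }

  orderings <- list()
  if (suite == "trained") {
    det_foods <- draw_foods(sampler_for("deterministic"), seed + 11L)
    sto_foods <- draw_foods(sampler_for("stochastic"), seed + 12L)
    r_det <- run_cell(models$det, det_foods, seed + 1L, "det", "deterministic")
    r_sto <- run_cell(models$sto, sto_foods, seed + 1L, "sto", "stochastic")
    run_cell(models$null_det, det_foods, seed + 1L, "null_det",
             "deterministic")
    run_cell(models$null_sto, sto_foods, seed + 1L, "null_sto", "stochastic")
    orderings$det_vs_sto_own <- p90_diff_ci(r_det, r_sto, q, n_boot,
                                            seed + 99L)
  } else if (suite == "p_grid") {
    for (p in p_grid) {
      foods <- draw_foods(sampler_for("p_mixture", p = p),
                          seed + 11L + round(1000 * p))
      scen <- paste0("p=", p)
      for (mn in names(models))
        run_cell(models[[mn]], foods, seed + 1L, mn, scen)
    }
  } else {
    for (R in R_grid) {
      foods <- draw_foods(sampler_for("radial", R_mm = R),
                          seed + 11L + round(R))
      scen <- paste0("R=", R)
      for (mn in names(models))
        run_cell(models[[mn]], foods, seed + 1L, mn, scen)
    }
  }
  structure(list(cells = cells, p90 = do.call(rbind, p90_rows),
                 orderings = orderings, suite = suite, q = q,
                 n_realizations = n_realizations,
                 max_sweeps = as.integer(max_sweeps)),
            class = "scenario_suite")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat("In-silico efficiency suite (", x$suite, "), ", x$n_realizations,
      " realisations per cell, cap ", x$max_sweeps, " sweeps\n", sep = "")
  print(x$p90, row.names = FALSE)
  if (length(x$orderings)) {
    o <- x$orderings$det_vs_sto_own
    cat("P", x$q, "(det@det) - P", x$q, "(sto@sto) = ", o$diff,
        " sweeps, 95% CI [", round(o$ci[1], 1), ", ", round(o$ci[2], 1),
        "]\n", sep = "")
  }
  invisible(x)
}
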