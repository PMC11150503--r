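test_that("single-spin detection follows the heat-bath geometric law", {
  # h = 0: flip probability 1/2 per sweep, mean 2 sweeps
  t0 <- vapply(1:2000, function(s) detection_time(replica(h = 0), 1, seed = s),
               integer(1))
  expect_lt(abs(mean(t0) - 2), 3 * sqrt(2 / 2000))   # geometric sd = sqrt(2)
  # strong positive field: q = 1/(1+e^-6), mean ~ 1.0025
  t3 <- vapply(1:2000, function(s) detection_time(replica(h = 3), 1, seed = s),
               integer(1))
  expect_lt(abs(mean(t3) - (1 + exp(-6))), 0.01)
  # strongly negative field censors at a small cap
  tc <- vapply(1:50, function(s)
    detection_time(replica(h = -4), 1, max_sweeps = 10, seed = s), integer(1))
  expect_gt(mean(is.na(tc)), 0.9)
  expect_error(detection_time(replica(h = 0), integer()), "empty food set")
  expect_error(detection_time(replica(h = 0), 5), "not in the model")
})

test_that("detection from a nest-occupied start is supported", {
  m <- replica(h = c(-1, 0, 0), node_ids = 1:3)
  t1 <- detection_time(m, 2, seed = 4, init = "nest", nest_node = 1)
  expect_true(is.na(t1) || t1 >= 1)
  expect_error(detection_time(m, 2, init = "nest"), "requires nest_node")
})

test_that("experiments are reproducible and samplers behave", {
  m <- replica(h = rep(-0.5, 6), node_ids = 1:6)
  # deterministic sampler: identical food in every realisation
  r <- run_experiment(m, c(2L, 3L), 40, max_sweeps = 200, seed = 7)
  expect_true(all(vapply(r$foods, identical, logical(1), y = c(2L, 3L))))
  r2 <- run_experiment(m, c(2L, 3L), 40, max_sweeps = 200, seed = 7)
  expect_identical(r$times, r2$times)
  # function samplers get fresh seeds; a p = 0.5 mixture picks the
  # deterministic set about half the time
  det_set <- c(1L, 2L)
  sampler <- function(s) { set.seed(s); if (stats::runif(1) < 0.5) det_set
    else sort(sample(3:6, 2)) }
  rp <- run_experiment(m, sampler, 400, max_sweeps = 50, seed = 9)
  frac <- mean(vapply(rp$foods, identical, logical(1), y = det_set))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("survival curves are proper tail probabilities", {
  r <- structure(list(times = c(1L, 2L, 3L), censored = rep(FALSE, 3),
                      max_sweeps = 10L, foods = NULL, metric = "all",
                      model_desc = "", scenario_desc = ""),
                 class = "detection_result")
  s <- survival_curve(r, t = 0:4)
  expect_equal(s$S, c(1, 2 / 3, 1 / 3, 0, 0))
  # property check on random censored results
  for (k in 1:20) {
    set.seed(k)
    n <- sample(5:40, 1)
    cap <- 50L
    times <- sample(1:cap, n, replace = TRUE)
    cens <- runif(n) < 0.3
    times[cens] <- NA
    rr <- structure(list(times = times, censored = cens, max_sweeps = cap,
                         foods = NULL, metric = "all", model_desc = "",
                         scenario_desc = ""), class = "detection_result")
    sc <- survival_curve(rr, t = c(0, sort(sample(1:cap, 5)), cap))
    expect_equal(sc$S[1], 1)
    expect_true(all(diff(sc$S) <= 0))
    expect_equal(sc$S[length(sc$S)], mean(cens))
  }
})

test_that("nearest-rank percentiles handle censoring strictly", {
  mk <- function(times, cens, cap = 100L)
    structure(list(times = replace(times, cens, NA), censored = cens,
                   max_sweeps = cap, foods = NULL, metric = "all",
                   model_desc = "", scenario_desc = ""),
              class = "detection_result")
  expect_equal(percentile_time(mk(1:10, rep(FALSE, 10)), 90), 9)
  expect_equal(percentile_time(mk(c(5, 5, 5), rep(FALSE, 3)), 50), 5)
  r <- mk(c(1:8, NA, NA), c(rep(FALSE, 8), TRUE, TRUE))
  expect_error(percentile_time(r, 90), "undefined")
  expect_equal(percentile_time(r, 50), 5)
})

test_that("adding food nodes never shortens detection (matched seeds)", {
  set.seed(3)
  m <- replica(rnorm(10, -1, 0.3), node_ids = 1:10)
  for (s in 1:25) {
    ta <- detection_time(m, c(2L, 5L), max_sweeps = 5000, seed = s)
    tb <- detection_time(m, c(2L, 5L, 8L), max_sweeps = 5000, seed = s)
    expect_true(is.na(tb) || (!is.na(ta) && tb >= ta))
  }
})

test_that("first-node metric is never slower than all-nodes", {
  set.seed(4)
  m <- replica(rnorm(8, -1, 0.4), node_ids = 1:8)
  for (s in 1:15) {
    t_all <- detection_time(m, c(1L, 4L, 7L), max_sweeps = 5000, seed = s)
    t_first <- detection_time(m, c(1L, 4L, 7L), max_sweeps = 5000, seed = s,
                              metric = "first")
    expect_true(is.na(t_all) || t_first <= t_all)
  }
})

test_that("detection result CSV round trip keeps times and censoring", {
  m <- replica(h = rep(-0.2, 4), node_ids = 1:4)
  r <- run_experiment(m, c(1L, 3L), 25, max_sweeps = 30, seed = 5,
                      model_desc = "toy", scenario_desc = "fixed")
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection(r, path)
  back <- read_detection(path)
  expect_identical(back$times, r$times)
  expect_identical(back$censored, r$censored)
  expect_identical(back$max_sweeps, r$max_sweeps)
})

test_that("the scenario suite reports cells, percentiles and orderings", {
  a <- test_arena()
  set.seed(8)
  # simple synthetic replicas concentrated near the deterministic faces
  det_sc <- place_food(a, "deterministic", seed = 1)
  n <- nrow(a$nodes)
  h_det <- rep(-2.5, n); h_det[det_sc$food_nodes] <- 0.5
  h_sto <- rep(-1.2, n)
  det_m <- replica(h_det, node_ids = a$active_nodes)
  sto_m <- replica(h_sto, node_ids = a$active_nodes)
  st <- scenario_suite(det_m, sto_m, det_m, sto_m, a, "trained",
                       n_realizations = 40, max_sweeps = 3000, seed = 12,
                       n_boot = 100)
  expect_length(st$cells, 4L)
  expect_identical(nrow(st$p90), 4L)
  expect_true(all(c("diff", "ci") %in% names(st$orderings$det_vs_sto_own)))
  sp <- scenario_suite(det_m, sto_m, det_m, sto_m, a, "p_grid",
                       n_realizations = 20, max_sweeps = 3000, seed = 13,
                       p_grid = c(0, 1), n_boot = 50)
  expect_identical(nrow(sp$p90), 8L)
  # identical foods across models within a scenario cell (paired draws)
  expect_identical(sp$cells[["det@p=0"]]$foods, sp$cells[["sto@p=0"]]$foods)
})
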