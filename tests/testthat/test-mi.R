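test_that("plug-in MI matches hand-computed 2x2 values", {
  # joint counts (40, 10, 10, 40) over 100 frames
  m <- rbind(matrix(c(1, 1), 40, 2, byrow = TRUE),
             matrix(c(1, 0), 10, 2, byrow = TRUE),
             matrix(c(0, 1), 10, 2, byrow = TRUE),
             matrix(c(0, 0), 40, 2, byrow = TRUE))
  mi <- pairwise_mi(as_occ(m))
  expect_equal(mi$values[1, 2], 0.2780719, tolerance = 1e-6)

  # an exactly factorised joint carries zero information
  ind <- as_occ(cbind(rep(c(1, 0), each = 4), rep(c(1, 0), 4)))
  expect_equal(pairwise_mi(ind)$values[1, 2], 0)

  # identical balanced columns -> 1 bit; in nats -> log(2)
  dup <- as_occ(cbind(rep(0:1, 10), rep(0:1, 10)))
  expect_equal(pairwise_mi(dup)$values[1, 2], 1)
  expect_equal(pairwise_mi(dup, base = exp(1))$values[1, 2], log(2))

  expect_error(pairwise_mi(as_occ(matrix(1, 1, 2))), "at least 2 frames")
})

test_that("MI matrices are symmetric, non-negative, zero-diagonal", {
  set.seed(4)
  occ <- as_occ(matrix(rbinom(600, 1, 0.3), 60, 10))
  mi <- pairwise_mi(occ)
  expect_identical(mi$values, t(mi$values))
  expect_true(all(mi$values >= 0))
  expect_true(all(diag(mi$values) == 0))
  # duplicating a column yields MI equal to the column entropy
  p <- mean(occ$values[, 1])
  H <- -p * log2(p) - (1 - p) * log2(1 - p)
  dup <- as_occ(cbind(occ$values[, 1], occ$values[, 1]))
  expect_equal(pairwise_mi(dup)$values[1, 2], H, tolerance = 1e-12)
})

test_that("average MI is the unordered-pair mean", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  expect_equal(average_mi(m), 0.2)
  expect_equal(average_mi(matrix(0, 4, 4)), 0)
  expect_error(average_mi(matrix(0, 1, 1)), "at least 2")
})

test_that("plug-in estimator converges to the analytic MI of 2x2 joints", {
  analytic_mi <- function(p) {
    pi1 <- p[1] + p[2]; pj1 <- p[1] + p[3]
    q <- c(pi1 * pj1, pi1 * (1 - pj1), (1 - pi1) * pj1,
           (1 - pi1) * (1 - pj1))
    sum(ifelse(p > 0, p * log2(p / q), 0))
  }
  joints <- list(c(0.4, 0.1, 0.1, 0.4), c(0.25, 0.25, 0.25, 0.25),
                 c(0.05, 0.15, 0.3, 0.5), c(0.6, 0.05, 0.05, 0.3))
  states <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  for (k in seq_along(joints)) {
    p <- joints[[k]]
    for (s in 1:5) {
      set.seed(1000 * k + s)
      draw <- sample.int(4, 1e4, replace = TRUE, prob = p)
      est <- pairwise_mi(as_occ(states[draw, ]))$values[1, 2]
      expect_lt(abs(est - analytic_mi(p)), 0.01)
    }
  }
})

test_that("nearest-neighbour MI map averages over channel neighbours", {
  a <- test_arena()
  n <- length(a$active_nodes)
  v <- which(!a$nodes$peripheral)[1]
  nb <- node_neighbors(a, v)
  m <- matrix(0, n, n)
  m[v, nb] <- m[nb, v] <- c(0.2, 0.4, 0.6)
  mi <- structure(list(values = m, node_ids = a$active_nodes,
                       window_s = c(0, 1), base = 2), class = "mi_matrix")
  map <- neighbor_mi_map(mi, a)
  expect_equal(unname(map[v]), 0.4)
  # all-zero MI gives an all-zero map
  zero <- structure(list(values = matrix(0, n, n), node_ids = a$active_nodes,
                         window_s = c(0, 1), base = 2), class = "mi_matrix")
  expect_true(all(neighbor_mi_map(zero, a) == 0))
  # nodes whose neighbours are absent from the matrix are undefined
  sub <- structure(list(values = matrix(0, 1, 1), node_ids = a$active_nodes[1],
                        window_s = c(0, 1), base = 2), class = "mi_matrix")
  expect_true(is.na(neighbor_mi_map(sub, a)[1]))
})

test_that("windowed average MI respects window and step", {
  set.seed(9)
  occ <- as_occ(matrix(rbinom(3600 * 6, 1, 0.3), 3600, 6))
  ser <- windowed_average_mi(occ, window_s = 900, step_s = 150)
  expect_equal(unique(round(diff(ser$center_s), 6)), 150)
  expect_true(all(ser$avg_mi >= 0))
  # i.i.d. occupancy: no trend beyond the estimator's positive bias floor
  sl <- summary(stats::lm(avg_mi ~ center_s, data = ser))$coefficients
  expect_gt(sl["center_s", "Pr(>|t|)"], 0.01)
  # degenerate constant occupancy has zero entropy everywhere
  ones <- as_occ(matrix(1L, 2400, 4))
  expect_true(all(windowed_average_mi(ones, 600, 300)$avg_mi == 0))
  expect_error(windowed_average_mi(occ, window_s = 5000), "longer than")
})

test_that("lag times follow the onset rules and sign conventions", {
  mk <- function(t, v) structure(data.frame(center_s = t, avg_mi = v),
                                 class = c("mi_series", "data.frame"))
  # V-shaped series: minimum at 2100 s, maximum at 5000 s
  t <- seq(0, 6000, by = 100)
  v <- c(seq(1, 0.5, length.out = 22), seq(0.52, 1.5, length.out = 29),
         seq(1.48, 1.1, length.out = 10))
  ser <- mk(t, v)
  tp <- structure(list(TP1_s = 1980, TP2_s = 5300, duration_s = 6000),
                  class = "phase_bounds")
  lt <- lag_times(ser, tp)
  expect_equal(lt$T1_s, 2100 - 1980)          # delayed rise: +120 s
  expect_equal(lt$T2_s, 5000 - 5300)          # anticipated fall: -300 s
  # minimum exactly at TP1 gives T1 = 0
  tp0 <- structure(list(TP1_s = 2100, TP2_s = 5300, duration_s = 6000),
                  class = "phase_bounds")
  expect_equal(lag_times(ser, tp0)$T1_s, 0)
  # monotone series has no turning points
  mono <- mk(t, seq(0, 1, length.out = length(t)))
  expect_true(is.na(lag_times(mono, tp)$T1_s))
  expect_error(lag_times(ser, structure(list(TP1_s = NA, TP2_s = 1),
                                        class = "phase_bounds")),
               "transition points")
})

test_that("MI matrix and series CSV round trips are faithful", {
  set.seed(2)
  occ <- as_occ(matrix(rbinom(400, 1, 0.4), 40, 10), node_ids = 2:11)
  mi <- pairwise_mi(occ)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_mi_matrix(mi, p1)
  back <- read_mi_matrix(p1)
  expect_equal(back$values, mi$values, tolerance = 1e-12)
  expect_identical(back$node_ids, mi$node_ids)

  ser <- windowed_average_mi(as_occ(matrix(rbinom(2000, 1, .3), 200, 10)),
                             window_s = 25, step_s = 10)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_mi_series(ser, p2)
  back2 <- read_mi_series(p2)
  expect_equal(back2$avg_mi, ser$avg_mi, tolerance = 1e-12)
})
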