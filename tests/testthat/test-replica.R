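test_that("configuration scores follow the pairwise energy", {
  m0 <- replica(h = c(0, 0))
  expect_equal(replica_score(m0, c(1, 1)), 0)
  expect_equal(replica_score(m0, c(0, 0)), 0)

  m <- replica(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(replica_score(m, c(1, 1)), 0.5)       # 1 - 1 + 0.5
  # spin-flip symmetry at h = 0
  mj <- replica(h = c(0, 0, 0), J = {
    J <- matrix(0.2, 3, 3); diag(J) <- 0; J
  })
  set.seed(1)
  cfg <- sample(c(0, 1), 3, replace = TRUE)
  expect_equal(replica_score(mj, cfg), replica_score(mj, 1 - cfg))
  expect_error(replica_score(m, c(1, 1, 1)), "dimension mismatch")
})

test_that("exact enumeration gives the canonical distribution", {
  m1 <- replica(h = 0)
  ed1 <- exact_distribution(m1)
  expect_equal(ed1$prob, c(0.5, 0.5))

  m <- replica(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  ed <- exact_distribution(m)
  expect_equal(sum(ed$prob), 1, tolerance = 1e-12)
  expect_equal(ed$Z, 2 * exp(0.5) + exp(1.5) + exp(-2.5), tolerance = 1e-9)
  i <- which(ed$states[, 1] == 1 & ed$states[, 2] == 0)
  expect_equal(ed$prob[i], exp(1.5) / ed$Z, tolerance = 1e-9)
  expect_equal(ed$prob[i], 0.570, tolerance = 1e-3)

  expect_error(exact_distribution(replica(h = numeric(25))), "N > 20")
})

test_that("the beta-scaling degeneracy leaves the distribution invariant", {
  set.seed(5)
  J <- matrix(rnorm(16, 0, 0.2), 4); J <- (J + t(J)) / 2; diag(J) <- 0
  h <- rnorm(4)
  p1 <- exact_distribution(replica(h, J, beta = 1))$prob
  p2 <- exact_distribution(replica(2 * h, 2 * J, beta = 0.5))$prob
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("independent fits use the smoothed closed form", {
  occ <- as_occ(matrix(c(rep(1L, 50), rep(0L, 50)), 100, 1))
  f <- fit_replica(occ, "independent")
  expect_equal(f$h, 0)                                 # p = 0.5
  expect_true(f$is_null && all(f$J == 0))

  occ8 <- as_occ(matrix(c(rep(1L, 80), rep(0L, 20)), 100, 1))
  expect_equal(fit_replica(occ8, "independent")$h, atanh(2 * 81 / 102 - 1),
               tolerance = 1e-12)
  # without smoothing, p = 0.8 maps to atanh(0.6) = 0.6931
  expect_equal(fit_replica(occ8, "independent", pseudocount = 0)$h,
               atanh(2 * 0.8 - 1), tolerance = 1e-12)
  expect_equal(atanh(2 * 0.8 - 1), log(4) / 2, tolerance = 1e-12)

  ones <- as_occ(matrix(1L, 98, 1))
  expect_equal(fit_replica(ones, "independent")$h, atanh(0.98),
               tolerance = 1e-9)
  expect_equal(atanh(0.98), 2.297560, tolerance = 1e-6)
})

test_that("Glauber sampling reproduces enumeration moments", {
  # free fair spins
  m0 <- replica(h = rep(0, 4))
  Y0 <- sample_replica(m0, 4000, burn_in_sweeps = 50, seed = 2)
  se <- sqrt(0.25 / 4000)
  expect_true(all(abs(colMeans(Y0) - 0.5) < 3 * se))

  # the two-spin model against its exact distribution
  m <- replica(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  Y <- sample_replica(m, 20000, burn_in_sweeps = 100, thin_sweeps = 2,
                      seed = 11)
  emp <- mean(Y[, 1] == 1 & Y[, 2] == 0)
  expect_lt(abs(emp - 0.570), 3 * sqrt(0.57 * 0.43 / 20000) + 0.005)

  # moments of random small models vs enumeration
  for (s in 1:3) {
    set.seed(100 + s)
    n <- sample(5:9, 1)
    J <- matrix(rnorm(n^2, 0, 0.3 / sqrt(n)), n); J <- (J + t(J)) / 2
    diag(J) <- 0
    m <- replica(rnorm(n, 0, 0.4), J)
    ed <- exact_distribution(m)
    S <- 2 * ed$states - 1
    mom_exact <- drop(ed$prob %*% S)
    Y <- 2 * sample_replica(m, 30000, burn_in_sweeps = 100, thin_sweeps = 2,
                            seed = 200 + s) - 1
    se_i <- apply(Y, 2, hexforage:::.batch_se)
    expect_true(all(abs(colMeans(Y) - mom_exact) < 4 * se_i))
  }
})

test_that("sampler accuracy improves with sample size (total variation)", {
  m <- replica(h = c(0.3, -0.2, 0.1), J = matrix(c(0, .3, 0, .3, 0, -.2,
                                                   0, -.2, 0), 3))
  ed <- exact_distribution(m)
  tv <- function(n, seed) {
    Y <- sample_replica(m, n, burn_in_sweeps = 100, thin_sweeps = 2,
                        seed = seed)
    idx <- drop(Y %*% c(1, 2, 4)) + 1
    emp <- tabulate(idx, nbins = 8) / n
    sum(abs(emp - ed$prob)) / 2
  }
  expect_lt(tv(100000, 3), tv(1000, 3))
})

test_that("pseudolikelihood on independent fair spins recovers zeros", {
  mean_absJ <- numeric(5); max_absh <- numeric(5)
  for (s in 1:5) {
    set.seed(400 + s)
    X <- matrix(rbinom(2e4 * 8, 1, 0.5), 2e4, 8)
    f <- fit_replica(as_occ(X), "pseudolikelihood")
    mean_absJ[s] <- mean(abs(f$J[upper.tri(f$J)]))
    max_absh[s] <- max(abs(f$h))
    expect_true(f$fit_meta$converged)
  }
  expect_lt(mean(mean_absJ), 0.05)
  expect_true(all(max_absh < 0.05))
})

test_that("pseudolikelihood recovers a known sparse model", {
  set.seed(77)
  n <- 15
  J <- matrix(0, n, n)
  idx <- which(upper.tri(J))
  sel <- sample(idx, 25)
  J[sel] <- runif(25, 0.15, 0.4) * sample(c(-1, 1), 25, TRUE, c(.3, .7))
  J <- J + t(J)
  h <- rnorm(n, -0.2, 0.3)
  X <- sample_replica(replica(h, J), 15000, burn_in_sweeps = 200,
                      thin_sweeps = 2, seed = 5)
  f <- fit_replica(as_occ(X), "pseudolikelihood")
  ut <- upper.tri(J)
  expect_gt(stats::cor(f$h, h), 0.9)
  expect_gt(stats::cor(f$J[ut], J[ut]), 0.8)
  # the two directed coupling estimates agree closely before averaging
  expect_lt(max(abs(f$J - t(f$J))), 1e-12)   # stored symmetric by contract
})

test_that("coupling support restriction zeroes excluded pairs", {
  set.seed(6)
  X <- matrix(rbinom(500 * 6, 1, 0.4), 500, 6)
  pairs <- cbind(c(1, 2, 3), c(2, 3, 4))
  f <- fit_replica(as_occ(X), "pseudolikelihood", pairs = pairs)
  allowed <- matrix(FALSE, 6, 6)
  allowed[pairs] <- TRUE; allowed <- allowed | t(allowed)
  expect_true(all(f$J[!allowed & upper.tri(allowed)] == 0))
  expect_error(fit_replica(as_occ(X), "pseudolikelihood",
                           pairs = cbind(1, 99)), "absent")
})

test_that("adjacency_pairs returns pairs within the hop limit", {
  a <- test_arena()
  p1 <- adjacency_pairs(a, 1)
  expect_identical(nrow(p1), nrow(a$edges))
  p2 <- adjacency_pairs(a, 2)
  expect_gt(nrow(p2), nrow(p1))
  hops <- igraph::distances(a$graph)
  expect_true(all(hops[p2] <= 2))
})

test_that("independent fit and sampling round-trip node frequencies", {
  p_true <- c(0.1, 0.3, 0.6, 0.85)
  m <- replica(atanh(2 * p_true - 1))
  Y <- sample_replica(m, 8000, burn_in_sweeps = 50, seed = 14)
  f <- fit_replica(as_occ(Y), "independent")
  p_back <- tanh(f$h) / 2 + 0.5
  se <- sqrt(p_true * (1 - p_true) / 8000)
  expect_true(all(abs(p_back - p_true) < 3 * se + 0.001))
})

test_that("field recalibration pins node occupancies of a misfit model", {
  set.seed(21)
  # data with heterogeneous marginals; model starts with wrong fields
  X <- sapply(c(0.05, 0.2, 0.5, 0.8), function(p) rbinom(3000, 1, p))
  start <- replica(h = rep(0, 4), J = matrix(c(0, .2, 0, 0, .2, 0, 0, 0,
                                               0, 0, 0, .1, 0, 0, .1, 0), 4))
  cal <- recalibrate_fields(start, as_occ(X), n_iter = 200, seed = 3)
  Y <- sample_replica(cal, 5000, burn_in_sweeps = 100, seed = 4)
  expect_lt(max(abs(colMeans(Y) - colMeans(X))), 0.03)
  expect_true(cal$fit_meta$recalibrated)
})

test_that("goodness of fit separates full and null replicas", {
  set.seed(31)
  n <- 10
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1)) J[k, k + 1] <- 0.5
  J <- J + t(J)
  truth <- replica(rnorm(n, -0.5, 0.3), J)
  X <- sample_replica(truth, 6000, burn_in_sweeps = 200, thin_sweeps = 2,
                      seed = 41)
  occ <- as_occ(X)
  # a model evaluated on its own sample is self-consistent
  g_self <- goodness_of_fit(truth, occ, n_samples = 6000, seed = 42)
  expect_gt(g_self$cor_occupancy, 0.98)
  expect_gt(g_self$cor_corr, 0.8)
  # the null reproduces occupancies but no pair correlations
  null <- fit_replica(occ, "independent")
  g_null <- goodness_of_fit(null, occ, n_samples = 6000, seed = 42)
  expect_gt(g_null$cor_occupancy, 0.98)
  expect_lt(abs(g_null$cor_corr), 0.35)
  expect_gt(g_self$cor_corr, g_null$cor_corr)
})

test_that("equilibrium occupancy decreases with beta", {
  set.seed(51)
  m <- replica(rnorm(12, -0.8, 0.3))
  ob <- occupancy_vs_beta(m, c(0.5, 1, 1.5), n_samples = 2000, seed = 6)
  expect_true(all(diff(ob$occupancy) < 0))
  # infinite-temperature limit approaches half occupancy
  hot <- occupancy_vs_beta(m, 0.01, n_samples = 2000, seed = 7)
  expect_lt(abs(hot$occupancy - 0.5), 0.02)
  # strongly negative fields at large beta empty the system
  cold <- occupancy_vs_beta(replica(rep(-3, 8)), 4, n_samples = 1000, seed = 8)
  expect_lt(cold$occupancy, 0.005)
})

test_that("beta calibration hits the target occupancy", {
  m <- replica(c(-1.2, -0.8, -1.5, -0.6))
  own <- mean(sample_replica(m, 4000, seed = 9))
  b <- calibrate_beta(m, own, tol = 0.01, seed = 10)
  expect_lt(abs(b - 1), 0.25)
  mb <- m; mb$beta <- b
  expect_lt(abs(mean(sample_replica(mb, 4000, seed = 11)) - own), 0.015)
  expect_error(calibrate_beta(m, 0.9999), "achievable")
})

test_that("pairwise fraction is 1 for pairs and 0 for pure parity", {
  set.seed(61)
  x <- rbinom(600, 1, 0.5)
  y <- ifelse(runif(600) < 0.85, x, 1 - x)
  expect_equal(pairwise_fraction(cbind(x, y), 1:2), 1, tolerance = 1e-6)
  # three-node uniform XOR: pairwise marginals independent, 1 bit of
  # purely higher-order structure
  par <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  par <- par[rowSums(par) %% 2 == 0, ]
  Xp <- par[rep(1:4, 60), ]
  expect_equal(pairwise_fraction(Xp, 1:3), 0, tolerance = 1e-9)
  # generic data stays within [0, 1]
  Z <- matrix(rbinom(500 * 5, 1, 0.4), 500, 5)
  fr <- pairwise_fraction(Z, 1:5)
  expect_gte(fr, 0); expect_lte(fr, 1 + 1e-9)
  expect_error(pairwise_fraction(Z, 1), "at least 2")
  expect_error(pairwise_fraction(matrix(0, 5, 12), 1:12), "too large")
})

test_that("replica JSON round trip is exact", {
  set.seed(71)
  J <- matrix(rnorm(25, 0, 0.3), 5); J <- (J + t(J)) / 2; diag(J) <- 0
  J[abs(J) < 0.1] <- 0
  m <- replica(rnorm(5), J, beta = 0.9, node_ids = c(3L, 7L, 9L, 12L, 20L))
  path <- withr::local_tempfile(fileext = ".json")
  write_replica(m, path)
  back <- read_replica(path)
  expect_equal(back$h, m$h, tolerance = 1e-15)
  expect_equal(back$J, m$J, tolerance = 1e-15)
  expect_identical(back$node_ids, m$node_ids)
  expect_identical(back$beta, m$beta)
  expect_error(read_replica(withr::local_tempfile(lines = "{]")), "malformed")
})

test_that("simulate, coef, predict and summary methods behave", {
  m <- replica(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  Y <- simulate(m, nsim = 50, seed = 3)
  expect_identical(dim(Y), c(50L, 2L))
  expect_identical(Y, simulate(m, nsim = 50, seed = 3))
  co <- coef(m)
  expect_equal(co$h, m$h)
  lp <- predict(m, rbind(c(1, 0), c(0, 0)), type = "logprob")
  expect_equal(exp(lp[1]), 0.570, tolerance = 1e-3)
  s <- summary(m)
  expect_identical(s$n_nodes, 2L)
})
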