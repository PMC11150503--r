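#' Fit a pairwise maximum-entropy replica of a colony
#'
#' Fits the canonical pairwise model
#' \deqn{P(I) = Z^{-1} \exp\!\big[\beta\big(\textstyle\sum_i h_i \sigma_i +
#'   \sum_{i<j} J_{ij} \sigma_i \sigma_j\big)\big],\qquad \sigma_i = 2 I_i - 1,}
#' to a binary occupancy matrix — the inverse Ising problem. The fitted
#' object is a *computational replica* of the colony: sampled with Glauber
#' dynamics it generates occupancy patterns statistically matching the
#' training data's node means and pairwise correlations.
#'
#' Two estimators are available. `"pseudolikelihood"` (the default)
#' maximises the node-wise logistic pseudolikelihood at `beta = 1` with an
#' L2 penalty `lambda` on the couplings, then symmetrises the two directed
#' coupling estimates by averaging; exact likelihood maximisation is
#' intractable at experimental system sizes (620 nodes span about 10^186
#' configurations). `"independent"` is the null model: couplings forced to
#' zero and fields obtained in closed form from the smoothed node means,
#' `h_i = atanh(2 p_i - 1) / beta`; it reproduces each node's occupancy but
#' none of the collective structure.
#'
#' Training conditionals are smoothed Laplace-style: `pseudocount` copies of
#' the all-occupied and all-empty frames are appended, which keeps fields
#' finite for never-occupied nodes.
#'
#' @param occupancy an `occupancy_matrix` (or plain 0/1 matrix).
#' @param method `"pseudolikelihood"` or `"independent"`.
#' @param beta inverse-temperature parameter stored with the model
#'   (training is performed at `beta = 1`; `beta` is a post-fit occupancy
#'   knob).
#' @param lambda L2 penalty on couplings (per-sample scale), default 0.01.
#' @param pseudocount Laplace smoothing pseudocount, default 1.
#' @param pairs optional two-column matrix of node-id pairs restricting the
#'   coupling support (e.g. [adjacency_pairs()] for channel-graph
#'   neighbourhoods); couplings outside the support are fixed at zero.
#'   `NULL` (default) fits all pairs.
#' @param tol,max_iter convergence tolerance and iteration cap of the
#'   per-node BFGS optimisation.
#' @return An object of class `ant_replica`: list with `h` (length-N
#'   fields), `J` (N x N symmetric couplings, zero diagonal), `beta`,
#'   `node_ids`, `is_null`, and `fit_meta` (method, lambda, converged,
#'   objective, train_frames).
#' @seealso [sample_replica()], [goodness_of_fit()], [exact_distribution()]
#' @export
fit_replica <- function(occupancy,
                        method = c("pseudolikelihood", "independent"),
                        beta = 1, lambda = 0.01, pseudocount = 1,
                        pairs = NULL, tol = 1e-8, max_iter = 500) {
  method <- match.arg(method)
  X <- if (inherits(occupancy, "occupancy_matrix")) occupancy$values
    else as.matrix(occupancy)
  node_ids <- if (inherits(occupancy, "occupancy_matrix"))
    occupancy$node_ids else seq_len(ncol(X))
  tt <- nrow(X); n <- ncol(X)
  if (tt < 1L) stop("occupancy is empty")
  stopifnot(beta > 0, lambda >= 0)

  if (method == "independent") {
    p <- (colSums(X) + pseudocount) / (tt + 2 * pseudocount)
    h <- atanh(2 * p - 1) / beta
    model <- .new_replica(h, matrix(0, n, n), beta, node_ids, is_null = TRUE,
                          fit_meta = list(method = "independent",
                                          lambda = 0, converged = TRUE,
                                          objective = NA_real_,
                                          train_frames = tt))
    return(model)
  }

  if (tt < 2L) stop("pseudolikelihood fit needs at least 2 frames")
  S <- 2 * X - 1
  storage.mode(S) <- "double"
  if (pseudocount > 0) {
    ones <- matrix(1, pseudocount, n)
    S <- rbind(S, ones, -ones)
  }
  tt_eff <- nrow(S)
  amat <- if (is.null(pairs)) !diag(n) > 0 else {
    pm <- cbind(match(pairs[, 1], node_ids), match(pairs[, 2], node_ids))
    if (anyNA(pm)) stop("pairs contain node ids absent from the occupancy")
    a <- matrix(FALSE, n, n)
    a[pm] <- TRUE; a[pm[, 2:1, drop = FALSE]] <- TRUE
    diag(a) <- FALSE
    a
  }
  h <- numeric(n)
  Jhat <- matrix(0, n, n)
  codes <- integer(n)
  obj <- 0
  for (i in seq_len(n)) {
    y <- S[, i]
    nbi <- which(amat[i, ])
    Fm <- S[, nbi, drop = FALSE]
    fn <- function(th) {
      f <- th[1] + drop(Fm %*% th[-1])
      z <- -2 * y * f
      nll <- ifelse(z > 30, z, log1p(exp(z)))
      mean(nll) + lambda * sum(th[-1]^2)
    }
    gr <- function(th) {
      f <- th[1] + drop(Fm %*% th[-1])
      z <- -2 * y * f
      w <- -2 * y * stats::plogis(z)
      c(mean(w), drop(crossprod(Fm, w)) / tt_eff + 2 * lambda * th[-1])
    }
    fit <- stats::optim(numeric(length(nbi) + 1L), fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    h[i] <- fit$par[1]
    Jhat[i, nbi] <- fit$par[-1]
    codes[i] <- fit$convergence
    obj <- obj + fit$value
  }
  J <- (Jhat + t(Jhat)) / 2
  diag(J) <- 0
  .new_replica(h, J, beta, node_ids, is_null = FALSE,
               fit_meta = list(method = "pseudolikelihood", lambda = lambda,
                               converged = all(codes == 0L),
                               objective = obj, train_frames = tt))
}

.new_replica <- function(h, J, beta, node_ids, is_null, fit_meta) {
  stopifnot(length(h) == nrow(J), nrow(J) == ncol(J), beta > 0,
            isTRUE(all.equal(J, t(J))), all(diag(J) == 0))
  if (is_null) stopifnot(all(J == 0))
  structure(list(h = as.numeric(h), J = J, beta = beta,
                 node_ids = as.integer(node_ids), is_null = is_null,
                 fit_meta = fit_meta),
            class = "ant_replica")
}

#' Create a pairwise replica from explicit parameters
#'
#' Constructor used for simulation studies and oracles: wraps given fields
#' and couplings into an `ant_replica` without fitting.
#'
#' @param h numeric fields.
#' @param J symmetric coupling matrix with zero diagonal (default all zero).
#' @param beta inverse temperature, default 1.
#' @param node_ids node labels, default `seq_along(h)`.
#' @return An `ant_replica`.
#' @export
replica <- function(h, J = NULL, beta = 1, node_ids = seq_along(h)) {
  n <- length(h)
  if (is.null(J)) J <- matrix(0, n, n)
  .new_replica(h, J, beta, node_ids, is_null = all(J == 0),
               fit_meta = list(method = "manual", lambda = NA,
                               converged = NA, objective = NA_real_,
                               train_frames = 0L))
}

#' @export
print.ant_replica <- function(x, ...) {
  n <- length(x$h)
  cat("Pairwise maximum-entropy replica (", n, " nodes, beta = ", x$beta,
      if (x$is_null) ", null model J = 0" else "", ")\n", sep = "")
  cat("  fit: ", x$fit_meta$method,
      if (!is.null(x$fit_meta$train_frames))
        paste0(", ", x$fit_meta$train_frames, " training frames"),
      if (isFALSE(x$fit_meta$converged)) " [NOT converged]", "\n", sep = "")
  cat("  h in [", signif(min(x$h), 3), ", ", signif(max(x$h), 3),
      "]; |J| mean ", signif(mean(abs(x$J[upper.tri(x$J)])), 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.ant_replica <- function(object, ...) {
  ut <- upper.tri(object$J)
  out <- list(
    n_nodes = length(object$h),
    beta = object$beta,
    is_null = object$is_null,
    h_summary = summary(object$h),
    J_summary = summary(object$J[ut]),
    frac_positive_J = mean(object$J[ut] > 0),
    fit_meta = object$fit_meta
  )
  class(out) <- "summary.ant_replica"
  out
}

#' @export
print.summary.ant_replica <- function(x, ...) {
  cat("Pairwise maximum-entropy replica:", x$n_nodes, "nodes, beta =",
      x$beta, if (x$is_null) "(null model)" else "", "\n")
  cat("Fields h:\n"); print(x$h_summary)
  cat("Couplings J (off-diagonal):\n"); print(x$J_summary)
  cat("Fraction of positive couplings:", signif(x$frac_positive_J, 3), "\n")
  invisible(x)
}

#' @export
coef.ant_replica <- function(object, ...) {
  list(h = object$h, J = object$J, beta = object$beta)
}

#' @export
plot.ant_replica <- function(x, arena = NULL, ...) {
  if (!is.null(arena)) {
    stopifnot(inherits(arena, "hex_arena"))
    sc <- (x$h - min(x$h)) / (diff(range(x$h)) + 1e-12)
    plot(arena$nodes$x[x$node_ids], arena$nodes$y[x$node_ids], asp = 1,
         pch = 16, cex = 0.4 + 1.6 * sc,
         col = grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)[
           pmax(1, ceiling(100 * sc))],
         xlab = "x (mm)", ylab = "y (mm)",
         main = "replica fields h by node", ...)
  } else {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::hist(x$h, main = "fields h", xlab = "h", ...)
    graphics::hist(x$J[upper.tri(x$J)], main = "couplings J", xlab = "J", ...)
  }
  invisible(x)
}

# map configurations (0/1 or +/-1; vector or matrix) to a spin matrix
.as_spin_matrix <- function(configuration, n) {
  m <- if (is.matrix(configuration)) configuration
    else matrix(configuration, nrow = 1)
  if (ncol(m) != n) stop("configuration dimension mismatch: expected ", n)
  u <- unique(as.vector(m))
  if (all(u %in% c(0, 1))) m <- 2 * m - 1
  else if (!all(u %in% c(-1, 1)))
    stop("configurations must be in {0,1} or {-1,+1}")
  storage.mode(m) <- "double"
  m
}

#' Score (log unnormalised probability) of configurations under a replica
#'
#' Returns `beta * (h . sigma + sum_{i<j} J_ij sigma_i sigma_j)` for each
#' configuration; the log-probability is this score minus `log Z`, which is
#' only computable at small N (see [exact_distribution()]).
#'
#' @param model an `ant_replica`.
#' @param configuration a configuration vector or matrix (rows =
#'   configurations) in 0/1 or -1/+1 coding.
#' @return Numeric vector of scores.
#' @export
replica_score <- function(model, configuration) {
  stopifnot(inherits(model, "ant_replica"))
  S <- .as_spin_matrix(configuration, length(model$h))
  model$beta * (drop(S %*% model$h) + 0.5 * rowSums((S %*% model$J) * S))
}

#' @export
predict.ant_replica <- function(object, newdata,
                                type = c("score", "logprob"), ...) {
  type <- match.arg(type)
  sc <- replica_score(object, newdata)
  if (type == "score") return(sc)
  sc - exact_distribution(object)$logZ
}

#' Exact distribution of a small replica by enumeration
#'
#' Enumerates all `2^N` configurations (guarded to `N <= 20`) and returns
#' their probabilities and the partition function — the oracle against
#' which the Glauber sampler and inference are validated.
#'
#' @param model an `ant_replica` with at most 20 nodes.
#' @return List with `states` (2^N x N 0/1 matrix), `prob`, `logZ`, `Z`.
#' @export
exact_distribution <- function(model) {
  stopifnot(inherits(model, "ant_replica"))
  n <- length(model$h)
  if (n > 20L) stop("exact enumeration refused for N > 20")
  m <- 2L^n
  states <- matrix(0L, m, n)
  for (j in seq_len(n))
    states[, j] <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  sc <- replica_score(model, states)
  logZ <- max(sc) + log(sum(exp(sc - max(sc))))
  list(states = states, prob = exp(sc - logZ), logZ = logZ, Z = exp(logZ))
}

#' Sample equilibrium configurations with Glauber dynamics
#'
#' Single-site heat-bath Monte Carlo: one sweep updates all N sites once in
#' random order, each site set occupied with its conditional probability
#' under the model. Samples are recorded after `burn_in_sweeps`, spaced
#' `thin_sweeps` apart.
#'
#' @param model an `ant_replica`.
#' @param n_samples number of configurations to return.
#' @param burn_in_sweeps sweeps discarded before sampling.
#' @param thin_sweeps sweeps between recorded samples.
#' @param init initial configuration (0/1 or -1/+1); default all empty.
#' @param seed integer seed (fully determines the output).
#' @return `n_samples` x N integer 0/1 matrix.
#' @export
sample_replica <- function(model, n_samples, burn_in_sweeps = 200,
                           thin_sweeps = 1, init = NULL, seed = 1L) {
  stopifnot(inherits(model, "ant_replica"), n_samples >= 1)
  n <- length(model$h)
  init <- if (is.null(init)) rep(-1L, n)
    else as.integer(.as_spin_matrix(init, n)[1, ])
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- .glauber_sample_cpp(model$h, model$J, model$beta,
                             as.integer(n_samples),
                             as.integer(burn_in_sweeps),
                             as.integer(thin_sweeps), init)
  colnames(out) <- model$node_ids
  out
}

#' @export
simulate.ant_replica <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  sample_replica(object, n_samples = nsim, seed = seed, ...)
}

#' Goodness of fit of a replica against occupancy data
#'
#' Samples the model and compares (a) per-node mean occupancies and (b)
#' per-pair connected correlations `cov(I_i, I_j)` between data and model,
#' summarised by RMSE and Pearson correlation.
#'
#' @param model an `ant_replica`.
#' @param occupancy the `occupancy_matrix` to compare against.
#' @param n_samples Monte Carlo sample size.
#' @param seed integer seed.
#' @param burn_in_sweeps,thin_sweeps passed to [sample_replica()].
#' @return List of class `replica_gof` with per-node and per-pair vectors
#'   and summary discrepancies.
#' @export
goodness_of_fit <- function(model, occupancy, n_samples = 2000, seed = 1L,
                            burn_in_sweeps = 200, thin_sweeps = 2) {
  stopifnot(inherits(model, "ant_replica"),
            inherits(occupancy, "occupancy_matrix"))
  if (!identical(as.integer(model$node_ids),
                 as.integer(occupancy$node_ids)))
    stop("model and occupancy node ids differ")
  X <- occupancy$values
  storage.mode(X) <- "double"
  Y <- sample_replica(model, n_samples, burn_in_sweeps, thin_sweeps,
                      seed = seed)
  storage.mode(Y) <- "double"
  ut <- upper.tri(diag(ncol(X)))
  occ_data <- colMeans(X); occ_model <- colMeans(Y)
  cov_data <- stats::cov(X)[ut]; cov_model <- stats::cov(Y)[ut]
  structure(list(
    occupancy_data = occ_data, occupancy_model = occ_model,
    corr_data = cov_data, corr_model = cov_model,
    rmse_occupancy = sqrt(mean((occ_data - occ_model)^2)),
    cor_occupancy = stats::cor(occ_data, occ_model),
    rmse_corr = sqrt(mean((cov_data - cov_model)^2)),
    cor_corr = suppressWarnings(stats::cor(cov_data, cov_model)),
    n_samples = n_samples
  ), class = "replica_gof")
}

#' @export
print.replica_gof <- function(x, ...) {
  cat("Replica goodness of fit (", x$n_samples, " samples)\n", sep = "")
  cat("  node occupancies: r = ", signif(x$cor_occupancy, 3),
      ", RMSE = ", signif(x$rmse_occupancy, 3), "\n", sep = "")
  cat("  pair correlations: r = ", signif(x$cor_corr, 3),
      ", RMSE = ", signif(x$rmse_corr, 3), "\n", sep = "")
  invisible(x)
}

#' Equilibrium occupancy as a function of the inverse temperature
#'
#' For each value on the grid, runs Glauber dynamics with the model's
#' parameters scaled by that `beta` and records the mean fraction of
#' occupied nodes. Occupancy grows as `beta` decreases (towards the
#' infinite-temperature value 1/2) — the handle used to match a null
#' replica's overall activity to the full replica's.
#'
#' @param model an `ant_replica`.
#' @param beta_grid positive values of beta to scan.
#' @param n_samples samples per grid point.
#' @param seed integer seed.
#' @param burn_in_sweeps,thin_sweeps passed to [sample_replica()].
#' @return Data frame `beta`, `occupancy`, `se` (batch-mean standard
#'   error).
#' @export
occupancy_vs_beta <- function(model, beta_grid = c(0.5, 0.75, 1, 1.25, 1.5),
                              n_samples = 2000, seed = 1L,
                              burn_in_sweeps = 200, thin_sweeps = 2) {
  stopifnot(all(beta_grid > 0))
  res <- lapply(seq_along(beta_grid), function(k) {
    m <- model; m$beta <- beta_grid[k]
    Y <- sample_replica(m, n_samples, burn_in_sweeps, thin_sweeps,
                        seed = seed + k)
    frac <- rowMeans(Y)
    data.frame(beta = beta_grid[k], occupancy = mean(frac),
               se = .batch_se(frac))
  })
  do.call(rbind, res)
}

# batch-means standard error, robust to autocorrelation in the chain
.batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  n_batches <- min(n_batches, n)
  bm <- tapply(x, ceiling(seq_along(x) / (n / n_batches)), mean)
  stats::sd(bm) / sqrt(length(bm))
}

#' Calibrate beta to reach a target occupancy
#'
#' Bisection on `beta` until the model's equilibrium mean occupancy is
#' within `tol` of the target, exploiting the monotone decrease of
#' occupancy in `beta`. Used to put a null (J = 0) replica on the same
#' overall activity as the full replica before efficiency comparisons.
#'
#' @param model an `ant_replica`.
#' @param target_occupancy target mean fraction of occupied nodes, in (0,1).
#' @param tol occupancy tolerance, default 0.005.
#' @param seed integer seed.
#' @param bracket search interval for beta.
#' @param n_samples Monte Carlo samples per evaluation.
#' @param max_iter bisection cap.
#' @return The calibrated `beta` (scalar).
#' @export
calibrate_beta <- function(model, target_occupancy, tol = 0.005, seed = 1L,
                           bracket = c(0.2, 3), n_samples = 3000,
                           max_iter = 30) {
  stopifnot(target_occupancy > 0, target_occupancy < 1)
  occ_at <- function(b, k) {
    m <- model; m$beta <- b
    mean(sample_replica(m, n_samples, burn_in_sweeps = 200, thin_sweeps = 1,
                        seed = seed + k))
  }
  lo <- bracket[1]; hi <- bracket[2]
  occ_lo <- occ_at(lo, 0L); occ_hi <- occ_at(hi, 1L)
  if (target_occupancy > occ_lo + tol || target_occupancy < occ_hi - tol)
    stop("target occupancy ", target_occupancy,
         " outside achievable range [", signif(occ_hi, 3), ", ",
         signif(occ_lo, 3), "] on the bracket")
  b <- NA_real_
  for (k in seq_len(max_iter)) {
    b <- (lo + hi) / 2
    occ <- occ_at(b, 1L + k)
    if (abs(occ - target_occupancy) <= tol) return(b)
    if (occ > target_occupancy) lo <- b else hi <- b
  }
  b
}

#' Fraction of total correlations captured by pairwise structure
#'
#' On a small node subset (exact enumeration regime), computes the
#' multi-information of the empirical joint, `I_N = sum_i H(I_i) - H(I)`,
#' and the share captured by the best pairwise maximum-entropy fit,
#' `I_2 = sum_i H(I_i) - H(P2)`, where `P2` matches all empirical single
#' and pair marginals (found by iterative proportional fitting). The ratio
#' `I_2 / I_N` lies in [0, 1] up to estimation noise: 1 when pairwise
#' structure explains everything (any 2-node subset), 0 for purely
#' higher-order dependence (e.g. the 3-node parity distribution).
#'
#' @param occupancy an `occupancy_matrix` or plain 0/1 matrix.
#' @param node_subset columns (2 to 10 of them) to analyse.
#' @param max_ipf_iter,tol iterative-proportional-fitting controls.
#' @return Scalar ratio in [0, 1]; 1 by convention when `I_N` is zero.
#' @export
pairwise_fraction <- function(occupancy, node_subset, max_ipf_iter = 200,
                              tol = 1e-8) {
  X <- if (inherits(occupancy, "occupancy_matrix")) occupancy$values
    else as.matrix(occupancy)
  k <- length(node_subset)
  if (k < 2L) stop("need at least 2 nodes")
  if (k > 10L) stop("subset too large for exact enumeration (max 10)")
  Xs <- X[, node_subset, drop = FALSE]
  m <- 2L^k
  idx <- drop(Xs %*% 2L^(seq_len(k) - 1L)) + 1L
  p <- tabulate(idx, nbins = m) / nrow(Xs)
  B <- matrix(0L, m, k)
  for (j in seq_len(k))
    B[, j] <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L

  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H_marg <- sum(vapply(seq_len(k), function(j)
    H(c(sum(p[B[, j] == 1]), sum(p[B[, j] == 0]))), numeric(1)))
  I_N <- H_marg - H(p)
  if (I_N < 1e-12) return(1.0)

  pairs <- utils::combn(k, 2)
  pair_cell <- lapply(seq_len(ncol(pairs)), function(q)
    B[, pairs[1, q]] + 2L * B[, pairs[2, q]] + 1L)
  pair_target <- lapply(seq_len(ncol(pairs)), function(q)
    vapply(1:4, function(cc) sum(p[pair_cell[[q]] == cc]), numeric(1)))

  q <- rep(1 / m, m)
  for (it in seq_len(max_ipf_iter)) {
    delta <- 0
    for (pq in seq_len(ncol(pairs))) {
      cells <- pair_cell[[pq]]
      cur <- vapply(1:4, function(cc) sum(q[cells == cc]), numeric(1))
      delta <- max(delta, max(abs(cur - pair_target[[pq]])))
      ratio <- ifelse(cur > 0, pair_target[[pq]] / cur, 0)
      q <- q * ratio[cells]
    }
    q <- q / sum(q)
    if (delta < tol) break
  }
  I_2 <- H_marg - H(q)
  I_2 / I_N
}


#' Node pairs within a channel-graph neighbourhood
#'
#' Returns the unordered node-id pairs at graph distance at most `max_hops`
#' on the arena's channel graph — the natural coupling support for spatial
#' pairwise models of lattice occupancy.
#'
#' @param arena a `hex_arena`.
#' @param max_hops neighbourhood radius in channels, default 2.
#' @return Two-column integer matrix of node-id pairs.
#' @export
adjacency_pairs <- function(arena, max_hops = 2) {
  stopifnot(inherits(arena, "hex_arena"), max_hops >= 1)
  gd <- igraph::distances(arena$graph)
  w <- which(gd <= max_hops & upper.tri(gd), arr.ind = TRUE)
  unname(w)
}

#' Recalibrate replica fields to match observed node occupancies
#'
#' Holds the couplings fixed and adjusts the fields by stochastic
#' approximation: at each iteration the model is sampled with a persistent
#' Glauber chain and each field moves along the gap between the smoothed
#' data magnetisation and the model's. This pins the replica's equilibrium
#' node occupancies to the data (the first moment-matching condition of
#' maximum-likelihood training), correcting the residual bias of the
#' pseudolikelihood couplings under model misspecification.
#'
#' @param model an `ant_replica`.
#' @param occupancy the training `occupancy_matrix`.
#' @param pseudocount Laplace smoothing of the target means.
#' @param n_iter stochastic-approximation iterations.
#' @param n_samples Glauber samples per iteration.
#' @param learn_rate initial learning rate (decays harmonically).
#' @param seed integer seed.
#' @return The model with updated fields; `fit_meta$recalibrated` is set.
#' @export
recalibrate_fields <- function(model, occupancy, pseudocount = 1,
                               n_iter = 250, n_samples = 150,
                               learn_rate = 0.3, seed = 1L) {
  stopifnot(inherits(model, "ant_replica"),
            inherits(occupancy, "occupancy_matrix"))
  X <- occupancy$values
  n <- ncol(X)
  if (n != length(model$h)) stop("model and occupancy dimensions differ")
  Xs <- rbind(X, matrix(1, pseudocount, n), matrix(0, pseudocount, n))
  m_target <- colMeans(2 * Xs - 1)
  h <- model$h
  state <- rep(-1L, n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    eta <- learn_rate / (1 + it / 100)
    Y <- .glauber_sample_cpp(h, model$J, model$beta, as.integer(n_samples),
                             3L, 1L, state)
    state <- as.integer(2L * Y[nrow(Y), ] - 1L)
    h <- h + eta * (m_target - colMeans(2 * Y - 1))
  }
  model$h <- h
  model$fit_meta$recalibrated <- TRUE
  model
}
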