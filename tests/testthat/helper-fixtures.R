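# Shared fixtures and independent oracles.  Fixtures are generated in
# code and memoised so multiple test files reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_pop <- function(species = "C", n = 12, L = 40, seed = 42) {
  key <- paste("pop", species, n, L, seed, sep = "_")
  cached(key, simulate_population(
    n_cells = n, proportions = setNames(1, species), n_frames = L, seed = seed
  ))
}

# Brute-force library evaluation: double loop over frames and pairs,
# independent of the C++ kernel.
brute_theta <- function(data, focal, library = force_library(), eps_v = 1e-12) {
  td <- cellswarm:::as_traj_mats(data)
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  i <- match(focal, td$ids)
  L <- td$L; N <- td$n; J <- nrow(library)
  alpha <- attr(library, "alpha")
  theta <- matrix(0, 2 * L, J)
  for (k in seq_len(L)) {
    vi <- c(V$vx[k, i], V$vy[k, i])
    si <- sqrt(sum(vi^2))
    for (j in seq_len(N)) {
      if (j == i) next
      disp <- c(td$px[k, j] - td$px[k, i], td$py[k, j] - td$py[k, i])
      r <- sqrt(sum(disp^2))
      ang <- pairwise_angle(vi, disp, eps_v)
      for (col in seq_len(J)) {
        blk <- library$block[col]; n <- library$n[col]; l <- library$ell[col]
        cn <- ang$cosn[n + 1]
        if (blk == "ar") {
          val <- cn * laguerre_polynomials(alpha * r, l)[, l + 1] *
            exp(-alpha * r / 2)
          vecpart <- -disp          # x_i - x_j
        } else if (blk == "align") {
          val <- (1 + cn) * exp(-2 * l * r)
          vecpart <- c(vi[1] - V$vx[k, j], vi[2] - V$vy[k, j])
        } else {
          val <- (1 + cn) * si^l
          vecpart <- vi
        }
        theta[k, col] <- theta[k, col] + val * vecpart[1] / N
        theta[L + k, col] <- theta[L + k, col] + val * vecpart[2] / N
      }
    }
  }
  theta
}

# A sparse constraint-feasible in-library ground truth.  The
# attraction-repulsion part uses the two-term combination
# amp * (20 p_0 + p_1)(alpha r) e^{-(alpha/2) r}, which is repulsive
# near zero (value 21 amp) and attractive beyond r = 21/36; alignment
# and drag carry non-positive coefficients.
random_sparse_model <- function(library, seed) {
  J <- nrow(library)
  col_of <- function(blk, n, l) {
    library$column[library$block == blk & library$n == n & library$ell == l]
  }
  withr::with_seed(seed, {
    w <- rep(0, J)
    if (runif(1) < 0.7) {
      n_ar <- sample(c(0, 2), 1)
      amp <- runif(1, 0.5, 1.2)
      w[col_of("ar", n_ar, 0)] <- 20 * amp
      w[col_of("ar", n_ar, 1)] <- amp
    }
    w[col_of("align", sample(0:2, 1), sample(1:2, 1))] <- -runif(1, 4, 9)
    w[col_of("drag", 0, sample(1:2, 1))] <- -runif(1, 1.5, 4)
    w
  })
}

# Support recovery is only well-posed when every true term contributes
# detectably to the response: dropping any single term and refitting
# the rest must leave a relative residual above `thresh` (otherwise the
# sparser model is the legitimate optimum of the L0 objective).
identifiable_in <- function(ws, w_true, thresh = 0.06) {
  S <- which(w_true != 0)
  b <- ws$G %*% w_true
  nb <- sqrt(sum(b^2))
  for (j in S) {
    S2 <- setdiff(S, j)
    G2 <- ws$G[, S2, drop = FALSE]
    res <- b - G2 %*% qr.solve(G2, b)
    if (sqrt(sum(res^2)) / nb < thresh) return(FALSE)
  }
  TRUE
}

# A weak system assembled from benchmark data, reused to manufacture
# consistent right-hand sides b = G w_true.
manufactured_system <- function() {
  cached("manufactured_ws", {
    d <- simulate_population(n_cells = 40, proportions = c(A = 1),
                             n_frames = 150, seed = 61)
    td <- cellswarm:::as_traj_mats(d)
    cfg <- swarm_config(m = 31, p = 8)
    state <- cellswarm:::learning_state(td, cfg)
    theta <- cellswarm:::cpp_eval_library(td$px, td$py, state$vx, state$vy,
                                          0L, state$terms, cfg$alpha,
                                          cfg$eps_v)
    ws <- assemble_weak_system(cbind(td$px[, 1], td$py[, 1]), theta,
                               state$basis, td$dt)
    list(ws = ws, state = state, cfg = cfg)
  })
}

# Draw `n` identifiable sparse feasible models and check sweep recovery;
# returns the number recovered exactly (support match and coefficients
# to 1e-2 relative).
count_exact_recoveries <- function(n = 10) {
  hit <- .fixture_cache[[paste0("recoveries_", n)]]
  if (!is.null(hit)) return(hit)
  ms <- manufactured_system()
  lib <- ms$state$library
  n_ok <- 0
  tested <- 0
  seed <- 0
  while (tested < n) {
    seed <- seed + 1
    w_true <- random_sparse_model(lib, seed)
    if (max(ms$state$constraints$C %*% w_true) > 1e-10) next
    if (!identifiable_in(ms$ws, w_true)) next
    tested <- tested + 1
    ws <- ms$ws
    ws$b <- as.vector(ms$ws$G %*% w_true)
    ws$bnorm <- sqrt(sum(ws$b^2))
    fit <- sweep_lambda(ws, ms$state$constraints, ms$cfg$lambda_grid)
    rel <- sqrt(sum((fit$w - w_true)^2)) / sqrt(sum(w_true^2))
    if (identical(which(fit$w != 0), which(w_true != 0)) && rel < 1e-2) {
      n_ok <- n_ok + 1
    }
  }
  .fixture_cache[[paste0("recoveries_", n)]] <- n_ok
  n_ok
}
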