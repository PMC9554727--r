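# Thresholding, constrained sequential thresholding, and the sparsity
# sweep, including support recovery of in-library ground truths.

test_that("threshold operator implements the two-sided magnitude cut", {
  gnorm <- c(1, 1, 1, 1)
  bnorm <- 1
  w <- c(1e-5, 1e4, 0.5, 2)
  out <- threshold_coefficients(w, gnorm, bnorm, 1e-3)
  expect_equal(out, c(0, 0, 0.5, 2))   # below lambda and above 1/lambda cut
  expect_equal(threshold_coefficients(w, gnorm, 0, 1e-3), rep(0, 4))
  expect_error(threshold_coefficients(w, gnorm, bnorm, 0))
  expect_error(threshold_coefficients(w, gnorm, bnorm, 2))
})

test_that("constrained least squares matches a quadratic-programming oracle", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      m <- 30; n <- 6
      G <- matrix(rnorm(m * n), m, n)
      b <- rnorm(m)
      C <- rbind(diag(n), matrix(rnorm(2 * n), 2, n))
      d <- rep(0, nrow(C))
      fit <- cellswarm:::cpp_lsi(G, b, C, d)
      expect_lte(max(C %*% fit$w - d), 1e-8)
      # oracle: pracma's active-set quadratic program on the normal form
      o <- pracma::quadprog(crossprod(G), -as.vector(crossprod(G, b)),
                            A = C, b = d)
      expect_equal(as.vector(fit$w), as.vector(o$xmin), tolerance = 1e-6)
    }
  })
})

test_that("nnls solves small problems against an enumeration oracle", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      A <- matrix(rnorm(12), 6, 2)
      b <- rnorm(6)
      x <- cellswarm:::cpp_nnls(A, b)
      expect_true(all(x >= 0))
      # oracle: best over all sign-support candidates
      best <- Inf
      for (s1 in 0:1) for (s2 in 0:1) {
        keep <- which(c(s1, s2) == 1)
        xx <- rep(0, 2)
        if (length(keep) > 0) {
          sol <- qr.solve(A[, keep, drop = FALSE], b)
          if (any(sol < 0)) next
          xx[keep] <- sol
        }
        best <- min(best, sum((A %*% xx - b)^2))
      }
      expect_equal(sum((A %*% x - b)^2), best, tolerance = 1e-8)
    }
  })
})

test_that("mstls handles degenerate inputs and enforces feasibility", {
  d <- tiny_pop("C", n = 10, L = 90, seed = 55)
  td <- cellswarm:::as_traj_mats(d)
  cfg <- swarm_config(m = 31, p = 8)
  state <- cellswarm:::learning_state(td, cfg)
  theta <- evaluate_library(d, focal = 1, state$library)
  ws <- assemble_weak_system(cbind(td$px[, 1], td$py[, 1]), theta,
                             state$basis, td$dt)
  # b = 0 -> w = 0
  ws0 <- ws; ws0$b <- 0 * ws$b; ws0$bnorm <- 0
  expect_equal(mstls(ws0, state$constraints, 1e-3), rep(0, 88))
  # feasibility of the solved model
  w <- mstls(ws, state$constraints, 1e-3)
  expect_lte(max(state$constraints$C %*% w), 1e-8)
  lib <- state$library
  expect_true(all(w[lib$column[lib$block %in% c("align", "drag")]] <= 0))
})

test_that("sparsity sweep exactly recovers identifiable in-library models", {
  # manufactured-solution oracle: the response is built as b = G w_true
  # from benchmark features, with every term of w_true contributing
  # detectably (support recovery is only well-posed then)
  expect_equal(count_exact_recoveries(10), 10)
})

test_that("a population simulated under an in-library model is relearned", {
  lib <- force_library()
  w_true <- rep(0, nrow(lib))
  w_true[lib$column[lib$block == "align" & lib$n == 1 & lib$ell == 4]] <- -8
  w_true[lib$column[lib$block == "drag" & lib$n == 0 & lib$ell == 1]] <- -2.5
  W <- matrix(w_true, nrow(lib), 30)
  d <- cellswarm:::simulate_library_model(W, lib, n_frames = 150, dt = 0.05,
                                          seed = 777, radius = 0.3)
  cfg <- swarm_config(m = 31, p = 8)
  mods <- learn_models(d, cfg, cells = 1:6)
  # individual models vary; the pipeline relies on the majority code
  codes <- table(mods$code)
  expect_equal(names(which.max(codes)), force_mode_code(w_true, lib))
  expect_gte(max(codes), 5)
  err <- sqrt(colSums((mods$W[, 1:6] - w_true)^2)) / sqrt(sum(w_true^2))
  expect_lt(median(err), 1e-2)
})

test_that("learning is deterministic and validates focal ids", {
  d <- tiny_pop("C", n = 8, L = 80, seed = 71)
  cfg <- swarm_config(m = 31, p = 8)
  f1 <- learn_cell_model(d, 3, cfg)
  f2 <- learn_cell_model(d, 3, cfg)
  expect_identical(f1$w, f2$w)
  expect_error(learn_cell_model(d, 99, cfg), "not found")
})

test_that("single-species learning finds the correct force modes", {
  d <- tiny_pop("C", n = 30, L = 150, seed = 81)
  cfg <- swarm_config(m = 31, p = 8)
  mods <- learn_models(d, cfg, cells = 1:6)
  lib <- mods$library
  for (k in 1:6) {
    w <- mods$W[, k]
    # alignment and drag present, attraction-repulsion absent
    expect_true(any(w[lib$column[lib$block == "align"]] != 0))
    expect_true(any(w[lib$column[lib$block == "drag"]] != 0))
    expect_equal(sum(w[lib$column[lib$block == "ar"]] != 0), 0)
  }
})
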