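# Data-driven validation simulations, the error metric, the Gaussian
# mixture classifier, and stopping decisions.

test_that("zero model yields straight-line motion and exact node replay", {
  d <- tiny_pop("C", n = 6, L = 40, seed = 101)
  td <- cellswarm:::as_traj_mats(d)
  out <- simulate_cell(rep(0, 88), d, focal = 2)
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  # x(t) = x(0) + t v(0) exactly under forward Euler with zero force
  tt <- out$sim$t
  expect_equal(out$sim$x, td$px[1, 2] + tt * V$vx[1, 2], tolerance = 1e-12)
  expect_equal(out$sim$y, td$py[1, 2] + tt * V$vy[1, 2], tolerance = 1e-12)
  expect_true(out$dv >= 0)

  # neighbour interpolants hit the data exactly at the coarse frames
  cfg <- swarm_config()
  setup <- cellswarm:::validation_setup(td, cfg)
  nodes <- seq(1, nrow(setup$FX), by = setup$nsub)
  expect_equal(setup$FX[nodes, ], td$px[seq_len(setup$Lp), ], tolerance = 1e-12)
  expect_equal(setup$FVX[nodes, ], V$vx[seq_len(setup$Lp), ], tolerance = 1e-12)
})

test_that("validation error metric matches hand values", {
  v <- cbind(c(1, 1), c(0, 0))
  expect_equal(validation_error(v, v), 0)
  expect_equal(validation_error(0 * v, v), 1)
  v_sim <- cbind(c(1, 0), c(0, 0))
  expect_equal(validation_error(v_sim, v, 2), 0.5)
  expect_error(validation_error(v, 0 * v), "zero")
  expect_error(validation_error(v, v, 5), "exceeds")
})

test_that("the true model validates its own cells accurately", {
  d <- tiny_pop("C", n = 25, L = 120, seed = 103)
  lib <- force_library()
  w_true <- rep(0, 88)
  w_true[lib$column[lib$block == "align" & lib$n == 1 & lib$ell == 4]] <- -8
  w_true[lib$column[lib$block == "drag" & lib$n == 0 & lib$ell == 1]] <- -2.5
  dv <- purrr::map_dbl(1:10, function(i) simulate_cell(w_true, d, i)$dv)
  expect_lt(median(dv), 0.05)
  expect_gt(mean(dv < 0.05), 0.8)
})

test_that("validation error is invariant under rigid translation", {
  d <- tiny_pop("A", n = 8, L = 40, seed = 105)
  lib <- force_library()
  w <- rep(0, 88)
  w[lib$column[lib$block == "drag" & lib$n == 0 & lib$ell == 1]] <- -2.5
  dv1 <- simulate_cell(w, d, 3)$dv
  shifted <- dplyr::mutate(d, x = .data$x + 5, y = .data$y - 2)
  dv2 <- simulate_cell(w, shifted, 3)$dv
  expect_equal(dv1, dv2, tolerance = 1e-9)
})

test_that("halving the fine step changes the error at first order", {
  d <- tiny_pop("C", n = 10, L = 60, seed = 107)
  lib <- force_library()
  w <- rep(0, 88)
  w[lib$column[lib$block == "align" & lib$n == 1 & lib$ell == 4]] <- -8
  w[lib$column[lib$block == "drag" & lib$n == 0 & lib$ell == 1]] <- -2.5
  traj_at <- function(ff) {
    simulate_cell(w, d, 4, swarm_config(fine_factor = ff))$sim
  }
  # compare simulated trajectories against a much finer reference so
  # the measured difference is the Euler discretisation error itself
  ref <- traj_at(512)
  err <- function(ff) {
    s <- traj_at(ff)
    max(abs(s$vx - ref$vx), abs(s$vy - ref$vy))
  }
  e32 <- err(32); e64 <- err(64); e128 <- err(128)
  expect_gt(e32 / e64, 1.5)
  expect_lt(e32 / e64, 2.8)
  expect_gt(e64 / e128, 1.5)
})

test_that("gaussian mixture separates two well-separated error clouds", {
  withr::with_seed(11, {
    lo <- 10^rnorm(60, -4, 0.3)
    hi <- 10^rnorm(40, -1, 0.3)
    ve <- c(lo, hi)
  })
  cls <- classify_gmm(ve, n_gmm = 10, seed = 2)
  expect_equal(cls$species, rep(c(TRUE, FALSE), c(60, 40)))
  # infinite sentinels always land outside the species
  cls2 <- classify_gmm(c(ve, Inf, Inf), n_gmm = 5, seed = 2)
  expect_equal(tail(cls2$species, 2), c(FALSE, FALSE))
  # determinism under a fixed seed
  cls3 <- classify_gmm(ve, n_gmm = 10, seed = 2)
  expect_identical(cls$posterior, cls3$posterior)
  # all-equal errors: single-cluster fallback, everything is the species
  cls4 <- classify_gmm(rep(0.01, 10), seed = 1)
  expect_true(cls4$degenerate)
  expect_true(all(cls4$species))
  expect_error(classify_gmm(c(0.1, Inf), seed = 1), "finite")
})

test_that("the mixture agrees with an established EM implementation", {
  withr::with_seed(17, {
    x <- c(rnorm(80, -4, 0.4), rnorm(50, -1.5, 0.5))
  })
  cls <- classify_gmm(10^x, n_gmm = 10, seed = 3)
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ours <- ifelse(cls$species, 1, 2)
  theirs <- ifelse(mc$classification == which.min(mc$parameters$mean), 1, 2)
  expect_gt(mean(ours == theirs), 0.95)
})

test_that("stopping decisions fire in the documented order", {
  cfg <- swarm_config()
  expect_equal(stopping_decision(1, NULL, 0, cfg), "stop_outliers")
  expect_equal(stopping_decision(100, rep(0.01, 100), 1, cfg), "stop_threshold")
  expect_equal(stopping_decision(100, rep(0.5, 100), 10, cfg),
               "stop_max_species")
  expect_equal(stopping_decision(100, rep(0.5, 100), 2, cfg), "continue")
  # threshold condition needs at least 99% below 5% error
  ve <- c(rep(0.01, 98), 0.5, 0.6)
  expect_equal(stopping_decision(100, ve, 0, cfg), "continue")
  ve2 <- c(rep(0.01, 99), 0.5)
  expect_equal(stopping_decision(100, ve2, 0, cfg), "stop_threshold")
})
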