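# Ground-truth forces, angle conventions, and the population simulator.

test_that("ground-truth forces match their closed forms", {
  expect_equal(true_force("ar", 0.1, 0), 25 * (exp(-2) - 0.25 * exp(-1)),
               tolerance = 1e-12)
  # root of the radial kernel: e^{-20r} = 0.25 e^{-10r} at r = ln(4)/10
  expect_equal(true_force("ar", log(4) / 10, 1.234), 0, tolerance = 1e-12)
  expect_equal(true_force("align", 0.7, pi), 0, tolerance = 1e-12)
  expect_equal(true_force("drag", 0), 0)
  expect_equal(true_force("drag", 0.3, 2), -1.5)
  expect_error(true_force("bogus", 1))
  expect_error(true_force("ar", -0.1))
})

test_that("pairwise angle and directional factors follow the convention", {
  a <- pairwise_angle(c(1, 0), c(2, 0))
  expect_equal(a$theta, 0)
  expect_equal(a$cosn, c(1, 1, 1))
  b <- pairwise_angle(c(1, 0), c(0, 3))
  expect_equal(b$theta, pi / 2)
  expect_equal(b$cosn, c(1, 0, -1), tolerance = 1e-14)
  # degenerate speed: anisotropic factors vanish by convention
  z <- pairwise_angle(c(0, 0), c(1, 1))
  expect_equal(z$cosn[2:3], c(0, 0))
  expect_error(pairwise_angle(c(1, 0), c(0, 0)))
})

test_that("cos(2 theta) is even and cos(theta) odd under disp -> -disp", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      v <- rnorm(2); d <- rnorm(2)
      a <- pairwise_angle(v, d)
      b <- pairwise_angle(v, -d)
      expect_equal(a$cosn[3], b$cosn[3], tolerance = 1e-12)
      expect_equal(a$cosn[2], -b$cosn[2], tolerance = 1e-12)
    }
  })
})

test_that("acceleration symmetries of the interaction model hold", {
  # two resting species-B cells: equal and opposite accelerations
  x <- rbind(c(0, 0), c(1, 0))
  v <- matrix(0, 2, 2)
  a <- acceleration_rhs(x, v, c("B", "B"))
  expect_equal(a[1, ], -a[2, ], tolerance = 1e-14)
  # at r = 1 the radial kernel is negative and multiplies (x_i - x_j),
  # so cell 1 accelerates towards cell 2 (positive x)
  expect_gt(a[1, 1], 0)

  # species C at rest stays at rest: all forces carry a velocity factor
  xc <- matrix(rnorm(10), 5, 2)
  ac <- acceleration_rhs(xc, matrix(0, 5, 2), rep("C", 5))
  expect_equal(max(abs(ac)), 0)

  # isotropic-mode momentum identity: with zero velocities only the n = 0
  # a-r mode acts, and the pairwise terms cancel over the population
  xs <- matrix(rnorm(16), 8, 2)
  as_ <- acceleration_rhs(xs, matrix(0, 8, 2), rep("B", 8))
  expect_equal(colSums(as_), c(0, 0), tolerance = 1e-13)

  expect_error(acceleration_rhs(rbind(c(0, 0), c(0, 0)), matrix(0, 2, 2),
                                c("B", "B")),
               "coincident")
})

test_that("two resting species-B cells at separation 1 attract", {
  d <- simulate_population(n_cells = 2, proportions = c(B = 1), n_frames = 3,
                           seed = 1)
  # override: place the two cells explicitly via the low-level simulator
  sim <- cellswarm:::cpp_simulate_true(
    c(-0.5, 0.5), c(0, 0), c(0, 0), c(0, 0),
    rep(1L, 2), rep(0L, 2), rep(1L, 2), 5L, 0.05, 8L, 100, 1e-12
  )
  sep <- abs(sim$px[, 2] - sim$px[, 1])
  expect_lt(sep[2], sep[1])     # kernel is negative at r = 1: attraction
  expect_true(all(diff(sep) < 0))
})

test_that("simulation is deterministic and stationary cases stay put", {
  d1 <- tiny_pop("C", n = 8, L = 10, seed = 3)
  d2 <- simulate_population(n_cells = 8, proportions = c(C = 1),
                            n_frames = 10, seed = 3)
  expect_identical(d1, d2)

  # species C started at rest never moves
  sim <- cellswarm:::cpp_simulate_true(
    rnorm(5), rnorm(5), rep(0, 5), rep(0, 5),
    rep(0L, 5), rep(1L, 5), rep(1L, 5), 8L, 0.05, 4L, 100, 1e-12
  )
  expect_equal(sim$px[8, ], sim$px[1, ], tolerance = 0)
  expect_equal(max(abs(sim$vx)), 0)
})

test_that("RK4 halving the substep changes positions at fourth order", {
  # a coarse frame interval keeps the integration error far above
  # roundoff so the convergence order is measurable
  # alignment + drag only: smooth nonlinear decay, no blow-up risk
  run <- function(sub) {
    cellswarm:::cpp_simulate_true(
      c(-0.3, 0.2, 0.05), c(0, 0.25, -0.2), c(0.3, -0.25, 0.1),
      c(0.25, 0.3, -0.2), rep(0L, 3), rep(1L, 3), rep(1L, 3),
      6L, 1.0, sub, 100, 1e-12
    )
  }
  ref <- run(256L)
  err <- function(sub) {
    s <- run(sub)
    max(abs(s$px[6, ] - ref$px[6, ]), abs(s$py[6, ] - ref$py[6, ]))
  }
  ratio <- err(1L) / err(2L)
  expect_gt(ratio, 10)
  expect_lt(ratio, 40)
})

test_that("simulator reports blow-ups with the offending cell", {
  expect_error(
    cellswarm:::cpp_simulate_true(
      c(0, 0.5), c(0, 0), c(5, 0), c(0, 0),
      rep(0L, 2), rep(0L, 2), rep(0L, 2), 50L, 1, 1L, 2, 1e-12
    ),
    "blow-up"
  )
})

test_that("trajectory CSV round-trips, tolerates shuffles, rejects bad grids", {
  d <- tiny_pop("B", n = 3, L = 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(d, path)
  back <- read_trajectory(path)
  expect_equal(back$x, d$x, tolerance = 1e-12)
  expect_equal(back$species, d$species)

  shuffled <- d[sample(nrow(d)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(shuffled, path2)
  expect_equal(read_trajectory(path2)$x, d$x, tolerance = 1e-12)

  bad <- d
  bad$t[bad$frame == 3] <- bad$t[bad$frame == 3] + 0.013
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad[c("cell_id", "frame", "t", "x", "y")], path3)
  expect_error(read_trajectory(path3), "uniform|increasing")

  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d[c("cell_id", "frame", "x", "y")], path4)
  expect_error(read_trajectory(path4), "missing")
})
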