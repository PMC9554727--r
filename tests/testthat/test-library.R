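# Force library structure, Laguerre orthogonality, and the feature
# evaluation kernel against a brute-force oracle.

test_that("library layout is the expected 88-term block structure", {
  lib <- force_library()
  expect_equal(nrow(lib), 88)
  expect_equal(sum(lib$block == "ar"), 54)
  expect_equal(sum(lib$block == "align"), 24)
  expect_equal(sum(lib$block == "drag"), 10)
  # column -> (block, n, ell) is a bijection
  expect_equal(anyDuplicated(lib[c("block", "n", "ell")]), 0)
  expect_equal(lib$column, seq_len(88))
})

test_that("weighted Laguerre polynomials are orthonormal", {
  # int_0^inf p_m p_n e^{-r} dr = delta_mn
  for (m in c(0, 1, 3, 7, 10)) {
    for (n in c(0, 2, 5, 10)) {
      val <- integrate(function(r) {
        P <- laguerre_polynomials(r, max(m, n))
        P[, m + 1] * P[, n + 1] * exp(-r)
      }, 0, Inf, rel.tol = 1e-10)$value
      expect_equal(val, as.numeric(m == n), tolerance = 1e-6)
    }
  }
})

test_that("library evaluation matches a brute-force pair loop", {
  d <- tiny_pop("A", n = 4, L = 12, seed = 21)
  lib <- force_library()
  fast <- evaluate_library(d, focal = 2, lib)
  slow <- brute_theta(d, focal = 2, lib)
  scale <- max(abs(slow))
  expect_lt(max(abs(fast - slow)) / scale, 1e-12)
})

test_that("library columns vanish in degenerate configurations", {
  # single-cell population: every pair sum is empty
  one <- tibble::tibble(cell_id = 1, frame = 1:10, t = (0:9) * 0.1,
                        x = (0:9) * 0.05, y = 0.3 * (0:9) * 0.05)
  th <- evaluate_library(one, focal = 1)
  expect_equal(max(abs(th)), 0)

  # rigid translation: all cells share velocity (0.1, 0), so every
  # alignment column is identically zero
  rigid <- dplyr::mutate(tiny_pop("B", n = 5, L = 12, seed = 23),
                         x = 0.3 * .data$cell_id + 0.1 * .data$t,
                         y = 0.2 * .data$cell_id)
  lib <- force_library()
  th2 <- evaluate_library(rigid, focal = 3, lib)
  align_cols <- lib$column[lib$block == "align"]
  expect_equal(max(abs(th2[, align_cols])), 0, tolerance = 1e-13)
})

test_that("finite-difference velocities are exact for polynomials", {
  L <- 20; dt <- 0.1
  tt <- (0:(L - 1)) * dt
  # affine: exact everywhere including endpoints
  px <- matrix(2 + 3 * tt); py <- matrix(-1 + 0.5 * tt)
  V <- finite_diff_velocity(px, py, dt)
  expect_equal(as.vector(V$vx), rep(3, L), tolerance = 1e-12)
  expect_equal(as.vector(V$vy), rep(0.5, L), tolerance = 1e-12)
  # quadratic: centred differences exact on interior frames
  px2 <- matrix(tt^2)
  V2 <- finite_diff_velocity(px2, px2, dt)
  expect_equal(V2$vx[2:(L - 1)], 2 * tt[2:(L - 1)], tolerance = 1e-12)
  expect_error(finite_diff_velocity(matrix(1:2), matrix(1:2), dt), "3 frames")
})

test_that("finite-difference error decays at second order", {
  err_at <- function(dt) {
    tt <- seq(0, 2, by = dt)
    px <- matrix(sin(tt))
    V <- finite_diff_velocity(px, px, dt)
    L <- length(tt)
    max(abs(V$vx[2:(L - 1)] - cos(tt[2:(L - 1)])))
  }
  ratio <- err_at(0.02) / err_at(0.01)
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.7)
})

test_that("near-field radius is the pooled pairwise distance quantile", {
  # all pairwise distances equal: static equilateral triangle, side 1
  tri <- tibble::tibble(
    cell_id = rep(1:3, each = 2), frame = rep(1:2, 3), t = rep(c(0, 1), 3),
    x = rep(c(0, 1, 0.5), each = 2),
    y = rep(c(0, 0, sqrt(3) / 2), each = 2)
  )
  expect_equal(near_field_radius(tri, 0.001), 1, tolerance = 1e-12)
  # quantile floor: p below 1/#distances gives the minimum distance
  d <- tiny_pop("B", n = 6, L = 10, seed = 31)
  td <- cellswarm:::as_traj_mats(d)
  dists <- c()
  for (k in seq_len(td$L)) {
    dists <- c(dists, as.vector(dist(cbind(td$px[k, ], td$py[k, ]))))
  }
  expect_equal(near_field_radius(d, 1e-9), min(dists), tolerance = 1e-12)
  # agreement with the sorted-distance definition at moderate p
  kth <- sort(dists)[max(1, ceiling(0.05 * length(dists)))]
  expect_equal(near_field_radius(d, 0.05), kth, tolerance = 1e-12)
  expect_error(near_field_radius(d, 1.5))
})
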