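# Cell statistics, KL divergence, validation-cell selection, and the
# replacement decision logic.

test_that("cell statistics are normalised histograms with shared edges", {
  d <- tiny_pop("B", n = 8, L = 30, seed = 91)
  st <- cell_statistics(d)
  expect_equal(colSums(st$rr), rep(1, 8), tolerance = 1e-12)
  expect_equal(colSums(st$vv), rep(1, 8), tolerance = 1e-12)
  expect_equal(colSums(st$v), rep(1, 8), tolerance = 1e-12)
  expect_true(all(st$rr >= 0))
  expect_equal(nrow(st$rr), 50)
})

test_that("constant-distance pair concentrates the distance histogram", {
  # x-coordinates exactly representable so finite differences are
  # exactly zero for the resting cells
  two <- tibble::tibble(
    cell_id = rep(1:2, each = 5), frame = rep(1:5, 2), t = rep((0:4) * 0.1, 2),
    x = c(rep(0, 5), rep(0.5, 5)), y = rep(0, 10)
  )
  st <- cell_statistics(two)
  expect_equal(max(st$rr[, 1]), 1)           # all mass in one bin
  # both cells are stationary: speed mass in the first bin
  expect_equal(st$v[1, ], c(1, 1))
})

test_that("KL divergence matches hand computation and is asymmetric", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-6)
  expect_equal(kl_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
                                kl_divergence(c(0.9, 0.1), c(0.5, 0.5)))))
  expect_error(kl_divergence(c(1), c(0.5, 0.5)), "bin")
  # empty reference bins stay finite through the pseudo-mass
  expect_true(is.finite(kl_divergence(c(0.5, 0.5), c(1, 0))))
})

test_that("validation-cell selection matches a brute-force ranking", {
  d <- tiny_pop("A", n = 10, L = 30, seed = 95)
  st <- cell_statistics(d)
  sel <- select_validation_cells(st, K = 4)
  expect_equal(dim(sel), c(10, 4))
  # brute force for one cell
  cost <- sapply(seq_len(10), function(j) {
    kl_divergence(st$rr[, 3], st$rr[, j])^2 +
      kl_divergence(st$vv[, 3], st$vv[, j])^2 +
      kl_divergence(st$v[, 3], st$v[, j])^2
  })
  cost[3] <- Inf
  expect_setequal(sel[3, ], order(cost, seq_len(10))[1:4])
  # K clamps to N - 1 and ties break by id
  sel_all <- select_validation_cells(st, K = 50)
  expect_equal(ncol(sel_all), 9)
  expect_error(select_validation_cells(st, K = 0))
})

test_that("identical statistics rank by cell id (tie-break)", {
  st <- list(rr = matrix(1 / 50, 50, 5), vv = matrix(1 / 50, 50, 5),
             v = matrix(1 / 50, 50, 5))
  sel <- select_validation_cells(st, K = 3)
  expect_equal(sel[1, ], c(2L, 3L, 4L))
  expect_equal(sel[5, ], c(1L, 2L, 3L))
})

test_that("replacement conditions and donor chains follow the rules", {
  # constructed pair: j = 2 qualifies to replace i = 1
  dv_self <- c(0.5, 0.1)
  dv_cross <- matrix(NA, 2, 2)
  dv_cross[2, 1] <- 0.1   # M2 on cell 1
  dv_cross[1, 2] <- 0.5   # M1 on cell 2
  mutual <- matrix(TRUE, 2, 2); diag(mutual) <- FALSE
  expect_equal(replacement_decisions(dv_self, dv_cross, mutual, tol = 0.25),
               c(2L, 2L))
  # condition 3 fails when the donor's errors are above tol
  expect_equal(replacement_decisions(dv_self, dv_cross, mutual, tol = 0.05),
               c(1L, 2L))
  # chain k -> j -> i: cell 1 ends with model 3 even though cells 1 and 3
  # are not mutual
  dv_self3 <- c(0.5, 0.2, 0.05)
  cross <- matrix(NA, 3, 3)
  cross[2, 1] <- 0.1; cross[1, 2] <- 0.6
  cross[3, 2] <- 0.05; cross[2, 3] <- 0.4
  mut <- matrix(FALSE, 3, 3)
  mut[1, 2] <- mut[2, 1] <- TRUE
  mut[2, 3] <- mut[3, 2] <- TRUE
  expect_equal(replacement_decisions(dv_self3, cross, mut, tol = 0.25),
               c(3L, 3L, 3L))
  # best donor wins: two qualifying donors, lower error on i chosen
  dv4 <- c(0.5, 0.1, 0.1, 0.1)
  cr <- matrix(NA, 4, 4)
  cr[2, 1] <- 0.2; cr[1, 2] <- 0.9
  cr[3, 1] <- 0.05; cr[1, 3] <- 0.9
  mu <- matrix(FALSE, 4, 4)
  mu[1, 2] <- mu[2, 1] <- mu[1, 3] <- mu[3, 1] <- TRUE
  expect_equal(replacement_decisions(dv4, cr, mu, tol = 0.25)[1], 3L)
  # no replacements when every model is best on its own cell
  none <- replacement_decisions(c(0.1, 0.1), matrix(0.2, 2, 2), mutual)
  expect_equal(none, c(1L, 2L))
})

test_that("replacement pass updates models and never hurts the recipient", {
  d <- tiny_pop("C", n = 20, L = 100, seed = 97)
  cfg <- swarm_config(m = 31, p = 8, K = 6)
  mods <- learn_models(d, cfg)
  mods2 <- replacement_pass(mods, d, cfg)
  log <- attr(mods2, "replacement_log")
  expect_true(tibble::is_tibble(log))
  if (nrow(log) > 0) {
    ok <- is.na(log$dv_after) | log$dv_after <= log$dv_before
    expect_true(all(ok))
  }
  # replaced columns equal their donor columns
  for (k in seq_len(nrow(log))) {
    i <- match(log$cell_id[k], mods2$cells)
    j <- match(log$replaced_by[k], mods2$cells)
    expect_identical(mods2$W[, i], mods2$W[, j])
  }
})
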