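# Weak-form sparse regression: per-cell linear systems, physical sign
# constraints, and constrained sequential-thresholding over a sparsity
# sweep.

#' Assemble the weak-form linear system for one focal cell
#'
#' Integrates the focal trajectory against the second derivatives of the
#' test functions (left-hand side) and the library features against the
#' test functions themselves (right-hand side), using the trapezoidal
#' rule on the frame grid.  Rows are stacked coordinate-major: all test
#' functions for x, then all for y.
#'
#' @param x_focal L x 2 matrix of the focal cell's positions.
#' @param theta Feature matrix from [evaluate_library()] (`2L x J`).
#' @param basis Test functions from [test_function_basis()].
#' @param dt Frame interval.
#' @return List with `G` (2Q x J), `b` (2Q), column norms `gnorm`, and
#'   `bnorm`.
#' @export
assemble_weak_system <- function(x_focal, theta, basis, dt) {
  L <- nrow(x_focal)
  stopifnot(nrow(theta) == 2 * L, ncol(basis$phi) == L)
  wt <- c(0.5, rep(1, L - 2), 0.5) * dt
  phiw <- basis$phi * rep(wt, each = basis$Q)
  phiddw <- basis$phidd * rep(wt, each = basis$Q)
  G <- rbind(phiw %*% theta[seq_len(L), , drop = FALSE],
             phiw %*% theta[L + seq_len(L), , drop = FALSE])
  b <- c(phiddw %*% x_focal[, 1], phiddw %*% x_focal[, 2])
  list(G = G, b = b, gnorm = sqrt(colSums(G^2)), bnorm = sqrt(sum(b^2)))
}

#' Physical sign constraints as a linear inequality system
#'
#' Encodes the force constraints as `C w <= d` with `d = 0`: alignment
#' and drag coefficients are elementwise non-positive (their basis
#' factors are non-negative), and the attraction-repulsion force is
#' constrained by collocation to be repulsive (`>= 0`) on a grid over
#' `(0, r_nf] x [0, pi]` and attractive (`<= 0`) on `[r_ff, r_max] x
#' [0, pi]`.
#'
#' @param library Library from [force_library()].
#' @param r_nf,r_ff Near- and far-field radii (`0 < r_nf < r_ff`).
#' @param r_max Maximum observed inter-cell distance.
#' @param n_r Collocation radii per region.
#' @param n_theta Collocation angles.
#' @return List with `C`, `d` and the collocation grids.
#' @export
build_constraints <- function(library, r_nf, r_ff, r_max,
                              n_r = 30, n_theta = 9) {
  if (r_ff <= r_nf) abort("r_ff must exceed r_nf")
  alpha <- attr(library, "alpha")
  J <- nrow(library)
  ar <- library[library$block == "ar", ]
  colloc_block <- function(radii, sgn) {
    thetas <- seq(0, pi, length.out = n_theta)
    grid <- tidyr::expand_grid(r = radii, th = thetas)
    lag <- laguerre_polynomials(alpha * grid$r, max(ar$ell))
    E <- exp(-alpha * grid$r / 2)
    B <- matrix(0, nrow(grid), J)
    for (k in seq_len(nrow(ar))) {
      cn <- cos(ar$n[k] * grid$th)
      B[, ar$column[k]] <- cn * lag[, ar$ell[k] + 1] * E
    }
    sgn * B
  }
  near <- colloc_block(seq(r_nf / n_r, r_nf, length.out = n_r), -1)  # f >= 0
  far_hi <- max(r_max, r_ff * 1.5)
  far <- colloc_block(seq(r_ff, far_hi, length.out = n_r), +1)       # f <= 0
  sign_rows <- library$column[library$block %in% c("align", "drag")]
  S <- matrix(0, length(sign_rows), J)
  S[cbind(seq_along(sign_rows), sign_rows)] <- 1                     # w <= 0
  C <- rbind(near, far, S)
  list(C = C, d = rep(0, nrow(C)), r_nf = r_nf, r_ff = r_ff, r_max = r_max)
}

#' Relative-magnitude thresholding operator
#'
#' Zeros coefficient `j` unless the size of its term relative to the
#' response, `norm(G_j) * |w_j| / norm(b)`, lies in `[lambda,
#' 1/lambda]`.  Thresholding on term magnitudes (not raw coefficients)
#' lets blocks with very different basis scales compete evenly.
#'
#' @param w Coefficient vector.
#' @param gnorm Column norms of `G`.
#' @param bnorm Norm of `b`; if 0 the whole vector is zeroed.
#' @param lambda Threshold in (0, 1].
#' @return Thresholded coefficient vector.
#' @export
threshold_coefficients <- function(w, gnorm, bnorm, lambda) {
  if (lambda <= 0 || lambda > 1) abort("lambda must lie in (0, 1]")
  if (bnorm == 0) return(rep(0, length(w)))
  ratio <- gnorm * abs(w) / bnorm
  w[ratio < lambda | ratio > 1 / lambda] <- 0
  w
}

# Solve the inequality-constrained least-squares subproblem restricted
# to a support, with memoisation across the sparsity sweep.
solve_support <- function(ws, constraints, supp, cache) {
  key <- paste(supp, collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  Cs <- constraints$C[, supp, drop = FALSE]
  live <- rowSums(abs(Cs)) > 0
  fit <- cpp_lsi(ws$G[, supp, drop = FALSE], ws$b,
                 Cs[live, , drop = FALSE], constraints$d[live])
  cache[[key]] <- fit
  fit
}

#' Constrained sequential-thresholding least squares
#'
#' Iterates between the inequality-constrained least-squares solve
#' restricted to the current support and the relative-magnitude
#' threshold, until the support stops changing.  The returned
#' coefficients satisfy the sign constraints.
#'
#' @param ws Weak system from [assemble_weak_system()].
#' @param constraints Constraint system from [build_constraints()].
#' @param lambda Sparsity threshold.
#' @param max_iter Iteration cap (defaults to the library size).
#' @param cache Optional environment memoising solves across a sweep.
#' @param repair Re-solve the final support with the slower primal
#'   active-set program if the fast solver left a constraint violation
#'   above 1e-8 (the sparsity sweep defers this to its selected model).
#' @return Coefficient vector of length J.
#' @export
mstls <- function(ws, constraints, lambda, max_iter = ncol(ws$G),
                  cache = new.env(parent = emptyenv()), repair = TRUE) {
  J <- ncol(ws$G)
  if (ws$bnorm == 0) return(rep(0, J))
  supp <- seq_len(J)
  w <- rep(0, J)
  for (iter in seq_len(max_iter)) {
    fit <- solve_support(ws, constraints, supp, cache)
    w <- rep(0, J)
    w[supp] <- fit$w
    w <- threshold_coefficients(w, ws$gnorm, ws$bnorm, lambda)
    new_supp <- which(w != 0)
    if (length(new_supp) == 0) return(rep(0, J))
    if (identical(new_supp, supp)) break
    supp <- new_supp
  }
  if (repair) w <- repair_feasibility(w, ws, constraints)
  w
}

# The fast least-distance route can lose feasibility on degenerate
# support geometries.  Re-solve one support with the (always feasible)
# primal active-set program; applied to selected models only.
repair_feasibility <- function(w, ws, constraints, tol = 1e-8) {
  if (nrow(constraints$C) == 0) return(w)
  if (max(constraints$C %*% w - constraints$d) <= tol) return(w)
  supp <- which(w != 0)
  if (length(supp) == 0) return(w)
  Cs <- constraints$C[, supp, drop = FALSE]
  live <- rowSums(abs(Cs)) > 0
  w_new <- rep(0, length(w))
  w_new[supp] <- cpp_asqp(ws$G[, supp, drop = FALSE], ws$b,
                          Cs[live, , drop = FALSE], constraints$d[live])
  w_new
}

#' Sweep the sparsity threshold and select a model
#'
#' Runs [mstls()] over a grid of thresholds (by default 40 values
#' log-spaced on `[1e-4, 1]`) and keeps the model minimising the
#' selection loss `norm(G w - b) / norm(b) + nnz(w) / J`, which balances
#' fidelity against support size.  Ties go to the smallest threshold.
#'
#' @inheritParams mstls
#' @param lambda_grid Thresholds to sweep.
#' @return List with the selected `w`, `lambda`, and a tibble `path` of
#'   per-threshold losses.
#' @export
sweep_lambda <- function(ws, constraints,
                         lambda_grid = 10^seq(-4, 0, length.out = 40)) {
  if (length(lambda_grid) == 0) abort("lambda grid must be non-empty")
  J <- ncol(ws$G)
  cache <- new.env(parent = emptyenv())
  ww <- matrix(0, J, length(lambda_grid))
  loss <- numeric(length(lambda_grid))
  for (g in seq_along(lambda_grid)) {
    w <- mstls(ws, constraints, lambda_grid[g], cache = cache,
               repair = FALSE)
    ww[, g] <- w
    loss[g] <- if (ws$bnorm == 0) sum(w != 0) / J else {
      sqrt(sum((ws$G %*% w - ws$b)^2)) / ws$bnorm + sum(w != 0) / J
    }
  }
  best <- which.min(loss)   # first minimum = smallest lambda on ties
  list(w = repair_feasibility(ww[, best], ws, constraints),
       lambda = lambda_grid[best],
       path = tibble(lambda = lambda_grid, loss = loss,
                     nnz = colSums(ww != 0)))
}

# Internal learning state shared by learn_models() and the pipeline:
# matrices, velocities, library, test functions, constraints.
learning_state <- function(td, config) {
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  lib <- force_library(alpha = config$alpha)
  basis <- test_function_basis(td$L, td$dt, config$m, config$p)
  ps <- cpp_pair_stats(td$px, td$py, config$p_nf)
  s_max <- max(sqrt(V$vx^2 + V$vy^2))
  constraints <- build_constraints(lib, ps$r_nf, config$r_ff, ps$r_max,
                                   n_r = config$colloc_r,
                                   n_theta = config$colloc_theta)
  list(td = td, vx = V$vx, vy = V$vy, library = lib, basis = basis,
       constraints = constraints, r_nf = ps$r_nf, r_max = ps$r_max,
       s_max = s_max, terms = library_terms(lib))
}

learn_one <- function(state, i, config) {
  theta <- cpp_eval_library(state$td$px, state$td$py, state$vx, state$vy,
                            i - 1L, state$terms, config$alpha, config$eps_v)
  ws <- assemble_weak_system(cbind(state$td$px[, i], state$td$py[, i]),
                             theta, state$basis, state$td$dt)
  sweep_lambda(ws, state$constraints, config$lambda_grid)
}

#' Learn a force model for every cell
#'
#' For each focal cell: estimate velocities by centred finite
#' differences, evaluate the 88-term force library against its
#' neighbours, assemble the weak-form system, and run the constrained
#' sparsity sweep.  Deterministic for fixed input.
#'
#' @param data Trajectory tibble.
#' @param config Pipeline configuration from [swarm_config()].
#' @param cells Cell ids to learn (default: all).
#' @param quiet Suppress the per-cell progress message.
#' @return A `cell_models` object: coefficient matrix `W` (J x N),
#'   per-cell selected `lambda` and force-mode `code`, the library and
#'   data-derived radii.  Supports [tidy()].
#' @export
learn_models <- function(data, config = swarm_config(), cells = NULL,
                         quiet = TRUE) {
  td <- as_traj_mats(data)
  if (td$L <= 2 * config$m) {
    abort("record too short for the chosen test-function width m")
  }
  state <- learning_state(td, config)
  if (is.null(cells)) cells <- td$ids
  idx <- match(cells, td$ids)
  if (anyNA(idx)) abort("unknown cell id in `cells`")
  W <- matrix(0, nrow(state$library), length(idx))
  lambda <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fit <- learn_one(state, idx[k], config)
    W[, k] <- fit$w
    lambda[k] <- fit$lambda
    if (!quiet && k %% 25 == 0) message("learned ", k, "/", length(idx), " cells")
  }
  structure(
    list(W = W, lambda = lambda, cells = cells,
         code = apply(W, 2, force_mode_code, library = state$library),
         provenance = rep("learned", length(idx)),
         library = state$library, r_nf = state$r_nf, r_max = state$r_max,
         s_max = state$s_max, config = config),
    class = "cell_models"
  )
}

#' Learn the force model of a single focal cell
#'
#' @inheritParams learn_models
#' @param focal Cell id of the focal cell.
#' @return List with coefficients `w`, selected `lambda`, force-mode
#'   `code`, and the sweep `path`.
#' @export
learn_cell_model <- function(data, focal, config = swarm_config()) {
  td <- as_traj_mats(data)
  i <- match(focal, td$ids)
  if (is.na(i)) abort("focal cell id not found")
  state <- learning_state(td, config)
  fit <- learn_one(state, i, config)
  list(w = fit$w, lambda = fit$lambda,
       code = force_mode_code(fit$w, state$library), path = fit$path)
}

#' @export
print.cell_models <- function(x, ...) {
  cat("<cell_models> ", length(x$cells), " cells, ",
      nrow(x$W), "-term library\n", sep = "")
  cat("codes:", paste(utils::head(sort(table(x$code), decreasing = TRUE), 5L),
                      names(utils::head(sort(table(x$code), decreasing = TRUE), 5L)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cell_models <- function(x, ...) {
  tibble(cell_id = x$cells, lambda = x$lambda, code = x$code,
         n_terms = colSums(x$W != 0), provenance = x$provenance)
}
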