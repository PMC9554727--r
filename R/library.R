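# The force library: ordered basis terms for the three interaction
# forces, test functions for the weak form, and velocity estimation.

#' Construct the force basis library
#'
#' The learning basis contains 88 terms in three blocks.
#' Attraction-repulsion: `cos(n * theta) * p_l(alpha * r) * exp(-alpha
#' * r / 2)` for directional modes n = 0..2 and weighted Laguerre
#' polynomials `p_l` of degree 0..17 (the weight `exp(-r/2)` makes the
#' polynomials orthonormal on `[0, Inf)`).  Alignment: `(1 + cos(n *
#' theta)) * exp(-2 * l * r)` for n = 0..2 and l = -2..5, shaped so a
#' non-positive force is guaranteed by non-positive coefficients.
#' Drag: `(1 + cos(n * theta)) * |v|^l` for n = 0..1 and l = 0..4.
#'
#' @param alpha Radial scale of the attraction-repulsion block; the
#'   default 36 corresponds to a maximum observed inter-cell distance of
#'   about 2, where the weight `exp(-alpha * r / 2)` reaches machine
#'   precision.
#' @return A tibble with one row per basis term (columns `column`,
#'   `block`, `n`, `ell`) carrying `alpha` as an attribute.
#' @export
#' @examples
#' lib <- force_library()
#' nrow(lib)            # 88
#' dplyr::count(lib, block)
force_library <- function(alpha = 36) {
  ar <- tidyr::expand_grid(block = "ar", n = 0:2, ell = 0:17)
  al <- tidyr::expand_grid(block = "align", n = 0:2, ell = -2:5)
  dr <- tidyr::expand_grid(block = "drag", n = 0:1, ell = 0:4)
  lib <- bind_rows(ar, al, dr)
  lib$column <- seq_len(nrow(lib))
  lib <- lib[, c("column", "block", "n", "ell")]
  attr(lib, "alpha") <- alpha
  class(lib) <- c("force_library", class(lib))
  lib
}

# Integer term table (block code, n, ell) for the C++ kernels.
library_terms <- function(library) {
  blk <- match(library$block, c("ar", "align", "drag")) - 1L
  cbind(blk, as.integer(library$n), as.integer(library$ell))
}

#' Laguerre polynomial values
#'
#' Evaluates the (standard) Laguerre polynomials `L_0 .. L_deg` by the
#' three-term recurrence.  These are orthonormal on `[0, Inf)` with
#' respect to the weight `exp(-x)`.
#'
#' @param x Numeric vector of evaluation points.
#' @param deg Maximum degree.
#' @return A `length(x)` x `(deg + 1)` matrix, column `l + 1` holding
#'   `L_l(x)`.
#' @export
laguerre_polynomials <- function(x, deg) {
  out <- matrix(0, length(x), deg + 1)
  out[, 1] <- 1
  if (deg >= 1) out[, 2] <- 1 - x
  if (deg >= 2) {
    for (k in 1:(deg - 1)) {
      out[, k + 2] <- ((2 * k + 1 - x) * out[, k + 1] - k * out[, k]) / (k + 1)
    }
  }
  out
}

# Evaluate one basis term as a function of (r-or-s, cos theta) vectors.
eval_basis_term <- function(block, n, ell, r, ctheta, alpha) {
  cn <- switch(as.character(n), "0" = rep(1, length(ctheta)),
               "1" = ctheta, "2" = 2 * ctheta^2 - 1)
  switch(block,
    ar = cn * laguerre_polynomials(alpha * r, ell)[, ell + 1] *
      exp(-alpha * r / 2),
    align = (1 + cn) * exp(-2 * ell * r),
    drag = (1 + cn) * r^ell
  )
}

#' Evaluate the library for one focal cell
#'
#' Builds the feature matrix whose columns are the candidate pairwise
#' forces summed over the focal cell's neighbours at every frame (each
#' divided by the total cell count): attraction-repulsion terms paired
#' with `x_i - x_j`, alignment with `v_i - v_j`, drag with `v_i`.
#'
#' @param data Trajectory tibble (`cell_id`, `frame`, `t`, `x`, `y`).
#' @param focal Cell id of the focal cell.
#' @param library Library from [force_library()].
#' @param eps_v Degenerate-speed threshold.
#' @return A `(2L) x J` matrix; rows `1..L` are the x coordinate, rows
#'   `L+1..2L` the y coordinate.
#' @export
evaluate_library <- function(data, focal, library = force_library(),
                             eps_v = 1e-12) {
  td <- as_traj_mats(data)
  i <- match(focal, td$ids)
  if (is.na(i)) abort("focal cell id not found")
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  cpp_eval_library(td$px, td$py, V$vx, V$vy, i - 1L, library_terms(library),
                   attr(library, "alpha"), eps_v)
}

#' Second-order finite-difference velocities
#'
#' Centred differences on interior frames, one-sided three-point
#' stencils of matching order at the two endpoints.
#'
#' @param px,py L x N position matrices (frames by cells).
#' @param dt Frame interval.
#' @return List with `vx`, `vy` (L x N).
#' @export
finite_diff_velocity <- function(px, py, dt) {
  L <- nrow(px)
  if (L < 3) abort("need at least 3 frames for second-order differences")
  d1 <- function(m) {
    v <- m
    v[2:(L - 1), ] <- (m[3:L, ] - m[1:(L - 2), ]) / (2 * dt)
    v[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * dt)
    v[L, ] <- (3 * m[L, ] - 4 * m[L - 1, ] + m[L - 2, ]) / (2 * dt)
    v
  }
  list(vx = d1(px), vy = d1(py))
}

#' Compactly supported test functions for the weak form
#'
#' Polynomial bumps `phi_q(t) = max(1 - ((t - t_q) / (m * dt))^2, 0)^p`
#' centred at every admissible frame, so that `Q = L - 2m` test
#' functions fit inside the record.  Second derivatives are analytic
#' (not numerical), which is what lets the weak form transfer the
#' acceleration onto the smooth test function.
#'
#' @param L Number of frames.
#' @param dt Frame interval.
#' @param m Support half-width in frames.
#' @param p Smoothness exponent (`p >= 3` keeps the bump C2).
#' @return List with `phi`, `phidd` (Q x L matrices tabulated on the
#'   frame grid), centres `t_q`, and `m`, `p`, `Q`.
#' @export
#' @examples
#' basis <- test_function_basis(L = 200, dt = 0.05, m = 35, p = 9)
#' basis$Q   # 130
test_function_basis <- function(L, dt, m, p) {
  if (L <= 2 * m) abort("need L > 2m test-function support widths")
  if (p < 3) abort("p must be at least 3 for a C2 test function")
  Q <- L - 2L * m
  tk <- (seq_len(L) - 1) * dt
  tq <- (m:(L - m - 1)) * dt
  u <- outer(tq, tk, function(a, b) (b - a) / (m * dt))
  g <- pmax(1 - u^2, 0)
  phi <- g^p
  inside <- g > 0
  phidd <- matrix(0, Q, L)
  # d2/dt2 (1-u^2)^p = [4 p (p-1) u^2 (1-u^2)^(p-2) - 2 p (1-u^2)^(p-1)] / (m dt)^2
  phidd[inside] <- (4 * p * (p - 1) * u[inside]^2 * g[inside]^(p - 2) -
                      2 * p * g[inside]^(p - 1)) / (m * dt)^2
  list(phi = phi, phidd = phidd, tq = tq, m = m, p = p, Q = Q)
}

#' Near-field radius from the data
#'
#' The empirical `p_nf` quantile of all pairwise inter-cell distances
#' pooled over all frames; below this radius the attraction-repulsion
#' force is constrained to be repulsive (volume exclusion).
#'
#' @param data Trajectory tibble.
#' @param p_nf Quantile level in (0, 1); default 0.001.
#' @return The near-field radius (scalar).
#' @export
near_field_radius <- function(data, p_nf = 0.001) {
  if (p_nf <= 0 || p_nf >= 1) abort("p_nf must lie in (0, 1)")
  td <- as_traj_mats(data)
  if (td$n < 2) abort("need at least 2 cells")
  cpp_pair_stats(td$px, td$py, p_nf)$r_nf
}
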