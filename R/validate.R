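# Data-driven validation: forward-Euler simulation of one cell at a
# time with all neighbours replayed from the data, and classification
# of the resulting errors with a two-component Gaussian mixture.

# Precompute everything validation needs from a dataset: finite-
# difference velocities, the comparison window, and shape-preserving
# cubic Hermite interpolants of neighbour positions and velocities
# tabulated on the fine simulation grid.
validation_setup <- function(td, config) {
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  Lp <- max(2L, as.integer(round(config$L_prime_frac * td$L)))
  nsub <- config$fine_factor
  nf <- (Lp - 1L) * nsub
  tc <- td$times[seq_len(Lp)]
  tf <- seq(tc[1], tc[Lp], length.out = nf + 1L)
  interp_block <- function(M) {
    out <- matrix(0, nf + 1L, td$n)
    for (i in seq_len(td$n)) {
      out[, i] <- splinefun(tc, M[seq_len(Lp), i], method = "monoH.FC")(tf)
    }
    out
  }
  list(
    FX = interp_block(td$px), FY = interp_block(td$py),
    FVX = interp_block(V$vx), FVY = interp_block(V$vy),
    DVX = V$vx[seq_len(Lp), , drop = FALSE],
    DVY = V$vy[seq_len(Lp), , drop = FALSE],
    vx_all = V$vx, vy_all = V$vy,
    Lp = Lp, nsub = nsub, h = td$dt / nsub, n = td$n,
    r_hi = 1.5 * cpp_pair_stats(td$px, td$py, 0.5)$r_max,
    s_hi = 2 * max(sqrt(V$vx^2 + V$vy^2)),
    blow_bound = config$blow_bound
  )
}

# Radial/speed mode profiles of one coefficient vector, tabulated on
# uniform grids for the fast validation kernel.  A term with factor
# cos(n theta) feeds mode n; a shifted factor (1 + cos(n theta)) feeds
# modes 0 and n.
mode_profiles <- function(w, library, r_hi, s_hi, nr = 4096, ns = 1024) {
  alpha <- attr(library, "alpha")
  r <- seq(0, r_hi, length.out = nr)
  s <- seq(0, s_hi, length.out = ns)
  AR <- matrix(0, nr, 3)
  AL <- matrix(0, nr, 3)
  DR <- matrix(0, ns, 2)
  nz <- which(w != 0)
  ar_terms <- nz[library$block[nz] == "ar"]
  if (length(ar_terms) > 0) {
    E <- exp(-alpha * r / 2)
    lag <- laguerre_polynomials(alpha * r, max(library$ell[ar_terms]))
    for (j in ar_terms) {
      AR[, library$n[j] + 1] <- AR[, library$n[j] + 1] +
        w[j] * lag[, library$ell[j] + 1] * E
    }
  }
  for (j in nz[library$block[nz] == "align"]) {
    prof <- w[j] * exp(-2 * library$ell[j] * r)
    n <- library$n[j]
    if (n == 0) {
      AL[, 1] <- AL[, 1] + 2 * prof
    } else {
      AL[, 1] <- AL[, 1] + prof
      AL[, n + 1] <- AL[, n + 1] + prof
    }
  }
  for (j in nz[library$block[nz] == "drag"]) {
    prof <- w[j] * s^library$ell[j]
    n <- library$n[j]
    if (n == 0) {
      DR[, 1] <- DR[, 1] + 2 * prof
    } else {
      DR[, 1] <- DR[, 1] + prof
      DR[, 2] <- DR[, 2] + prof
    }
  }
  list(AR = AR, AL = AL, DR = DR)
}

# Stack per-model profiles into cubes for the batched kernel.
model_profiles <- function(W, library, setup) {
  P <- ncol(W)
  AR <- array(0, c(4096, 3, P))
  AL <- array(0, c(4096, 3, P))
  DR <- array(0, c(1024, 2, P))
  for (p in seq_len(P)) {
    mp <- mode_profiles(W[, p], library, setup$r_hi, setup$s_hi)
    AR[, , p] <- mp$AR
    AL[, , p] <- mp$AL
    DR[, , p] <- mp$DR
  }
  list(AR = AR, AL = AL, DR = DR)
}

# Run a batch of (model, cell) validation tasks; returns one error per
# task (+Inf sentinel on blow-up).
validate_tasks <- function(tasks, profs, setup, config) {
  cpp_validate_batch(
    matrix(as.integer(tasks - 1L), ncol = 2), setup$FX, setup$FY,
    setup$FVX, setup$FVY, setup$DVX, setup$DVY,
    profs$AR, profs$AL, profs$DR, setup$r_hi, setup$s_hi,
    setup$h, as.integer(setup$nsub), as.integer(setup$Lp),
    as.integer(setup$n), config$eps_v, setup$blow_bound
  )
}

#' Simulate one cell under a candidate model, neighbours from data
#'
#' Forward-Euler simulation of a single cell on a fine time grid (by
#' default 1/32 of the frame interval) with the initial condition taken
#' from the data and every neighbour's position and velocity replayed
#' from shape-preserving cubic Hermite interpolants of the data.  Only
#' the focal cell is evolved, so the per-step cost is linear, not
#' quadratic, in the population size.
#'
#' @param w Coefficient vector over the library (e.g. an aggregate
#'   model).
#' @param data Trajectory tibble.
#' @param focal Cell id to simulate.
#' @param config Pipeline configuration from [swarm_config()].
#' @return List with the relative velocity error `dv` and the simulated
#'   coarse trajectory tibble `sim` (`frame`, `t`, `x`, `y`, `vx`,
#'   `vy`).
#' @export
simulate_cell <- function(w, data, focal, config = swarm_config()) {
  td <- as_traj_mats(data)
  i <- match(focal, td$ids)
  if (is.na(i)) abort("focal cell id not found")
  setup <- validation_setup(td, config)
  lib <- force_library(alpha = config$alpha)
  mp <- mode_profiles(w, lib, setup$r_hi, setup$s_hi)
  out <- cpp_validate_single(i - 1L, setup$FX, setup$FY, setup$FVX, setup$FVY,
                             setup$DVX, setup$DVY, mp$AR, mp$AL, mp$DR,
                             setup$r_hi, setup$s_hi, setup$h,
                             as.integer(setup$nsub), as.integer(setup$Lp),
                             as.integer(setup$n), config$eps_v,
                             setup$blow_bound)
  list(dv = out$dv,
       sim = tibble(frame = seq_len(setup$Lp),
                    t = td$times[seq_len(setup$Lp)],
                    x = as.numeric(out$px), y = as.numeric(out$py),
                    vx = as.numeric(out$vx), vy = as.numeric(out$vy)))
}

#' Relative velocity validation error
#'
#' Ratio of summed squared velocity differences between simulation and
#' data to the summed squared data speeds, over the first `L'` frames.
#'
#' @param v_sim,v_data L' x 2 velocity matrices.
#' @param L_prime Number of frames to compare (defaults to all rows).
#' @return Non-negative scalar; 0 iff the velocities agree exactly.
#' @export
#' @examples
#' validation_error(cbind(c(1, 0), 0), cbind(c(1, 1), 0))   # 0.5
validation_error <- function(v_sim, v_data, L_prime = nrow(v_data)) {
  if (L_prime > nrow(v_data)) abort("L_prime exceeds the record length")
  ks <- seq_len(L_prime)
  den <- sum(v_data[ks, ]^2)
  if (den == 0) abort("all data velocities are zero on the comparison window")
  sum((v_sim[ks, ] - v_data[ks, ])^2) / den
}

# --- two-component Gaussian mixture on log10 validation errors --------

# One EM fit from an initial hard split; x is sorted-agnostic.
em_fit_1d <- function(x, split, tol = 1e-8, max_iter = 500) {
  n <- length(x)
  lab <- x <= split
  if (all(lab) || !any(lab)) lab <- x <= median(x)
  if (all(lab) || !any(lab)) lab <- seq_len(n) <= n / 2
  mu <- c(mean(x[lab]), mean(x[!lab]))
  s2 <- c(stats::var(x[lab]), stats::var(x[!lab]))
  s2[!is.finite(s2) | s2 < 1e-10] <- max(1e-10, stats::var(x) / 4)
  pi_k <- c(mean(lab), 1 - mean(lab))
  ll_old <- -Inf
  R <- matrix(0.5, n, 2)
  for (it in seq_len(max_iter)) {
    d1 <- pi_k[1] * dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pi_k[2] * dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    R <- cbind(d1 / tot, d2 / tot)
    nk <- colSums(R)
    if (any(nk < 1e-8)) break
    mu <- colSums(R * x) / nk
    s2 <- pmax(colSums(R * (x - rep(mu, each = n))^2) / nk, 1e-10)
    pi_k <- nk / n
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {   # component 1 = lower mean
    mu <- rev(mu); s2 <- rev(s2); pi_k <- rev(pi_k); R <- R[, 2:1, drop = FALSE]
  }
  list(mu = mu, s2 = s2, pi = pi_k, posterior = R)
}

#' Classify validation errors with a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture to `log10` of the validation
#' errors by EM, restarting `n_gmm` times from jittered median splits
#' and averaging the per-cell posteriors across fits.  Cells whose
#' averaged posterior favours the lower-mean component form the new
#' species.  Infinite errors (blow-up sentinels) always land outside
#' the species; if the errors are (numerically) all equal, everything
#' is the species.
#'
#' @param ve Vector of validation errors (non-negative; may contain
#'   `Inf`).
#' @param n_gmm Number of random-restart EM fits to average.
#' @param seed Integer seed for the restarts.
#' @return List with logical `species` membership, the averaged
#'   `posterior` (n x 2, column 1 = lower-mean component), per-fit
#'   component `means`, and a `degenerate` flag.
#' @export
classify_gmm <- function(ve, n_gmm = 20, seed = 1) {
  finite <- is.finite(ve)
  if (sum(finite) < 2) abort("need at least 2 finite validation errors")
  x <- log10(pmax(ve[finite], .Machine$double.xmin))
  n <- length(x)
  post <- matrix(0, n, 2)
  if (sd(x) < 1e-10) {
    post[, 1] <- 1
    species <- rep(FALSE, length(ve))
    species[finite] <- TRUE
    return(list(species = species,
                posterior = post, means = matrix(mean(x), 1, 2),
                degenerate = TRUE))
  }
  means <- matrix(0, n_gmm, 2)
  with_seed(seed, {
    for (g in seq_len(n_gmm)) {
      split <- median(x) + rnorm(1, sd = 0.25 * sd(x))
      fit <- em_fit_1d(x, split)
      post <- post + fit$posterior / n_gmm
      means[g, ] <- fit$mu
    }
  })
  species <- rep(FALSE, length(ve))
  species[finite] <- post[, 1] > post[, 2]
  list(species = species, posterior = post, means = means,
       degenerate = FALSE)
}

#' Stopping decision for the classification loop
#'
#' The loop over cluster/aggregate/validate/classify ends when (1)
#' fewer than `n_min` unlabelled cells remain, (2) at least `(1 -
#' delta_gmm)` of the remaining cells validate below `eps_gmm` (those
#' cells become a final species, the rest outliers), or (3) the species
#' budget `s_max_species` is reached.
#'
#' @param n_remaining Number of unlabelled cells.
#' @param ve Validation errors of the remaining cells under the current
#'   candidate model, or `NULL` before validation.
#' @param n_species Number of species identified so far.
#' @param config Pipeline configuration from [swarm_config()].
#' @return One of `"continue"`, `"stop_outliers"`, `"stop_threshold"`,
#'   `"stop_max_species"`.
#' @export
stopping_decision <- function(n_remaining, ve = NULL, n_species = 0,
                              config = swarm_config()) {
  if (n_remaining < config$n_min) return("stop_outliers")
  if (!is.null(ve) && length(ve) > 0 &&
      mean(ve < config$eps_gmm) >= 1 - config$delta_gmm) {
    return("stop_threshold")
  }
  if (n_species >= config$s_max_species) return("stop_max_species")
  "continue"
}
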