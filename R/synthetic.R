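# Synthetic benchmark populations: ground-truth forces, species presets,
# and the second-order interacting-particle simulator.

#' Benchmark species and their active forces
#'
#' Three reference cell types used throughout the package's benchmarks.
#' Species A obeys all three forces (attraction-repulsion, alignment,
#' drag), species B attraction-repulsion and drag, and species C
#' alignment and drag.  The ground-truth forces are a quadrupolar
#' attraction-repulsion `(15 + 10 cos 2t)(exp(-20r) - 0.25 exp(-10r))`,
#' a dipolar alignment `-(8 + 8 cos t) exp(-8r)` and a linear isotropic
#' drag `-5 s`.
#'
#' @return A tibble with columns `species`, `has_ar`, `has_align`,
#'   `has_drag`.
#' @export
#' @examples
#' species_presets()
species_presets <- function() {
  tibble(
    species = c("A", "B", "C"),
    has_ar = c(TRUE, TRUE, FALSE),
    has_align = c(TRUE, FALSE, TRUE),
    has_drag = c(TRUE, TRUE, TRUE)
  )
}

#' Ground-truth pairwise force magnitudes
#'
#' Evaluates the benchmark forces used by the synthetic populations.
#' `"ar"` is the anisotropic attraction-repulsion force as a function of
#' inter-cell distance `r` and angle `theta`; `"align"` the dipolar
#' alignment force; `"drag"` the isotropic drag as a function of speed
#' (`theta` is ignored for drag).
#'
#' @param kind One of `"ar"`, `"align"`, `"drag"`.
#' @param r Non-negative distance (or speed, for `"drag"`).
#' @param theta Angle in radians between a cell's velocity and the
#'   displacement towards its neighbour.  Recycled against `r`.
#' @return Numeric vector of force magnitudes.
#' @export
#' @examples
#' true_force("ar", 0.1, 0)
#' true_force("align", 0.7, pi)   # vanishes: dipolar factor is zero
true_force <- function(kind, r, theta = 0) {
  kind <- match.arg(kind, c("ar", "align", "drag"))
  if (any(r < 0)) abort("r must be non-negative")
  switch(kind,
    ar = (15 + 10 * cos(2 * theta)) * (exp(-20 * r) - 0.25 * exp(-10 * r)) +
      0 * theta,
    align = -(8 + 8 * cos(theta)) * exp(-8 * r),
    drag = -5 * r + 0 * theta
  )
}

#' Angle between a cell's velocity and the displacement to a neighbour
#'
#' Returns the interaction angle and the directional factors `cos(n *
#' theta)` for modes n = 0, 1, 2.  When the speed falls below `eps_v` no
#' direction of motion is defined and the anisotropic factors (n >= 1)
#' are zero by convention, so only isotropic force modes act.
#'
#' @param v Length-2 velocity vector of the focal cell.
#' @param disp Length-2 displacement `x_j - x_i` towards the neighbour;
#'   must be nonzero.
#' @param eps_v Degenerate-speed threshold.
#' @return List with `theta` (in `[0, pi]`, `NA` when degenerate) and
#'   `cosn`, the factors for n = 0, 1, 2.
#' @export
pairwise_angle <- function(v, disp, eps_v = 1e-12) {
  dn <- sqrt(sum(disp^2))
  if (dn < 1e-14) abort("displacement must be nonzero (self-pairs are excluded)")
  s <- sqrt(sum(v^2))
  if (s < eps_v) {
    return(list(theta = NA_real_, cosn = c(1, 0, 0)))
  }
  c1 <- max(-1, min(1, sum(v * disp) / (s * dn)))
  list(theta = acos(c1), cosn = c(1, c1, 2 * c1^2 - 1))
}

#' Population accelerations under the ground-truth forces
#'
#' Computes the per-cell accelerations of the directional
#' interacting-particle model: each force is summed over the other cells
#' and divided by the total population size; the attraction-repulsion
#' term acts along `x_i - x_j`, alignment along `v_i - v_j`, and drag
#' along `v_i`.
#'
#' @param x,v N x 2 matrices of positions and velocities.
#' @param species Character vector of species labels (one per cell),
#'   matched against `specs`.
#' @param specs Species definition table as from [species_presets()].
#' @param eps_v Degenerate-speed threshold.
#' @return N x 2 matrix of accelerations.
#' @export
acceleration_rhs <- function(x, v, species, specs = species_presets(),
                             eps_v = 1e-12) {
  idx <- match(species, specs$species)
  if (anyNA(idx)) abort("unknown species label")
  cpp_true_accel(x[, 1], x[, 2], v[, 1], v[, 2],
                 as.integer(specs$has_ar[idx]),
                 as.integer(specs$has_align[idx]),
                 as.integer(specs$has_drag[idx]), eps_v)
}

#' Simulate a benchmark cell population
#'
#' Integrates the second-order directional interaction model forward in
#' time with a fixed-step RK4 integrator on a fine sub-grid, recording
#' positions and velocities at `n_frames` coarse frames.  Initial
#' positions are uniform on a disc; initial velocities point in uniform
#' random directions with speeds drawn from `v0_range`, so drag stays
#' identifiable for every cell.  The default disc radius keeps the
#' areal cell density at the benchmark operating point when `n_cells`
#' is scaled down; the library's radial scale (`alpha = 36`, matched to
#' a maximum inter-cell distance of about 2 at full population size) is
#' retained throughout.
#'
#' @param n_cells Total number of cells.
#' @param proportions Named numeric vector of species proportions, e.g.
#'   `c(A = 0.5, C = 0.5)`.  Names must appear in `specs`.  Counts are
#'   rounded; the first species absorbs the remainder.
#' @param n_frames Number of recorded frames `L`.
#' @param dt Frame interval (model time units).
#' @param seed Integer seed; the same seed reproduces the data exactly.
#' @param radius Radius of the initial disc; the default (`NULL`)
#'   chooses the radius so the initial areal density is 315 cells per
#'   unit area regardless of `n_cells`, which reproduces the benchmark
#'   operating point at any population size (and a maximum inter-cell
#'   distance near 2 at 1000 cells).
#' @param v0_range Range of initial speeds; each cell starts at a speed
#'   drawn uniformly from this interval in a uniformly random
#'   direction, so every trajectory sweeps a comparable speed range as
#'   drag decelerates it (keeping the drag force identifiable for every
#'   cell).
#' @param substeps RK4 sub-steps per frame interval.
#' @param blow_bound Error if any position norm exceeds this bound.
#' @param specs Species definition table as from [species_presets()].
#' @param eps_v Degenerate-speed threshold.
#' @return A long tibble with columns `cell_id`, `frame`, `t`, `x`, `y`,
#'   `species`, plus matching velocity columns `vx`, `vy`.
#' @export
#' @examples
#' traj <- simulate_population(n_cells = 20, proportions = c(C = 1),
#'                             n_frames = 20, seed = 1)
#' dplyr::count(traj, species)
simulate_population <- function(n_cells = 200,
                                proportions = c(A = 1),
                                n_frames = 200,
                                dt = 0.05,
                                seed = 1,
                                radius = NULL,
                                v0_range = c(0.08, 0.3),
                                substeps = 8,
                                blow_bound = 100,
                                specs = species_presets(),
                                eps_v = 1e-12) {
  stopifnot(n_cells >= 1, n_frames >= 2, dt > 0, substeps >= 1)
  if (is.null(names(proportions)) || any(!names(proportions) %in% specs$species)) {
    abort("proportions must be named by species present in `specs`")
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort("species proportions must sum to 1")
  }
  if (is.null(radius)) radius <- sqrt(n_cells / (pi * 315))
  counts <- floor(proportions * n_cells)
  counts[1] <- counts[1] + n_cells - sum(counts)
  species <- rep(names(proportions), times = counts)

  ic <- with_seed(seed, {
    # uniform on a disc via rejection-free polar sampling
    u <- runif(n_cells)
    th <- runif(n_cells, 0, 2 * pi)
    r0 <- radius * sqrt(u)
    s0 <- runif(n_cells, v0_range[1], v0_range[2])
    dir <- runif(n_cells, 0, 2 * pi)
    list(x = r0 * cos(th), y = r0 * sin(th),
         vx = s0 * cos(dir), vy = s0 * sin(dir))
  })

  idx <- match(species, specs$species)
  sim <- cpp_simulate_true(ic$x, ic$y, ic$vx, ic$vy,
                           as.integer(specs$has_ar[idx]),
                           as.integer(specs$has_align[idx]),
                           as.integer(specs$has_drag[idx]),
                           as.integer(n_frames), dt, as.integer(substeps),
                           blow_bound, eps_v)
  times <- (seq_len(n_frames) - 1) * dt
  out <- traj_tibble(sim$px, sim$py, times, seq_len(n_cells), species)
  out$vx <- as.vector(sim$vx)
  out$vy <- as.vector(sim$vy)
  out
}

# Simulate a population in which every cell follows an arbitrary
# coefficient vector over the force library (used to manufacture
# constraint-feasible in-library ground truths).
simulate_library_model <- function(W, library, n_frames, dt, seed = 1,
                                   radius = 0.5, v0_range = c(0.08, 0.3),
                                   substeps = 8, blow_bound = 100,
                                   eps_v = 1e-12) {
  n_cells <- ncol(W)
  ic <- with_seed(seed, {
    u <- runif(n_cells)
    th <- runif(n_cells, 0, 2 * pi)
    r0 <- radius * sqrt(u)
    s0 <- runif(n_cells, v0_range[1], v0_range[2])
    dir <- runif(n_cells, 0, 2 * pi)
    list(x = r0 * cos(th), y = r0 * sin(th),
         vx = s0 * cos(dir), vy = s0 * sin(dir))
  })
  sim <- cpp_simulate_model(ic$x, ic$y, ic$vx, ic$vy, W, library_terms(library),
                            attr(library, "alpha"), as.integer(n_frames), dt,
                            as.integer(substeps), blow_bound, eps_v)
  times <- (seq_len(n_frames) - 1) * dt
  out <- traj_tibble(sim$px, sim$py, times, seq_len(n_cells))
  out$vx <- as.vector(sim$vx)
  out$vy <- as.vector(sim$vy)
  out
}

#' Read and write trajectory tables
#'
#' Long-format CSV with header `cell_id,frame,t,x,y[,species]`.  Reading
#' sorts by `(cell_id, frame)`, checks that every cell shares one
#' strictly increasing, uniformly spaced time grid, and errors
#' otherwise.
#'
#' @param data Trajectory tibble as produced by [simulate_population()].
#' @param path File path.
#' @return `read_trajectory()` returns the validated trajectory tibble;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(data, path) {
  keep <- intersect(c("cell_id", "frame", "t", "x", "y", "species"), names(data))
  readr::write_csv(data[keep], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  td <- as_traj_mats(data)   # validates columns, grid uniformity, finiteness
  traj_tibble(td$px, td$py, td$times, td$ids, td$labels)
}
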