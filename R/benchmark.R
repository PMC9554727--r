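# Named benchmark experiments: simulate a population from the
# ground-truth species, run the full pipeline, and evaluate against the
# known labels and forces.

BENCHMARKS <- list(
  A        = list(proportions = c(A = 1), n_frames = 200),
  B        = list(proportions = c(B = 1), n_frames = 200),
  C        = list(proportions = c(C = 1), n_frames = 200),
  AC       = list(proportions = c(A = 0.5, C = 0.5), n_frames = 200),
  BC       = list(proportions = c(B = 0.5, C = 0.5), n_frames = 200),
  AB       = list(proportions = c(A = 0.5, B = 0.5), n_frames = 200),
  ABC      = list(proportions = c(A = 1 / 3, B = 1 / 3, C = 1 / 3),
                  n_frames = 200),
  ABC_long = list(proportions = c(A = 1 / 3, B = 1 / 3, C = 1 / 3),
                  n_frames = 400)
)

#' Run a named benchmark experiment end to end
#'
#' Simulates a population of the requested species mixture, runs the
#' full sorting pipeline, and evaluates the discovered clusters against
#' the ground truth (relative force errors, classification success,
#' mean validation errors).
#'
#' @param experiment One of `"A"`, `"B"`, `"C"` (homogeneous), `"AC"`,
#'   `"BC"`, `"AB"` (two-species half/half), `"ABC"`, `"ABC_long"`
#'   (three-species thirds; the long variant doubles the record).
#' @param n_cells Population size.
#' @param seed Seed for the simulated population.
#' @param config Pipeline configuration from [swarm_config()].
#' @param quiet Suppress progress messages.
#' @return List with the simulated `data`, the `result`
#'   (`species_sort`), and the evaluation `report` tibble.
#' @export
run_benchmark <- function(experiment = names(BENCHMARKS), n_cells = 200,
                          seed = 1, config = swarm_config(), quiet = TRUE) {
  experiment <- match.arg(experiment)
  spec <- BENCHMARKS[[experiment]]
  data <- simulate_population(n_cells = n_cells,
                              proportions = spec$proportions,
                              n_frames = spec$n_frames, seed = seed)
  config$seed <- seed
  result <- sort_species(data, config, quiet = quiet)
  list(experiment = experiment, data = data, result = result,
       report = species_report(result))
}
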