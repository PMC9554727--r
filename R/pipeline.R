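# End-to-end pipeline: learn -> replace -> (cluster -> aggregate ->
# validate -> classify) until stopping, plus ground-truth evaluation
# metrics.

#' Pipeline configuration
#'
#' All tunable parameters with their default values.  The defaults are
#' the package's standard operating point: near-field quantile `p_nf =
#' 0.001`, far-field radius `r_ff = 1`, radial library scale `alpha =
#' 36`, test-function shape `(m, p) = (35, 9)`, a 40-point log-spaced
#' sparsity sweep on `[1e-4, 1]`, `K = 32` validation cells with
#' replacement tolerance 0.25, aggregate threshold 4 decades, fine
#' validation step of 1/32 frame interval over the first quarter of the
#' record, mixture stopping pair `(0.05, 0.01)`, at least 2 cells per
#' species, 20 averaged mixture fits, and at most 10 species.
#'
#' @param p_nf Near-field quantile level.
#' @param r_ff Far-field radius above which attraction is enforced.
#' @param alpha Radial scale of the attraction-repulsion basis.
#' @param m,p Test-function support half-width (frames) and smoothness
#'   exponent; admissible ranges 31-38 and 8-9.
#' @param lambda_grid Sparsity thresholds to sweep.
#' @param K Validation cells per cell for model replacement.
#' @param tol_replace Replacement error tolerance.
#' @param lambda_log Aggregate-threshold decades.
#' @param fine_factor Fine sub-steps per frame interval in validation
#'   simulations.
#' @param L_prime_frac Fraction of the record used for validation.
#' @param eps_gmm,delta_gmm Threshold-stopping pair: stop when at least
#'   `1 - delta_gmm` of cells validate below `eps_gmm`.
#' @param n_min Minimum unlabelled cells to continue.
#' @param n_gmm Mixture fits averaged per classification round.
#' @param s_max_species Maximum number of species.
#' @param colloc_r,colloc_theta Collocation grid sizes for the
#'   attraction-repulsion sign constraints.
#' @param eps_v Degenerate-speed threshold.
#' @param blow_bound Position bound marking a validation blow-up.
#' @param seed Master seed (mixture restarts).
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(p_nf = 0.001, r_ff = 1, alpha = 36, m = 35, p = 9,
                         lambda_grid = 10^seq(-4, 0, length.out = 40),
                         K = 32, tol_replace = 0.25, lambda_log = 4,
                         fine_factor = 32, L_prime_frac = 0.25,
                         eps_gmm = 0.05, delta_gmm = 0.01, n_min = 2,
                         n_gmm = 20, s_max_species = 10,
                         colloc_r = 30, colloc_theta = 9,
                         eps_v = 1e-12, blow_bound = 100, seed = 1) {
  if (!(m %in% 31:38)) warning("m outside the validated range 31-38")
  if (!(p %in% 8:9)) warning("p outside the validated range 8-9")
  structure(list(
    p_nf = p_nf, r_ff = r_ff, alpha = alpha, m = m, p = p,
    lambda_grid = lambda_grid, K = K, tol_replace = tol_replace,
    lambda_log = lambda_log, fine_factor = fine_factor,
    L_prime_frac = L_prime_frac, eps_gmm = eps_gmm, delta_gmm = delta_gmm,
    n_min = n_min, n_gmm = n_gmm, s_max_species = s_max_species,
    colloc_r = colloc_r, colloc_theta = colloc_theta,
    eps_v = eps_v, blow_bound = blow_bound, seed = seed
  ), class = "swarm_config")
}

#' Sort a cell population into species
#'
#' The full pipeline.  One force model is learned per cell by
#' constrained weak-form sparse regression; poorly fitting models are
#' replaced by the models of statistically similar cells; then the
#' remaining cells are repeatedly clustered by force-mode code, the
#' largest cluster averaged into a candidate species model, every
#' remaining cell validated under it by data-driven forward simulation,
#' and the low-error mixture component split off as a new species,
#' until a stopping condition fires.
#'
#' @param data Trajectory tibble (`cell_id`, `frame`, `t`, `x`, `y`,
#'   optional `species` truth labels kept for evaluation).
#' @param config Pipeline configuration from [swarm_config()].
#' @param models Optional pre-learned `cell_models` (skips learning).
#' @param replace Run the model-replacement pass (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return A `species_sort` object with one entry per discovered
#'   species (member cells, aggregate model, per-cell validation
#'   errors), the outlier cells, the individual models, and a round
#'   log.  Supports [tidy()], [glance()], [augment()] and
#'   [autoplot()].
#' @export
sort_species <- function(data, config = swarm_config(), models = NULL,
                         replace = TRUE, quiet = TRUE) {
  td <- as_traj_mats(data)
  setup <- validation_setup(td, config)
  if (is.null(models)) {
    if (!quiet) message("learning ", td$n, " single-cell models")
    models <- learn_models(data, config, quiet = quiet)
  }
  if (replace) {
    if (!quiet) message("model replacement pass")
    models <- replacement_pass(models, data, config, setup = setup)
  }

  N <- td$n
  remaining <- seq_len(N)
  species <- list()
  ve_rounds <- list()
  log <- list()
  stop_reason <- NULL
  round <- 0L
  while (TRUE) {
    round <- round + 1L
    if (length(remaining) < config$n_min) {
      stop_reason <- "stop_outliers"
      break
    }
    if (length(species) >= config$s_max_species) {
      stop_reason <- "stop_max_species"
      break
    }
    part <- partition_by_code(models$code[remaining])
    members_pos <- remaining[part$clusters$cells[[1]]]
    agg <- aggregate_cluster(models$W[, members_pos, drop = FALSE],
                             models$library, config$lambda_log,
                             cells = models$cells[members_pos])
    prof <- model_profiles(matrix(agg$w, ncol = 1), models$library, setup)
    ve <- validate_tasks(cbind(1L, remaining), prof, setup, config)
    ve_rounds[[round]] <- tibble(round = round,
                                 cell_id = models$cells[remaining], ve = ve)
    if (!quiet) {
      message("round ", round, ": ", length(remaining), " cells, code ",
              agg$code, ", median dV ", signif(median(ve), 3))
    }
    decision <- stopping_decision(length(remaining), ve, length(species), config)
    if (decision == "stop_threshold") {
      sel <- ve < config$eps_gmm
      species[[length(species) + 1]] <- list(
        ordinal = length(species) + 1L,
        cells = models$cells[remaining[sel]],
        model = agg, dv = ve[sel], round = round
      )
      remaining <- remaining[!sel]
      stop_reason <- "stop_threshold"
      break
    }
    cls <- classify_gmm(ve, n_gmm = config$n_gmm,
                        seed = config$seed + 1000L * round)
    sel <- cls$species
    log[[round]] <- tibble(round = round, n_remaining = length(remaining),
                           code = agg$code, cluster_size = agg$size,
                           n_assigned = sum(sel),
                           gmm_mean_lo = mean(cls$means[, 1]),
                           gmm_mean_hi = mean(cls$means[, 2]))
    if (!any(sel)) {
      stop_reason <- "stop_outliers"
      break
    }
    species[[length(species) + 1]] <- list(
      ordinal = length(species) + 1L,
      cells = models$cells[remaining[sel]],
      model = agg, dv = ve[sel], round = round
    )
    remaining <- remaining[!sel]
  }

  structure(list(
    species = species,
    outliers = models$cells[remaining],
    models = models,
    config = config,
    stop_reason = stop_reason,
    ve_rounds = if (length(ve_rounds)) bind_rows(ve_rounds) else tibble(),
    log = if (length(log)) bind_rows(log) else tibble(),
    labels = td$labels,
    cells = models$cells,
    n_cells = N
  ), class = "species_sort")
}

#' Relative force error against a ground-truth force
#'
#' Relative L2 error between a learned force and the ground truth on a
#' dense evaluation grid: for attraction-repulsion and alignment a
#' 1000 x 1000 Cartesian grid over `[-2, 2]^2` (with `r` the radius and
#' `theta` the polar angle), for drag a 1000 x 1000 grid over `[0,
#' s_max] x [0, pi]`.
#'
#' @param w Learned coefficient vector.
#' @param library Library from [force_library()].
#' @param kind One of `"ar"`, `"align"`, `"drag"`.
#' @param present Is this force present in the ground truth?  Errors if
#'   not (tables print a dash).
#' @param s_max Maximum speed for the drag grid.
#' @param n_grid Grid points per direction.
#' @return Relative L2 error (dimensionless scalar).
#' @export
force_error <- function(w, library, kind = c("ar", "align", "drag"),
                        present = TRUE, s_max = 1, n_grid = 1000) {
  kind <- match.arg(kind)
  if (!present) abort("force absent from the ground truth")
  alpha <- attr(library, "alpha")
  if (kind == "drag") {
    s <- seq(0, s_max, length.out = n_grid)
    th <- seq(0, pi, length.out = n_grid)
    idx <- which(w != 0 & library$block == "drag")
    prof0 <- rep(0, n_grid); prof1 <- rep(0, n_grid)
    for (j in idx) {
      p <- w[j] * s^library$ell[j]
      if (library$n[j] == 0) prof0 <- prof0 + 2 * p
      else { prof0 <- prof0 + p; prof1 <- prof1 + p }
    }
    c1 <- cos(th)
    fhat <- outer(prof0, rep(1, n_grid)) + outer(prof1, c1)
    ftrue <- matrix(-5 * s, n_grid, n_grid)
    return(sqrt(sum((fhat - ftrue)^2) / sum(ftrue^2)))
  }
  g <- seq(-2, 2, length.out = n_grid)
  xx <- rep(g, times = n_grid)
  yy <- rep(g, each = n_grid)
  r <- sqrt(xx^2 + yy^2)
  c1 <- xx / r
  c2 <- 2 * c1^2 - 1
  if (kind == "ar") {
    idx <- which(w != 0 & library$block == "ar")
    prof <- matrix(0, length(r), 3)
    if (length(idx) > 0) {
      E <- exp(-alpha * r / 2)
      maxl <- max(library$ell[idx])
      pkm1 <- rep(1, length(r)); pk <- 1 - alpha * r
      for (l in 0:maxl) {
        pl <- if (l == 0) pkm1 else if (l == 1) pk else {
          pnew <- ((2 * (l - 1) + 1 - alpha * r) * pk - (l - 1) * pkm1) / l
          pkm1 <- pk; pk <- pnew; pnew
        }
        for (j in idx[library$ell[idx] == l]) {
          prof[, library$n[j] + 1] <- prof[, library$n[j] + 1] + w[j] * pl * E
        }
      }
    }
    fhat <- prof[, 1] + c1 * prof[, 2] + c2 * prof[, 3]
    ftrue <- (15 + 10 * c2) * (exp(-20 * r) - 0.25 * exp(-10 * r))
  } else {
    idx <- which(w != 0 & library$block == "align")
    prof <- matrix(0, length(r), 3)
    for (j in idx) {
      p <- w[j] * exp(-2 * library$ell[j] * r)
      if (library$n[j] == 0) prof[, 1] <- prof[, 1] + 2 * p
      else { prof[, 1] <- prof[, 1] + p
             prof[, library$n[j] + 1] <- prof[, library$n[j] + 1] + p }
    }
    fhat <- prof[, 1] + c1 * prof[, 2] + c2 * prof[, 3]
    ftrue <- -(8 + 8 * c1) * exp(-8 * r)
  }
  sqrt(sum((fhat - ftrue)^2) / sum(ftrue^2))
}

#' Classification success of a discovered cluster
#'
#' Fraction of the cells of one true species that ended up in the given
#' cluster.
#'
#' @param members Cell ids of the cluster.
#' @param labels Named or positional character vector of true labels
#'   (one per cell, aligned with `cells`).
#' @param cells Cell ids aligned with `labels`.
#' @param species True species to score.
#' @return Fraction in `[0, 1]`.
#' @export
classification_success <- function(members, labels, cells, species) {
  truth <- cells[labels == species]
  if (length(truth) == 0) abort(paste0("species ", species, " absent from the data"))
  length(intersect(members, truth)) / length(truth)
}

#' Per-cluster evaluation report
#'
#' One row per discovered cluster in discovery order, with the relative
#' force errors for every force present in the cluster's majority true
#' species (`NA` where the truth has no such force), the classification
#' success against each true species, and the cluster's mean validation
#' error.
#'
#' @param result A `species_sort` object from [sort_species()].
#' @param specs Species definition table as from [species_presets()].
#' @return A tibble; also serialisable with
#'   [jsonlite::write_json()].
#' @export
species_report <- function(result, specs = species_presets()) {
  labels <- result$labels
  if (is.null(labels)) abort("data carried no true species labels")
  present <- intersect(specs$species, unique(labels))
  rows <- purrr::map(result$species, function(sp) {
    maj <- names(sort(table(labels[match(sp$cells, result$cells)]),
                      decreasing = TRUE))[1]
    flags <- specs[specs$species == maj, ]
    lib <- result$models$library
    row <- tibble(
      cluster = sp$ordinal,
      n_cells = length(sp$cells),
      code = sp$model$code,
      majority_species = maj,
      delta_f_ar = if (flags$has_ar)
        force_error(sp$model$w, lib, "ar") else NA_real_,
      delta_f_align = if (flags$has_align)
        force_error(sp$model$w, lib, "align") else NA_real_,
      delta_f_drag = if (flags$has_drag)
        force_error(sp$model$w, lib, "drag",
                    s_max = result$models$s_max) else NA_real_,
      mean_dv = mean(sp$dv)
    )
    for (s in present) {
      row[[paste0("cs_", s)]] <-
        classification_success(sp$cells, labels, result$cells, s)
    }
    row
  })
  bind_rows(rows)
}

# --- broom-style methods ----------------------------------------------

#' @export
print.species_sort <- function(x, ...) {
  cat("<species_sort> ", length(x$species), " species, ",
      length(x$outliers), " outliers of ", x$n_cells, " cells (",
      x$stop_reason, ")\n", sep = "")
  for (sp in x$species) {
    cat("  species ", sp$ordinal, ": ", length(sp$cells), " cells, code ",
        sp$model$code, ", mean dV ", signif(mean(sp$dv), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.species_sort <- function(x, ...) {
  bind_rows(purrr::map(x$species, function(sp) {
    tibble(cluster = sp$ordinal, n_cells = length(sp$cells),
           code = sp$model$code, mean_dv = mean(sp$dv),
           max_dv = max(sp$dv), round = sp$round)
  }))
}

#' @export
glance.species_sort <- function(x, ...) {
  tibble(n_species = length(x$species), n_outliers = length(x$outliers),
         n_cells = x$n_cells, n_rounds = max(c(0L, purrr::map_int(x$species,
                                                                  "round"))),
         stop_reason = x$stop_reason)
}

#' @export
augment.species_sort <- function(x, ...) {
  assign <- tibble(cell_id = x$cells, cluster = NA_integer_, dv = NA_real_)
  for (sp in x$species) {
    idx <- match(sp$cells, assign$cell_id)
    assign$cluster[idx] <- sp$ordinal
    assign$dv[idx] <- sp$dv
  }
  assign$outlier <- assign$cell_id %in% x$outliers
  if (!is.null(x$labels)) assign$species <- x$labels
  assign
}

#' Plot a species-sorting result
#'
#' `type = "errors"` shows the distribution of log10 validation errors
#' of the classified cells, coloured by discovered cluster --- the
#' quantity the Gaussian-mixture classifier operates on.  `type =
#' "modes"` shows the learned radial force-mode profiles of each
#' aggregate model.
#'
#' @param object A `species_sort` object.
#' @param type `"errors"` or `"modes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_sort <- function(object, type = c("errors", "modes"), ...) {
  type <- match.arg(type)
  if (type == "errors") {
    df <- augment(object) |> filter(!is.na(.data$cluster))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$dv),
                                       fill = factor(.data$cluster))) +
        ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
        ggplot2::labs(x = "log10 validation error", y = "cells",
                      fill = "cluster") +
        ggplot2::theme_minimal()
    )
  }
  lib <- object$models$library
  r <- seq(0, max(2, object$models$r_max), length.out = 400)
  n_r <- length(r)
  rows <- purrr::map(object$species, function(sp) {
    mp <- mode_profiles(sp$model$w, lib, max(r), 1, nr = n_r, ns = 2)
    tibble(cluster = sp$ordinal, r = rep(r, 6),
           profile = c(mp$AR[, 1], mp$AR[, 2], mp$AR[, 3],
                       mp$AL[, 1], mp$AL[, 2], mp$AL[, 3]),
           mode = rep(c("ar0", "ar1", "ar2", "align0", "align1", "align2"),
                      each = n_r))
  })
  ggplot2::ggplot(bind_rows(rows),
                  ggplot2::aes(x = .data$r, y = .data$profile,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = "distance r", y = "force mode profile",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
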