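# Model replacement ("cross-pollination"): models learned from highly
# informative trajectories are transferred to statistically similar
# cells whose own models validate worse.

#' Per-cell trajectory statistics
#'
#' Fifty-bin normalised histograms, with bin edges shared across the
#' population, of (i) distances from each cell to all others pooled
#' over frames, (ii) velocity differences to all others, and (iii) the
#' cell's own speed.  These summarise how much information a trajectory
#' carries about each of the three forces.
#'
#' @param data Trajectory tibble.
#' @param nbins Number of histogram bins.
#' @return List with matrices `rr`, `vv`, `v` (`nbins` x N, columns sum
#'   to 1) and the shared upper edges `r_max`, `dv_max`, `v_max`.
#' @export
cell_statistics <- function(data, nbins = 50) {
  td <- as_traj_mats(data)
  if (td$n < 2) abort("need at least 2 cells")
  V <- finite_diff_velocity(td$px, td$py, td$dt)
  out <- cpp_cell_stats(td$px, td$py, V$vx, V$vy, as.integer(nbins))
  out$cells <- td$ids
  out
}

#' Kullback-Leibler divergence between binned distributions
#'
#' Discrete KL divergence `sum rho * log(rho / nu)` in nats over shared
#' bins.  A small pseudo-mass is added to `nu` (then renormalised) so
#' that empty reference bins do not produce infinities.
#'
#' @param rho,nu Probability vectors over the same bins.
#' @param eps Pseudo-mass added to each bin of `nu`.
#' @return Non-negative scalar (up to pseudo-mass effects).
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.9, 0.1))   # about 0.511
kl_divergence <- function(rho, nu, eps = 1e-10) {
  if (length(rho) != length(nu)) abort("distributions must share bin edges")
  nu <- nu + eps
  nu <- nu / sum(nu)
  pos <- rho > 0
  sum(rho[pos] * log(rho[pos] / nu[pos]))
}

# KL divergence matrix D(i | j) for histogram columns of P.
kl_matrix <- function(P, eps = 1e-10) {
  Nu <- sweep(P + eps, 2, colSums(P + eps), "/")
  self <- colSums(ifelse(P > 0, P * log(P), 0))
  cross <- t(P) %*% log(Nu)               # (i, j): sum_b P_bi log Nu_bj
  matrix(self, nrow(cross), ncol(cross)) - cross
}

#' Select statistically similar validation cells
#'
#' For each cell, ranks the other cells by the squared-KL cost
#' `D(rr_i | rr_j)^2 + D(vv_i | vv_j)^2 + D(v_i | v_j)^2` and keeps the
#' `K` cheapest (ties broken by lower cell id; `K` is clamped to N-1).
#'
#' @param stats Statistics from [cell_statistics()].
#' @param K Number of validation cells per cell.
#' @return Integer matrix, one row per cell, of validation-cell indices
#'   (positions, not ids).
#' @export
select_validation_cells <- function(stats, K = 32) {
  if (K < 1) abort("K must be at least 1")
  N <- ncol(stats$rr)
  cost <- kl_matrix(stats$rr)^2 + kl_matrix(stats$vv)^2 + kl_matrix(stats$v)^2
  K <- min(K, N - 1)
  out <- matrix(0L, N, K)
  for (i in seq_len(N)) {
    ord <- order(cost[i, ], seq_len(N))
    ord <- ord[ord != i]
    out[i, ] <- ord[seq_len(K)]
  }
  out
}

#' Replacement decisions from validation-error tables
#'
#' Model `M_j` may replace `M_i` when cells i and j are mutual
#' validation cells and (1) `M_j` beats `M_i` on cell i, (2) `M_j`
#' beats `M_i` on cell j, and (3) `M_j` achieves error below `tol` on
#' both cells.  Each cell takes the best qualifying donor (smallest
#' error on itself), and donations chain: if `M_k` replaces `M_j` which
#' replaces `M_i`, cell i receives `M_k`.
#'
#' @param dv_self Vector of `dv[i]` = error of model i on cell i.
#' @param dv_cross Matrix or tibble of cross errors: `dv_cross[j, i]` =
#'   error of model j simulated on cell i (`NA` where not computed).
#' @param mutual Logical matrix; `mutual[i, j]` marks mutual validation
#'   pairs.
#' @param tol Error tolerance for condition (3).
#' @return Integer vector `source`; `source[i] = j` means cell i ends
#'   with model j (identity where no replacement occurs).
#' @export
replacement_decisions <- function(dv_self, dv_cross, mutual, tol = 0.25) {
  N <- length(dv_self)
  source <- seq_len(N)
  direct <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    best_j <- NA_integer_
    best_dv <- Inf
    for (j in seq_len(N)) {
      if (j == i || !isTRUE(mutual[i, j])) next
      dv_ji <- dv_cross[j, i]
      dv_ij <- dv_cross[i, j]
      if (is.na(dv_ji) || is.na(dv_ij)) next
      ok <- dv_self[i] > dv_ji &&
        dv_ij > dv_self[j] &&
        max(dv_ji, dv_self[j]) < tol
      if (ok && dv_ji < best_dv) {
        best_dv <- dv_ji
        best_j <- j
      }
    }
    direct[i] <- best_j
  }
  # transitive closure along donor chains, guarded against cycles
  for (i in seq_len(N)) {
    if (is.na(direct[i])) next
    j <- direct[i]
    seen <- c(i)
    while (!is.na(direct[j]) && !(direct[j] %in% seen)) {
      seen <- c(seen, j)
      j <- direct[j]
    }
    source[i] <- j
  }
  source
}

#' Replace poorly fitting models with better neighbours' models
#'
#' Runs the full replacement pass: per-cell statistics, mutual
#' validation-cell selection, data-driven validation of each model on
#' itself and on its mutual validation cells, then the replacement
#' decisions of [replacement_decisions()] including donor chains.
#'
#' @param models A `cell_models` object.
#' @param data Trajectory tibble the models were learned from.
#' @param config Pipeline configuration from [swarm_config()].
#' @param setup Optional precomputed validation setup (internal reuse).
#' @return The updated `cell_models` with a `replacement_log` attribute:
#'   a tibble of `cell_id`, `replaced_by`, `dv_before`, `dv_after`.
#' @export
replacement_pass <- function(models, data, config = swarm_config(),
                             setup = NULL) {
  td <- as_traj_mats(data)
  if (is.null(setup)) setup <- validation_setup(td, config)
  stats <- cpp_cell_stats(td$px, td$py, setup$vx_all, setup$vy_all, 50L)
  vcells <- select_validation_cells(stats, config$K)
  N <- length(models$cells)
  mutual <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    for (j in vcells[i, ]) {
      if (i %in% vcells[j, ]) mutual[i, j] <- TRUE
    }
  }

  profs <- model_profiles(models$W, models$library, setup)
  # own-model errors
  dv_self <- validate_tasks(cbind(seq_len(N), seq_len(N)), profs, setup, config)
  # cross errors for mutual pairs where the donor passes tol on itself
  pairs <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  tasks <- NULL
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    # cross errors are only consulted when one of the two models passes
    # the tolerance on its own cell (condition 3 fails otherwise)
    if (dv_self[j] < config$tol_replace || dv_self[i] < config$tol_replace) {
      tasks <- rbind(tasks, c(j, i), c(i, j))
    }
  }
  dv_cross <- matrix(NA_real_, N, N)
  if (!is.null(tasks) && nrow(tasks) > 0) {
    dv <- validate_tasks(tasks, profs, setup, config)
    dv_cross[tasks] <- dv
  }
  source <- replacement_decisions(dv_self, dv_cross, mutual,
                                  tol = config$tol_replace)

  replaced <- which(source != seq_len(N))
  log <- tibble(
    cell_id = models$cells[replaced],
    replaced_by = models$cells[source[replaced]],
    dv_before = dv_self[replaced],
    dv_after = dv_cross[cbind(source[replaced], replaced)]
  )
  models$W[, replaced] <- models$W[, source[replaced], drop = FALSE]
  models$lambda[replaced] <- models$lambda[source[replaced]]
  models$code[replaced] <- models$code[source[replaced]]
  models$provenance[replaced] <- paste0("replaced_from:",
                                        models$cells[source[replaced]])
  attr(models, "replacement_log") <- log
  models
}
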