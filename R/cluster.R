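# Clustering learned models by their active directional force modes and
# averaging the largest cluster into a candidate species model.

# Mode order of the 8-bit code:
MODE_NAMES <- c("ar0", "ar1", "ar2", "align0", "align1", "align2",
                "drag0", "drag1")

#' Directional force-mode code of a model
#'
#' Each force decomposes into directional modes `f = f0 + cos(theta) f1
#' + cos(2 theta) f2` (drag has modes 0 and 1 only).  A library term
#' with factor `cos(n theta)` activates mode n of its block; a shifted
#' factor `(1 + cos(n theta))` activates modes 0 and n.  The code is
#' the 8-bit string over the ordered modes (attraction-repulsion 0-2,
#' alignment 0-2, drag 0-1) marking which modes carry any nonzero
#' coefficient.
#'
#' @param w Coefficient vector over the library.
#' @param library Library from [force_library()].
#' @return 8-character string of 0s and 1s.
#' @export
#' @examples
#' lib <- force_library()
#' force_mode_code(rep(0, nrow(lib)), lib)   # "00000000"
force_mode_code <- function(w, library) {
  stopifnot(length(w) == nrow(library))
  bits <- setNames(rep(FALSE, 8), MODE_NAMES)
  nz <- which(w != 0)
  for (j in nz) {
    blk <- library$block[j]
    n <- library$n[j]
    if (blk == "ar") {
      bits[paste0("ar", n)] <- TRUE
    } else {
      bits[paste0(blk, 0)] <- TRUE
      if (n >= 1) bits[paste0(blk, n)] <- TRUE
    }
  }
  paste(as.integer(bits), collapse = "")
}

#' Partition models into clusters by force-mode code
#'
#' Groups models with identical 8-bit codes; the largest cluster is the
#' candidate for aggregation (ties broken by the smaller numeric code).
#'
#' @param models A `cell_models` object, or a character vector of codes.
#' @return List with `clusters` (a tibble of `code`, `size`, and member
#'   list-column `cells`) and `largest` (the code of the largest
#'   cluster).
#' @export
partition_by_code <- function(models) {
  if (inherits(models, "cell_models")) {
    codes <- models$code
    cells <- models$cells
  } else {
    codes <- as.character(models)
    cells <- seq_along(codes)
  }
  if (length(codes) == 0) abort("need at least one model")
  cl <- tibble(code = codes, cell = cells) |>
    group_by(.data$code) |>
    summarise(size = n(), cells = list(.data$cell), .groups = "drop") |>
    arrange(dplyr::desc(.data$size), strtoi(.data$code, base = 2))
  list(clusters = cl, largest = cl$code[1])
}

#' Aggregate a model cluster
#'
#' Uniform average of the member coefficient vectors (zeros included),
#' followed by one round of magnitude thresholding: entries below
#' `10^-lambda_log` times the largest absolute averaged coefficient are
#' zeroed, which only prunes negligible terms before forward
#' simulation.
#'
#' @param W J x k matrix of member coefficient vectors (or a
#'   `cell_models` object together with `cells`).
#' @param library Library from [force_library()].
#' @param lambda_log Threshold decades below the maximum (default 4).
#' @param cells Optional member ids recorded in the result.
#' @return List with averaged coefficients `w`, the `code`, `cells`, and
#'   cluster size `size`.
#' @export
aggregate_cluster <- function(W, library, lambda_log = 4, cells = NULL) {
  if (inherits(W, "cell_models")) {
    models <- W
    if (is.null(cells)) cells <- models$cells
    W <- models$W[, match(cells, models$cells), drop = FALSE]
    library <- models$library
  }
  if (ncol(W) == 0) abort("cluster must be non-empty")
  wbar <- rowMeans(W)
  mx <- max(abs(wbar))
  if (mx > 0) wbar[abs(wbar) < 10^(-lambda_log) * mx] <- 0
  list(w = wbar, code = force_mode_code(wbar, library),
       cells = cells, size = ncol(W))
}
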