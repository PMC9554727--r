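# Internal helpers: long-format trajectory tables <-> frame-by-cell matrices.

TIME_REL_TOL <- 1e-10

# Validate a long trajectory table and convert to matrices.
# Returns list(px, py [L x N], times, ids, labels or NULL, dt, n, L).
as_traj_mats <- function(data) {
  need <- c("cell_id", "frame", "t", "x", "y")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- dplyr::arrange(as_tibble(data), .data$cell_id, .data$frame)
  ids <- unique(data$cell_id)
  n <- length(ids)
  L <- nrow(data) / n
  if (L != round(L)) {
    abort("all cells must be observed at the same set of frames")
  }
  L <- as.integer(L)
  times <- data$t[seq_len(L)]
  if (L < 2) abort("need at least 2 frames")
  dts <- diff(times)
  if (any(dts <= 0) || diff(range(dts)) > TIME_REL_TOL * max(abs(dts))) {
    abort("time stamps must be strictly increasing with uniform spacing")
  }
  # every cell must carry the same time grid
  tmat <- matrix(data$t, nrow = L)
  if (max(abs(tmat - times)) > TIME_REL_TOL * max(1, max(abs(times)))) {
    abort("cells observed at inconsistent time stamps")
  }
  if (any(!is.finite(data$x)) || any(!is.finite(data$y))) {
    abort("all positions must be finite")
  }
  labels <- NULL
  if ("species" %in% names(data)) {
    lab <- matrix(as.character(data$species), nrow = L)
    labels <- lab[1, ]
  }
  list(px = matrix(data$x, nrow = L), py = matrix(data$y, nrow = L),
       times = times, ids = ids, labels = labels,
       dt = mean(dts), n = n, L = L)
}

# Long tibble from matrices.
traj_tibble <- function(px, py, times, ids, labels = NULL) {
  L <- nrow(px); n <- ncol(px)
  out <- tibble(
    cell_id = rep(ids, each = L),
    frame = rep(seq_len(L), times = n),
    t = rep(times, times = n),
    x = as.vector(px),
    y = as.vector(py)
  )
  if (!is.null(labels)) out$species <- rep(labels, each = L)
  out
}

# Restore-on-exit seeded evaluation so package functions do not disturb the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
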