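#' Assign DOFs to parcellation regions
#'
#' Every DOF takes the label of its nearest parcellation point (Euclidean
#' distance, ties to the lowest region id). DOFs farther than `cap` from any
#' point are left unassigned (sentinel `NA`).
#'
#' @param parc a [parcellation()].
#' @param dof_positions n x 3 matrix of DOF positions (m).
#' @param cap distance cap in meters (default 10 mm).
#' @return integer region id per DOF (`NA` = unassigned).
#' @export
assign_dofs_to_regions <- function(parc, dof_positions, cap = 0.010) {
  dof_positions <- as_points3(dof_positions)
  if (!nrow(parc$points) || !nrow(dof_positions))
    stop("parcellation points and DOF positions must be non-empty")
  # order points by label so distance ties resolve to the lowest region id
  ord <- order(parc$labels)
  pts <- parc$points[ord, , drop = FALSE]
  labs <- parc$labels[ord]
  idx <- nearest_index(dof_positions, pts)
  d <- rownorms(dof_positions - pts[idx, , drop = FALSE])
  out <- labs[idx]
  out[d > cap] <- NA_integer_
  if (all(is.na(out)))
    warning("all DOFs farther than the distance cap from any ",
            "parcellation point")
  out
}

#' Region activity time series
#'
#' Scalarizes a reconstruction to per-DOF amplitudes (Euclidean norm over
#' the k components at each time step) and aggregates member-DOF amplitudes
#' per region and time step with the requested statistic.
#'
#' @param reconstruction DOF-coefficient matrix, (n_loc * k) x time.
#' @param assignment region id per location (from
#'   [assign_dofs_to_regions()]).
#' @param stat `"max"` or `"median"`.
#' @param k components per location.
#' @return An object of class `region_time_series`: `regions` (sorted ids),
#'   `values` (region x time), `stat`, `empty` (regions with no DOFs, rows
#'   of zeros).
#' @export
region_time_series <- function(reconstruction, assignment,
                               stat = c("max", "median"), k = 1L) {
  stat <- match.arg(stat)
  reconstruction <- as.matrix(reconstruction)
  nt <- ncol(reconstruction)
  nloc <- nrow(reconstruction) / k
  amp <- if (k == 1L) abs(reconstruction)
  else {
    a <- matrix(0, nloc, nt)
    for (c3 in seq_len(k))
      a <- a + reconstruction[seq(c3, by = k, length.out = nloc), ,
                              drop = FALSE]^2
    sqrt(a)
  }
  regions <- sort(unique(assignment[!is.na(assignment)]))
  if (!length(regions)) stop("no assigned DOFs")
  fun <- if (stat == "max") max else median
  vals <- matrix(0, length(regions), nt)
  empty <- logical(length(regions))
  for (r in seq_along(regions)) {
    rows <- which(!is.na(assignment) & assignment == regions[r])
    if (!length(rows)) { empty[r] <- TRUE; next }
    vals[r, ] <- apply(amp[rows, , drop = FALSE], 2L, fun)
  }
  structure(list(regions = regions, values = vals, stat = stat,
                 empty = empty),
            class = "region_time_series")
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment with absolute-difference local
#' cost, unit steps (1,0), (0,1), (1,1) and no warping window.
#'
#' @param a,b numeric series (non-empty).
#' @return the DTW distance (>= 0).
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty series")
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    cost <- abs(a[i] - b)
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- cost[j] + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Statistics of region time series
#'
#' @param ts a `region_time_series`.
#' @return list with `amplitude` (per-region max absolute value), `std`,
#'   `correlation`, `covariance` (over the time axis; correlations of
#'   constant series are set to 0 and flagged in `constant`), and the
#'   symmetric zero-diagonal `dtw` matrix.
#' @export
series_statistics <- function(ts) {
  v <- ts$values
  nr <- nrow(v)
  if (ncol(v) < 2L) stop("need >= 2 time steps for std/correlation")
  amplitude <- apply(abs(v), 1L, max)
  stds <- apply(v, 1L, sd)
  covm <- cov(t(v))
  constant <- stds == 0
  corm <- matrix(0, nr, nr)
  ok <- which(!constant)
  if (length(ok))
    corm[ok, ok] <- cor(t(v[ok, , drop = FALSE]))
  dtwm <- matrix(0, nr, nr)
  if (nr > 1L)
    for (i in 1:(nr - 1L)) for (j in (i + 1L):nr) {
      dtwm[i, j] <- dtwm[j, i] <- dtw_distance(v[i, ], v[j, ])
    }
  list(amplitude = amplitude, std = stds, correlation = corm,
       covariance = covm, dtw = dtwm, constant = constant)
}

#' Export region time series as delimited text
#'
#' One row per region with a region-name header column.
#'
#' @param ts a `region_time_series`.
#' @param path output path.
#' @param colortable optional colortable data.frame (`id`, `name`) to name
#'   the regions.
#' @return `path`, invisibly.
#' @export
write_region_time_series <- function(ts, path, colortable = NULL) {
  nm <- as.character(ts$regions)
  if (!is.null(colortable))
    nm <- colortable$name[match(ts$regions, colortable$id)]
  df <- data.frame(region = nm, ts$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
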