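#' Lead-field matrix container
#'
#' @param L dense sensors x columns matrix.
#' @param row_labels electrode / measurement identifiers.
#' @param column_layout one of `"cartesian3"`, `"normal1"`,
#'   `"raw_whitney"`, `"eit_dof"`.
#' @param positions DOF positions backing the columns (one row per location).
#' @param orientations optional orientations.
#' @param reference EEG row reference; `"common_average"`.
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(L, row_labels = NULL, column_layout, positions = NULL,
                       orientations = NULL, reference = "common_average") {
  structure(list(L = L, row_labels = row_labels %||% seq_len(nrow(L)),
                 column_layout = column_layout, positions = positions,
                 orientations = orientations, reference = reference),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d sensors x %d columns (%s, reference %s)\n",
              nrow(x$L), ncol(x$L), x$column_layout, x$reference))
  invisible(x)
}

# node parts of the transfer solves: column l solves the augmented CEM
# system for the deflated unit pattern at electrode l
transfer_matrix <- function(system, tol = 1e-8, max_iter = NULL) {
  K <- cem_matrix(system)
  d <- lumped_diagonal_preconditioner(K)
  n <- system$n_nodes; E <- system$n_electrodes
  Tn <- matrix(0, n, E); Te <- matrix(0, E, E)
  for (l in seq_len(E)) {
    rhs <- c(numeric(n), (seq_len(E) == l) - 1 / E)
    sol <- solve_pcg(K, rhs, tol = tol, max_iter = max_iter, precond = d,
                     deflate = TRUE)
    if (!sol$converged)
      stop("PCG failed to converge for electrode ", l,
           " (rel residual ", signif(sol$rel_residual, 3), ")")
    Tn[, l] <- sol$x[seq_len(n)]
    Te[, l] <- sol$x[n + seq_len(E)]
  }
  list(Tn = Tn, Te = Te)
}

#' EEG lead-field matrix
#'
#' Computed via the transfer-matrix approach: one (symmetric) CEM solve per
#' electrode yields the adjoint field `t_l`, and `L[l, k] = t_l . F[, k]`;
#' this equals direct per-source forward solves within solver tolerance but
#' costs `n_electrodes` solves instead of `n_columns`. Rows are
#' re-referenced to the common average, making every column zero-mean.
#'
#' @param system a `fem_system` from [assemble_cem()].
#' @param sources a `source_loads` object (or a plain zero-column-sum load
#'   matrix).
#' @param tol PCG relative-residual tolerance.
#' @param method `"transfer"` (default) or `"direct"` (one forward solve
#'   per source column; used as an internal cross-check).
#' @return A [lead_field()] in volts per unit source strength.
#' @export
eeg_leadfield <- function(system, sources, tol = 1e-8,
                          method = c("transfer", "direct")) {
  method <- match.arg(method)
  F <- if (inherits(sources, "source_loads")) sources$F else sources
  E <- system$n_electrodes
  if (method == "transfer") {
    tm <- transfer_matrix(system, tol = tol)
    L <- as.matrix(Matrix::crossprod(F, tm$Tn))  # K x E
    L <- t(L)
  } else {
    K <- cem_matrix(system)
    d <- lumped_diagonal_preconditioner(K)
    n <- system$n_nodes
    L <- matrix(0, E, ncol(F))
    for (k in seq_len(ncol(F))) {
      rhs <- c(as.numeric(F[, k]), numeric(E))
      sol <- solve_pcg(K, rhs, tol = tol, precond = d, deflate = TRUE)
      if (!sol$converged) stop("PCG failed for source column ", k)
      L[, k] <- sol$x[n + seq_len(E)]
    }
  }
  L <- sweep(L, 2L, colMeans(L))  # common-average reference
  lead_field(L,
             column_layout = if (inherits(sources, "source_loads"))
               sources$layout else "cartesian3",
             positions = if (inherits(sources, "source_loads"))
               sources$positions,
             orientations = if (inherits(sources, "source_loads"))
               sources$orientations)
}

#' Current injection patterns and measurement map
#'
#' Default scheme: every electrode is paired against a fixed reference
#' electrode with unit current, giving `E - 1` zero-sum patterns of rank
#' `E - 1`; measurements are the zero-mean electrode voltages of every
#' pattern.
#'
#' @param electrodes an [electrode_set()] (or an electrode count).
#' @param scheme currently `"reference"`.
#' @param reference index of the reference electrode (default: the last).
#' @return list with `patterns` (E x P matrix of injected currents, columns
#'   zero-sum) and `reference`.
#' @export
measurement_patterns <- function(electrodes, scheme = "reference",
                                 reference = NULL) {
  E <- if (inherits(electrodes, "electrode_set")) nrow(electrodes$centers)
       else as.integer(electrodes)
  if (E < 2L) stop("need at least 2 electrodes")
  if (!identical(scheme, "reference")) stop("unknown scheme: ", scheme)
  if (is.null(reference)) reference <- E
  if (reference < 1L || reference > E)
    stop("scheme names unknown electrode: ", reference)
  others <- setdiff(seq_len(E), reference)
  P <- matrix(0, E, E - 1L)
  for (j in seq_along(others)) {
    P[others[j], j] <- 1
    P[reference, j] <- -1
  }
  list(patterns = P, reference = reference)
}

# per-element gradient of a nodal field (or matrix of fields):
# returns list(gx, gy, gz), each m x n_fields
field_gradients <- function(mesh, u, eg = NULL) {
  if (is.null(eg)) eg <- element_gradients(mesh)
  u <- as.matrix(u)
  tt <- mesh$tetra
  gx <- gy <- gz <- matrix(0, nrow(tt), ncol(u))
  for (i in 1:4) {
    ui <- u[tt[, i], , drop = FALSE]
    gx <- gx + ui * eg$grads[[i]][, 1]
    gy <- gy + ui * eg$grads[[i]][, 2]
    gz <- gz + ui * eg$grads[[i]][, 3]
  }
  list(gx = gx, gy = gy, gz = gz, volume = eg$volume)
}

# nearest center index per point (Euclidean, ties to lowest index)
nearest_index <- function(points, centers) {
  points <- as_points3(points); centers <- as_points3(centers)
  out <- integer(nrow(points))
  cn2 <- rowSums(centers * centers)
  chunk <- max(1L, floor(2e6 / nrow(centers)))
  for (s in seq(1L, nrow(points), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(points))
    blk <- points[s:e, , drop = FALSE]
    d2 <- -2 * blk %*% t(centers)
    d2 <- sweep(d2, 2L, cn2, "+")
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Linearized-EIT lead field (conductivity Jacobian)
#'
#' Adjoint linearization of the CEM forward map around the mesh's background
#' conductivity: for drive field `u_d` and measurement adjoint field `u_m`,
#' the element-level Jacobian is `J[(d,m), e] = -V_e (grad u_d . grad
#' u_m)_e` (gradients are constant per element, so the integral is exact).
#' Element columns are aggregated to conductivity DOFs by nearest-DOF-center
#' assignment, restricted to elements of the designated compartments.
#'
#' @param system a `fem_system`.
#' @param mesh the [tet_mesh()] the system was assembled from.
#' @param dof_centers n_dof x 3 matrix of DOF center points (m).
#' @param patterns current-pattern matrix from [measurement_patterns()] (or
#'   the list it returns).
#' @param restrict_labels compartment indices whose elements carry
#'   conductivity DOFs (default: the active compartments).
#' @param tol PCG tolerance.
#' @return A [lead_field()] with `column_layout = "eit_dof"`, rows ordered
#'   pattern-major (all electrodes of pattern 1, then pattern 2, ...);
#'   extra fields `assignment` (DOF per restricted element) and `elements`
#'   (the restricted element indices).
#' @export
eit_leadfield <- function(system, mesh, dof_centers, patterns,
                          restrict_labels = NULL, tol = 1e-8) {
  if (is.list(patterns) && !is.null(patterns$patterns))
    patterns <- patterns$patterns
  if (is.null(restrict_labels))
    restrict_labels <- which(mesh$compartments$active)
  dof_centers <- as_points3(dof_centers)
  tm <- transfer_matrix(system, tol = tol)
  eg <- element_gradients(mesh)
  # adjoint fields: one per electrode (zero-mean voltage measurements)
  gm <- field_gradients(mesh, tm$Tn, eg)
  # drive fields: combinations of transfer columns
  Ud <- tm$Tn %*% patterns
  gd <- field_gradients(mesh, Ud, eg)
  el <- which(mesh$labels %in% restrict_labels)
  if (!length(el)) stop("no elements in the designated compartments")
  assignment <- nearest_index(tet_barycenters(mesh)[el, , drop = FALSE],
                              dof_centers)
  n_dof <- nrow(dof_centers)
  if (length(unique(assignment)) < n_dof) {
    missing_dof <- setdiff(seq_len(n_dof), unique(assignment))
    stop("DOF(s) with no assigned element: ",
         paste(head(missing_dof, 10L), collapse = ", "))
  }
  E <- system$n_electrodes; P <- ncol(patterns)
  L <- matrix(0, P * E, n_dof)
  ve <- eg$volume[el]
  agg <- Matrix::sparseMatrix(i = seq_along(el), j = assignment, x = 1,
                              dims = c(length(el), n_dof))
  for (d in seq_len(P)) {
    dot <- gd$gx[el, d] * gm$gx[el, , drop = FALSE] +
      gd$gy[el, d] * gm$gy[el, , drop = FALSE] +
      gd$gz[el, d] * gm$gz[el, , drop = FALSE]
    rows <- -t(ve * dot) %*% agg  # E x n_dof
    L[(d - 1L) * E + seq_len(E), ] <- as.matrix(rows)
  }
  lf <- lead_field(L, column_layout = "eit_dof", positions = dof_centers,
                   reference = "common_average",
                   row_labels = paste0("p", rep(seq_len(P), each = E),
                                       "_e", rep(seq_len(E), P)))
  lf$assignment <- assignment
  lf$elements <- el
  lf
}

#' Export a lead field as delimited text
#'
#' @param lf a [lead_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_leadfield_text <- function(lf, path) {
  utils::write.table(lf$L, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
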