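#' Electrode set
#'
#' Ring (annulus) or disc electrodes for the complete electrode model.
#'
#' @param centers E x 3 matrix of electrode center positions (m).
#' @param impedances contact impedance per electrode (Ohm), recycled.
#' @param outer_diameter,inner_diameter electrode ring geometry (m);
#'   `inner_diameter = 0` gives a disc.
#' @return An object of class `electrode_set`.
#' @export
electrode_set <- function(centers, impedances = 1000,
                          outer_diameter = 0.010, inner_diameter = 0) {
  centers <- as_points3(centers, "electrode centers")
  impedances <- rep_len(as.numeric(impedances), nrow(centers))
  if (any(impedances <= 0)) stop("impedances must be > 0")
  if (inner_diameter >= outer_diameter)
    stop("inner_diameter must be < outer_diameter")
  structure(list(centers = centers, impedances = impedances,
                 outer_diameter = outer_diameter,
                 inner_diameter = inner_diameter),
            class = "electrode_set")
}

# per-element linear-basis gradients and volumes.
# grads[[i]] is an m x 3 matrix holding grad(lambda_i) per element.
element_gradients <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tetra
  e1 <- nd[tt[, 2], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e2 <- nd[tt[, 3], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e3 <- nd[tt[, 4], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  v6 <- rowSums(e1 * cross3(e2, e3))
  if (any(abs(v6) < .Machine$double.eps * 100))
    stop("zero-volume element: ",
         paste(head(which(abs(v6) < .Machine$double.eps * 100), 5L),
               collapse = ", "))
  g2 <- cross3(e2, e3) / v6
  g3 <- cross3(e3, e1) / v6
  g4 <- cross3(e1, e2) / v6
  g1 <- -(g2 + g3 + g4)
  list(grads = list(g1, g2, g3, g4), volume = v6 / 6)
}

# apply per-element conductivity (scalar or 6-component tensor rows) to an
# m x 3 field of vectors
apply_sigma <- function(conductivity, g) {
  if (is.matrix(conductivity)) {
    s <- conductivity
    cbind(s[, 1] * g[, 1] + s[, 4] * g[, 2] + s[, 5] * g[, 3],
          s[, 4] * g[, 1] + s[, 2] * g[, 2] + s[, 6] * g[, 3],
          s[, 5] * g[, 1] + s[, 6] * g[, 2] + s[, 3] * g[, 3])
  } else conductivity * g
}

#' Assemble the FE stiffness matrix
#'
#' `A[i,j] = sum_T V_T (grad phi_i)' sigma_T (grad phi_j)` with constant
#' linear-basis gradients per tetrahedron. Isotropic conductivities are
#' treated as `sigma * I`; 6-component rows as symmetric tensors.
#'
#' @param mesh a [tet_mesh()].
#' @return sparse symmetric `dgCMatrix`, nodes x nodes, in siemens.
#' @export
assemble_stiffness <- function(mesh) {
  eg <- element_gradients(mesh)
  tt <- mesh$tetra
  n <- nrow(mesh$nodes); m <- nrow(tt)
  ii <- jj <- integer(16L * m); xx <- numeric(16L * m)
  pos <- 0L
  sg <- lapply(eg$grads, function(g) apply_sigma(mesh$conductivity, g))
  for (i in 1:4) for (j in 1:4) {
    val <- eg$volume * rowSums(sg[[i]] * eg$grads[[j]])
    idx <- pos + seq_len(m)
    ii[idx] <- tt[, i]; jj[idx] <- tt[, j]; xx[idx] <- val
    pos <- pos + m
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
}

#' Assemble the complete-electrode-model system
#'
#' Electrode patches are the boundary triangles whose centroid, projected on
#' the electrode's local tangent plane, falls inside the ring annulus. The
#' CEM adds, per electrode `l` with impedance `Z_l` and patch `e_l`:
#' `M[i,j] += (1/Z_l) int_{e_l} phi_i phi_j dS`,
#' `B[i,l] = (1/Z_l) int_{e_l} phi_i dS`, `C[l,l] = |e_l| / Z_l`,
#' all with exact closed-form triangle integrals.
#'
#' @param mesh a [tet_mesh()].
#' @param electrodes an [electrode_set()].
#' @return An object of class `fem_system`: fields `A`, `M`, `B`, `C`
#'   (diagonal vector), `electrode_patches` (boundary-face index list),
#'   `boundary` (the [boundary_faces()] structure), `patch_centers`
#'   (area-weighted effective electrode positions on the discrete
#'   boundary), `n_nodes`, `n_electrodes`.
#' @export
assemble_cem <- function(mesh, electrodes) {
  A <- assemble_stiffness(mesh)
  bf <- boundary_faces(mesh)
  n <- nrow(mesh$nodes)
  E <- nrow(electrodes$centers)
  r_out <- electrodes$outer_diameter / 2
  r_in <- electrodes$inner_diameter / 2
  patches <- vector("list", E)
  Mi <- Mj <- integer(0); Mx <- numeric(0)
  Bi <- Bl <- integer(0); Bx <- numeric(0)
  Cd <- numeric(E)
  # electrode centers are projected onto the discrete boundary (nearest
  # boundary-face centroid): nominal positions sit on the smooth anatomy,
  # which the voxelized surface approximates to within a cell size. The
  # axial cap keeps the patch on the local surface sheet.
  for (l in seq_len(E)) {
    d2 <- rowSums((bf$centroid - matrix(electrodes$centers[l, ],
                                        nrow(bf$centroid), 3,
                                        byrow = TRUE))^2)
    near <- which.min(d2)
    ctr <- bf$centroid[near, ]
    nhat <- bf$normal[near, ]
    rel <- bf$centroid - matrix(ctr, nrow(bf$centroid), 3, byrow = TRUE)
    t_ax <- as.vector(rel %*% nhat)
    radial <- sqrt(pmax(rowSums(rel * rel) - t_ax^2, 0))
    sel <- which(radial >= r_in & radial <= r_out & abs(t_ax) <= r_out)
    if (!length(sel))
      stop("electrode ", l, " has an empty patch (no boundary triangles ",
           "inside its annulus)")
    patches[[l]] <- sel
    Z <- electrodes$impedances[l]
    ar <- bf$area[sel]
    fc <- bf$face[sel, , drop = FALSE]
    # int phi_i phi_j dS = area * (1 + delta_ij) / 12
    for (i in 1:3) for (j in 1:3) {
      Mi <- c(Mi, fc[, i]); Mj <- c(Mj, fc[, j])
      Mx <- c(Mx, ar * (1 + (i == j)) / (12 * Z))
    }
    # int phi_i dS = area / 3
    for (i in 1:3) {
      Bi <- c(Bi, fc[, i]); Bl <- c(Bl, rep(l, length(sel)))
      Bx <- c(Bx, ar / (3 * Z))
    }
    Cd[l] <- sum(ar) / Z
    patch_centers <- if (l == 1L) matrix(0, E, 3) else patch_centers
    patch_centers[l, ] <- colSums(bf$centroid[sel, , drop = FALSE] * ar) /
      sum(ar)
  }
  M <- Matrix::sparseMatrix(i = Mi, j = Mj, x = Mx, dims = c(n, n))
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  B <- Matrix::sparseMatrix(i = Bi, j = Bl, x = Bx, dims = c(n, E))
  structure(list(A = A, M = M, B = B, C = Cd,
                 electrode_patches = patches, boundary = bf,
                 patch_centers = patch_centers,
                 n_nodes = n, n_electrodes = E),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("fem_system: %d nodes, %d electrodes, nnz(A) = %d\n",
              x$n_nodes, x$n_electrodes, Matrix::nnzero(x$A)))
  invisible(x)
}

#' Augmented CEM matrix
#'
#' `[[A + M, -B], [-B', diag(C)]]`: symmetric positive semi-definite with a
#' one-dimensional null space (constant potential over nodes and
#' electrodes).
#'
#' @param system a `fem_system` from [assemble_cem()].
#' @return sparse symmetric matrix of size `(n_nodes + n_electrodes)^2`.
#' @export
cem_matrix <- function(system) {
  K <- rbind(cbind(system$A + system$M, -system$B),
             cbind(-Matrix::t(system$B),
                   Matrix::sparseMatrix(i = seq_along(system$C),
                                        j = seq_along(system$C),
                                        x = system$C)))
  Matrix::forceSymmetric(K)
}

#' Lumped diagonal preconditioner
#'
#' Each diagonal entry is the row sum of the absolute values of the matrix
#' entries: `d_i = sum_j |A_ij|`.
#'
#' @param A square sparse (or dense) matrix.
#' @return numeric vector of diagonal entries.
#' @export
lumped_diagonal_preconditioner <- function(A) {
  d <- Matrix::rowSums(abs(A))
  if (any(d == 0))
    stop("zero row(s) in matrix (disconnected node): ",
         paste(head(which(d == 0), 5L), collapse = ", "))
  as.numeric(d)
}

#' Preconditioned conjugate gradient solver
#'
#' PCG under the lumped diagonal preconditioner, with optional deflation of
#' the constant null vector (pure-Neumann / CEM gauge). The operator may be
#' given as a matrix or as an abstract matrix-vector-product function, so an
#' accelerated backend can be swapped in without touching the algorithm.
#'
#' @param A symmetric positive semi-definite matrix, or a function `v ->
#'   A %*% v`.
#' @param b right-hand side.
#' @param tol relative-residual stopping tolerance.
#' @param max_iter iteration cap (default `3 * length(b)`).
#' @param precond diagonal preconditioner vector; computed from `A` with
#'   [lumped_diagonal_preconditioner()] when `A` is a matrix and `precond`
#'   is `NULL`.
#' @param deflate if `TRUE`, project the constant vector out of `b`, the
#'   iterates and the residual (required for the singular CEM system).
#' @return list with `x`, `converged`, `iterations`, `rel_residual`.
#' @export
solve_pcg <- function(A, b, tol = 1e-8, max_iter = NULL, precond = NULL,
                      deflate = FALSE) {
  n <- length(b)
  if (is.null(max_iter)) max_iter <- 3L * n
  matvec <- if (is.function(A)) A else function(v) as.numeric(A %*% v)
  if (is.null(precond)) {
    precond <- if (is.function(A)) rep(1, n)
               else lumped_diagonal_preconditioner(A)
  }
  proj <- if (deflate) function(v) v - mean(v) else identity
  b <- proj(b)
  bn <- vnorm(b)
  if (bn == 0) return(list(x = numeric(n), converged = TRUE,
                           iterations = 0L, rel_residual = 0))
  x <- numeric(n)
  r <- b
  z <- proj(r / precond)
  p <- z
  rz <- sum(r * z)
  best_x <- x; best_res <- bn
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Ap <- proj(matvec(p))
    pAp <- sum(p * Ap)
    if (pAp <= 0) break
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- vnorm(r)
    if (rn < best_res) { best_res <- rn; best_x <- x }
    if (rn / bn <= tol)
      return(list(x = proj(x), converged = TRUE, iterations = it,
                  rel_residual = rn / bn))
    z <- proj(r / precond)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  warning("PCG did not reach tol = ", tol, " in ", it,
          " iterations (rel residual ", signif(best_res / bn, 3), ")")
  list(x = proj(best_x), converged = FALSE, iterations = it,
       rel_residual = best_res / bn)
}

#' Forward CEM solve for injected currents
#'
#' Solves the augmented complete-electrode-model system for a zero-sum
#' current pattern under the zero-mean gauge.
#'
#' @param system a `fem_system`.
#' @param currents injected current per electrode (A); must sum to zero.
#' @param tol,max_iter passed to [solve_pcg()].
#' @return list with node potentials `u`, zero-mean electrode voltages `U`,
#'   and the solver report (`converged`, `iterations`).
#' @export
cem_forward <- function(system, currents, tol = 1e-8, max_iter = NULL) {
  E <- system$n_electrodes
  if (length(currents) != E) stop("need one current per electrode")
  if (abs(sum(currents)) > 1e-12 * max(abs(currents), 1))
    stop("currents must sum to zero (current conservation)")
  K <- cem_matrix(system)
  rhs <- c(numeric(system$n_nodes), currents)
  sol <- solve_pcg(K, rhs, tol = tol, max_iter = max_iter, deflate = TRUE)
  if (!sol$converged)
    warning("cem_forward: PCG flagged non-convergence")
  u <- sol$x[seq_len(system$n_nodes)]
  U <- sol$x[system$n_nodes + seq_len(E)]
  list(u = u, U = U - mean(U), converged = sol$converged,
       iterations = sol$iterations)
}
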