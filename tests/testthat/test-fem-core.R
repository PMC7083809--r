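test_that("stiffness of the reference tetrahedron matches the symbolic
           integrals", {
  A <- as.matrix(assemble_stiffness(ref_tet_mesh()))
  expect_equal(A[1, 1], 1 / 2, tolerance = 1e-14)
  expect_equal(A[2, 2], 1 / 6, tolerance = 1e-14)
  expect_equal(A[1, 2], -1 / 6, tolerance = 1e-14)
  # anisotropic sigma = diag(2,1,1) doubles the x-gradient entry
  A2 <- as.matrix(assemble_stiffness(ref_tet_mesh(
    conductivity = matrix(c(2, 1, 1, 0, 0, 0), 1))))
  expect_equal(A2[2, 2], 2 * A[2, 2], tolerance = 1e-14)
  expect_equal(A2[3, 3], A[3, 3], tolerance = 1e-14)
})

test_that("stiffness is symmetric with zero row sums and is PSD", {
  m <- sphere_mesh_coarse()
  A <- assemble_stiffness(m)
  expect_lt(max(abs(A - Matrix::t(A))), 1e-15)
  rs <- Matrix::rowSums(A)
  expect_lt(max(abs(rs)) / max(abs(A)), 1e-12)
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(abs(ev)))
})

test_that("a single-triangle electrode integrates exactly and scales as
           1/Z", {
  # flat slab; a tiny electrode catches exactly one boundary triangle
  seg <- one_compartment_segmentation(cube_surface(side = 0.02))
  m <- generate_uniform_mesh(seg, 0.01)
  bf <- boundary_faces(m)
  top <- which(abs(bf$centroid[, 3] - 0.02) < 1e-12)[1]
  ctr <- bf$centroid[top, ]
  area <- bf$area[top]
  el1 <- electrode_set(rbind(ctr), impedances = 1,
                       outer_diameter = 2e-3)
  sys1 <- assemble_cem(m, el1)
  expect_length(sys1$electrode_patches[[1]], 1L)
  expect_equal(sys1$C[1], area, tolerance = 1e-12)
  expect_equal(sum(sys1$B[, 1]), area, tolerance = 1e-12)
  # int phi_i phi_j dS closed forms: diag area/6, off-diag area/12
  Msub <- as.matrix(sys1$M[bf$face[top, ], bf$face[top, ]])
  expect_equal(diag(Msub), rep(area / 6, 3), tolerance = 1e-12)
  expect_equal(Msub[1, 2], area / 12, tolerance = 1e-12)

  el2 <- electrode_set(rbind(ctr), impedances = 2, outer_diameter = 2e-3)
  sys2 <- assemble_cem(m, el2)
  expect_equal(sys2$C[1], sys1$C[1] / 2)
  expect_equal(max(abs(sys2$B - sys1$B / 2)), 0)
  expect_equal(max(abs(sys2$M - sys1$M / 2)), 0)
})

test_that("ring-electrode patch area approaches the analytic annulus area
           on a fine flat patch", {
  mk_slab <- function(h) {
    v <- cube_surface(side = 1)$vertices
    v[, 1:2] <- v[, 1:2] * 0.06
    v[, 3] <- v[, 3] * 0.012
    sm <- surface_mesh(v, cube_surface()$triangles, "slab")
    generate_uniform_mesh(one_compartment_segmentation(sm), h)
  }
  target <- pi * (0.005^2 - 0.00375^2)  # 10 / 7.5 mm ring
  for (h in c(0.003, 0.0015)) {
    m <- mk_slab(h)
    el <- electrode_set(rbind(c(0.03, 0.03, 0.012)), 1000,
                        outer_diameter = 0.010, inner_diameter = 0.0075)
    sys <- assemble_cem(m, el)
    expect_lt(abs(sys$C[1] * 1000 - target) / target, 0.10)
  }
})

test_that("empty electrode patches raise an error naming the electrode", {
  m <- sphere_mesh_coarse()
  el <- electrode_set(rbind(c(0, 0, sphere_radius)), 1000,
                      outer_diameter = 0.004, inner_diameter = 0.0038)
  expect_error(assemble_cem(m, el), "electrode 1")
})

test_that("lumped diagonal preconditioner is the absolute row sum", {
  expect_equal(lumped_diagonal_preconditioner(rbind(c(2, -1), c(-1, 2))),
               c(3, 3))
  expect_equal(lumped_diagonal_preconditioner(diag(5)), rep(1, 5))
  expect_error(
    lumped_diagonal_preconditioner(Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                                        dims = c(2, 2))),
    "zero row")
  # CEM coupling only adds boundary mass: d(A+M) >= d(A) entrywise
  sys <- fixture("coarse_system", function()
    assemble_cem(sphere_mesh_coarse(), sphere_electrodes(12)))
  dA <- lumped_diagonal_preconditioner(sys$A)
  dAM <- lumped_diagonal_preconditioner(sys$A + sys$M)
  expect_true(all(dAM >= dA - 1e-15))
})

test_that("PCG solves the identity in one iteration and matches a dense
           direct oracle on the CEM system", {
  b <- c(3, -1, 2)
  sol <- solve_pcg(diag(3), b)
  expect_equal(sol$x, b, tolerance = 1e-14)
  expect_equal(sol$iterations, 1L)

  sys <- fixture("coarse_system", function()
    assemble_cem(sphere_mesh_coarse(), sphere_electrodes(12)))
  K <- cem_matrix(sys)
  n <- sys$n_nodes; E <- sys$n_electrodes
  rhs <- c(numeric(n), (seq_len(E) == 1) - 1 / E)
  sol <- solve_pcg(K, rhs, tol = 1e-10, deflate = TRUE)
  expect_true(sol$converged)
  # dense oracle: ground the last unknown, solve, re-gauge to zero mean
  Kd <- as.matrix(K)
  idx <- seq_len(n + E - 1L)
  xd <- c(solve(Kd[idx, idx], rhs[idx]), 0)
  xd <- xd - mean(xd)
  expect_lt(sqrt(sum((sol$x - xd)^2)) / sqrt(sum(xd^2)), 1e-8)
})

test_that("PCG error decreases monotonically in the A-norm", {
  set.seed(5)
  B <- matrix(rnorm(400), 20)
  A <- crossprod(B) + diag(20)
  b <- rnorm(20)
  xstar <- solve(A, b)
  errs <- numeric(12)
  for (k in seq_len(12)) {
    xk <- suppressWarnings(solve_pcg(A, b, tol = 0, max_iter = k))$x
    e <- xk - xstar
    errs[k] <- sqrt(sum(e * (A %*% e)))
  }
  expect_true(all(diff(errs) <= 1e-10 * errs[1]))
})

test_that("PCG accepts an abstract matrix-vector-product backend", {
  set.seed(6)
  B <- matrix(rnorm(225), 15)
  A <- crossprod(B) + diag(15)
  b <- rnorm(15)
  ref <- solve(A, b)
  sol <- solve_pcg(function(v) as.numeric(A %*% v), b, tol = 1e-12,
                   precond = lumped_diagonal_preconditioner(A))
  expect_equal(sol$x, ref, tolerance = 1e-8)
})

test_that("CEM forward solves obey linearity, reciprocity and current
           conservation", {
  sys <- fixture("coarse_system", function()
    assemble_cem(sphere_mesh_coarse(), sphere_electrodes(12)))
  E <- sys$n_electrodes
  z <- cem_forward(sys, numeric(E))
  expect_equal(max(abs(z$u)), 0)
  expect_equal(max(abs(z$U)), 0)

  I1 <- numeric(E); I1[1] <- 1; I1[3] <- -1
  f1 <- cem_forward(sys, I1, tol = 1e-10)
  f1n <- cem_forward(sys, -I1, tol = 1e-10)
  expect_equal(f1n$U, -f1$U, tolerance = 1e-8)

  I2 <- numeric(E); I2[5] <- 1; I2[8] <- -1
  f2 <- cem_forward(sys, I2, tol = 1e-10)
  expect_equal(f1$U[5] - f1$U[8], f2$U[1] - f2$U[3], tolerance = 1e-8)

  expect_error(cem_forward(sys, rep(1, E)), "sum to zero")
})
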