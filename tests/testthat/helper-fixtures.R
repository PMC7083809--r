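# Shared fixtures. Expensive objects (meshes, transfer matrices) are built
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# unit tetrahedron surface (closed, 4 vertices / 4 faces), coordinates in m
unit_tetra_surface <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) / 1000,
               rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
               name = "tetra")
}

# the same surface as FreeSurfer .ASC text (mm, 0-based faces)
write_tetra_asc <- function(path) {
  writeLines(c("#!ascii test surface",
               "4 4",
               "0 0 0 0", "1 0 0 0", "0 1 0 0", "0 0 1 0",
               "0 2 1 0", "0 1 3 0", "1 2 3 0", "0 3 2 0"), path)
  path
}

# axis-aligned unit cube surface in meters
cube_surface <- function(side = 1, origin = c(0, 0, 0), name = "cube") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) * side
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  surface_mesh(v, f, name)
}

one_compartment_segmentation <- function(surface, conductivity = 1,
                                         active = TRUE) {
  segmentation(list(list(name = surface$name, sub_meshes = list(surface),
                         conductivity = conductivity, priority = 1L,
                         active = active)))
}

# single-compartment unit reference tetrahedron mesh
ref_tet_mesh <- function(conductivity = 1) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1), 1L, conductivity,
           data.frame(name = "ref", conductivity = 1, priority = 1L,
                      active = TRUE))
}

# homogeneous sphere phantom, radius 0.09 m
sphere_radius <- 0.09
sphere_sigma <- 0.33

sphere_mesh_coarse <- function()   # ~1.3k nodes, module-level tests
  fixture("sphere_coarse", function()
    generate_uniform_mesh(
      make_layered_sphere_segmentation(sphere_radius, sphere_sigma, 3,
                                       names = "brain"),
      sphere_radius / 6))

sphere_mesh_fine <- function()     # h = r/10, forward-accuracy tests
  fixture("sphere_fine", function()
    generate_uniform_mesh(
      make_layered_sphere_segmentation(sphere_radius, sphere_sigma, 3,
                                       names = "brain"),
      sphere_radius / 10))

sphere_electrodes <- function(n = 32)
  electrode_set(fibonacci_sphere_points(n, sphere_radius), 1000,
                outer_diameter = 0.010)

sphere_system_fine <- function()
  fixture("sphere_system_fine", function()
    assemble_cem(sphere_mesh_fine(), sphere_electrodes()))

sphere_transfer_fine <- function()
  fixture("sphere_transfer_fine", function()
    neurofem:::transfer_matrix(sphere_system_fine(), tol = 1e-8))

# three-layer head phantom at 12 mm resolution (EIT experiments)
layered_mesh <- function()
  fixture("layered12", function()
    generate_uniform_mesh(
      make_layered_sphere_segmentation(c(0.092, 0.085, 0.080),
                                       c(0.43, 0.0064, 0.33), 3,
                                       names = c("scalp", "skull", "brain")),
      0.012))

layered_electrodes <- function(n = 16)
  electrode_set(fibonacci_sphere_points(n, 0.092), 1000,
                outer_diameter = 0.024)

layered_system <- function()
  fixture("layered_system", function()
    assemble_cem(layered_mesh(), layered_electrodes()))

# all monotone warping paths through an n x m grid (unit steps right/down/
# diagonal), as lists of (i, j) cell index matrices — the exhaustive DTW
# oracle enumerates these independently of the DP recursion
enumerate_warping_paths <- function(n, m) {
  paths <- list()
  walk <- function(i, j, cells) {
    cells <- rbind(cells, c(i, j))
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- cells
      return(invisible())
    }
    if (i < n) walk(i + 1L, j, cells)
    if (j < m) walk(i, j + 1L, cells)
    if (i < n && j < m) walk(i + 1L, j + 1L, cells)
  }
  walk(1L, 1L, matrix(integer(0), 0, 2))
  paths
}

dtw_bruteforce <- function(a, b) {
  paths <- enumerate_warping_paths(length(a), length(b))
  min(vapply(paths, function(p)
    sum(abs(a[p[, 1]] - b[p[, 2]])), 0))
}

# degree-2 (4-point) quadrature rule on a tetrahedron
tet_quad_points <- function(p1, p2, p3, p4) {
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  w <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(points = w %*% rbind(p1, p2, p3, p4), weights = rep(1 / 4, 4))
}
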