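#' Labeled tetrahedral finite-element mesh
#'
#' @param nodes numeric matrix, n x 3, node coordinates in meters.
#' @param tetra integer matrix, m x 4, 1-based node indices; every element
#'   must have positive signed volume.
#' @param labels integer compartment index per element (into `compartments`).
#' @param conductivity per-element scalar (length m) or m x 6 matrix of
#'   symmetric tensor rows (s11,s22,s33,s12,s13,s23) in S/m.
#' @param compartments data.frame with columns `name`, `conductivity`,
#'   `priority`, `active` describing the compartments the labels refer to.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tetra, labels, conductivity, compartments) {
  nodes <- as_points3(nodes, "nodes")
  tetra <- as.matrix(tetra); storage.mode(tetra) <- "integer"
  if (ncol(tetra) != 4L) stop("tetra must have 4 columns")
  if (nrow(tetra) && (min(tetra) < 1L || max(tetra) > nrow(nodes)))
    stop("tetra index out of range")
  labels <- as.integer(labels)
  if (length(labels) != nrow(tetra)) stop("labels length != element count")
  if (nrow(tetra) && any(labels < 1L | labels > nrow(compartments)))
    stop("labels reference non-existing compartments")
  if (is.matrix(conductivity)) {
    if (nrow(conductivity) != nrow(tetra) || ncol(conductivity) != 6L)
      stop("tensor conductivity must be m x 6")
  } else if (length(conductivity) != nrow(tetra))
    stop("conductivity length != element count")
  m <- structure(list(nodes = nodes, tetra = tetra, labels = labels,
                      conductivity = conductivity,
                      compartments = compartments),
                 class = "tet_mesh")
  v <- tet_volumes(m)
  if (nrow(tetra) && any(v <= 0))
    stop("element(s) with non-positive volume: ",
         paste(head(which(v <= 0), 5L), collapse = ", "))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d elements, %d compartments\n",
              nrow(x$nodes), nrow(x$tetra), nrow(x$compartments)))
  tab <- table(factor(x$labels, levels = seq_len(nrow(x$compartments)),
                      labels = x$compartments$name))
  for (nm in names(tab)) cat(sprintf("  %-12s %d elements\n", nm, tab[[nm]]))
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param mesh a [tet_mesh()], or a list with `nodes` and `tetra`.
#' @return numeric vector of signed volumes (m^3) under the stored node
#'   ordering.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tetra
  if (!nrow(tt)) return(numeric(0))
  e1 <- nd[tt[, 2], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e2 <- nd[tt[, 3], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e3 <- nd[tt[, 4], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  rowSums(e1 * cross3(e2, e3)) / 6
}

# barycenters of all elements
tet_barycenters <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tetra
  (nd[tt[, 1], , drop = FALSE] + nd[tt[, 2], , drop = FALSE] +
     nd[tt[, 3], , drop = FALSE] + nd[tt[, 4], , drop = FALSE]) / 4
}

# fixed, deliberately irrational-looking ray directions; three rays with a
# majority vote make the parity test robust to rays grazing triangle edges
ray_directions <- function() {
  r <- rbind(c(0.285430, 0.719482, 0.633190),
             c(-0.614301, 0.293815, 0.732301),
             c(0.421937, -0.842103, 0.335712))
  r / rownorms(r)
}

#' Point-in-surface test by ray-casting parity
#'
#' Casts three fixed rays from each query point, counts triangle crossings
#' and takes a parity majority vote. Intersecting or slightly imperfect
#' surfaces are tolerated.
#'
#' @param points n x 3 matrix of query points (m).
#' @param surfaces a [surface_mesh()] or list of them (a point is inside a
#'   compartment if it is inside any of its sub-meshes).
#' @return logical vector of length n.
#' @export
points_in_surface <- function(points, surfaces) {
  points <- as_points3(points)
  if (inherits(surfaces, "surface_mesh")) surfaces <- list(surfaces)
  inside <- rep(FALSE, nrow(points))
  for (s in surfaces) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- .raycast_inside(points[todo, , drop = FALSE],
                                    s$vertices, s$triangles,
                                    ray_directions())
  }
  inside
}

#' Label mesh elements by compartment
#'
#' Each element's barycenter is tested against the compartments in priority
#' order (lower priority value first, innermost compartment breaking ties);
#' the first containing compartment gives the base label. When an element's
#' nodes fall in two or more compartments, the compartment with the smallest
#' priority value among those wins, which lets high-priority thin layers
#' (e.g. skull) keep their width. Elements whose barycenter lies outside all
#' compartments get the sentinel label 0.
#'
#' @param mesh a `tet_mesh`-like list with `nodes` and `tetra`.
#' @param seg a [segmentation()].
#' @return integer label vector (index into `seg$compartments`; 0 =
#'   unlabeled sentinel).
#' @export
label_elements <- function(mesh, seg) {
  comps <- seg$compartments
  nc <- length(comps)
  bary <- tet_barycenters(mesh)
  prio <- vapply(comps, function(c) as.numeric(c$priority), 0)
  # priority order; innermost (later in the outermost-first list) wins ties
  ord <- order(prio, -seq_len(nc))
  m <- nrow(mesh$tetra); n <- nrow(mesh$nodes)
  lab_b <- integer(m); lab_n <- integer(n)
  for (ci in rev(ord)) {  # lowest-priority first, later wins by overwrite
    inb <- points_in_surface(bary, comps[[ci]]$sub_meshes)
    lab_b[inb] <- ci
    inn <- points_in_surface(mesh$nodes, comps[[ci]]$sub_meshes)
    lab_n[inn] <- ci
  }
  lab <- lab_b
  # node-straddle priority rule, applied only to labelable elements
  el_nl <- matrix(lab_n[mesh$tetra], ncol = 4L)
  straddle <- which(lab_b > 0L &
                      apply(el_nl, 1L, function(r) {
                        r <- r[r > 0L]; length(unique(r)) >= 2L
                      }))
  if (length(straddle)) {
    rank_of <- integer(nc); rank_of[ord] <- seq_len(nc)
    for (e in straddle) {
      cand <- unique(el_nl[e, ]); cand <- cand[cand > 0L]
      lab[e] <- cand[which.min(rank_of[cand])]
    }
  }
  lab
}

#' Generate a uniform labeled tetrahedral mesh
#'
#' Covers the bounding box of the outermost surface with an axis-aligned
#' cubic lattice of the requested spacing, splits each cube into 6
#' tetrahedra (Kuhn split, conforming by construction), labels the elements
#' with [label_elements()] and discards elements outside all compartments.
#'
#' @param seg a [segmentation()].
#' @param resolution lattice spacing in meters.
#' @return A [tet_mesh()].
#' @export
generate_uniform_mesh <- function(seg, resolution) {
  if (!length(seg$compartments)) stop("segmentation is empty")
  if (resolution <= 0) stop("resolution must be > 0")
  # lattice covers the union of all surfaces (the outermost surface's box
  # in a nested segmentation; robust also when boundaries intersect)
  allv <- do.call(rbind, lapply(seg$compartments, function(cc)
    do.call(rbind, lapply(cc$sub_meshes, function(s) s$vertices))))
  lo <- apply(allv, 2, min); hi <- apply(allv, 2, max)
  ncell <- pmax(1L, as.integer(ceiling((hi - lo) / resolution - 1e-9)))
  nx <- ncell[1]; ny <- ncell[2]; nz <- ncell[3]
  gx <- lo[1] + resolution * (0:nx)
  gy <- lo[2] + resolution * (0:ny)
  gz <- lo[3] + resolution * (0:nz)
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  nodes <- cbind(rep(gx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gy, each = nx + 1), times = nz + 1),
                 rep(gz, each = (nx + 1) * (ny + 1)))
  # cube corner offsets for the 6 Kuhn tetrahedra: paths 0 -> e_p1 ->
  # e_p1+e_p2 -> (1,1,1) over the 6 axis permutations
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  corner <- function(off, ci, cj, ck) nid(ci + off[1], cj + off[2], ck + off[3])
  ci <- rep(0:(nx - 1), times = ny * nz)
  cj <- rep(rep(0:(ny - 1), each = nx), times = nz)
  ck <- rep(0:(nz - 1), each = nx * ny)
  tets <- vector("list", 6L)
  for (p in seq_len(6L)) {
    o1 <- c(0, 0, 0); o2 <- o1; o2[perms[p, 1]] <- 1
    o3 <- o2; o3[perms[p, 2]] <- 1; o4 <- c(1, 1, 1)
    tets[[p]] <- cbind(corner(o1, ci, cj, ck), corner(o2, ci, cj, ck),
                       corner(o3, ci, cj, ck), corner(o4, ci, cj, ck))
  }
  tetra <- do.call(rbind, tets)
  pre <- list(nodes = nodes, tetra = tetra)
  v <- tet_volumes(pre)
  neg <- v < 0
  if (any(neg)) tetra[neg, c(3, 4)] <- tetra[neg, c(4, 3)]
  pre$tetra <- tetra
  lab <- label_elements(pre, seg)
  keep <- lab > 0L
  tetra <- tetra[keep, , drop = FALSE]; lab <- lab[keep]
  for (ci2 in seq_along(seg$compartments)) {
    cc <- seg$compartments[[ci2]]
    if (isTRUE(cc$active) && !any(lab == ci2))
      stop("resolution too coarse: active compartment '", cc$name,
           "' received no elements")
  }
  used <- sort(unique(as.vector(tetra)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  tetra <- matrix(remap[tetra], ncol = 4L)
  comps <- data.frame(
    name = vapply(seg$compartments, `[[`, "", "name"),
    conductivity = vapply(seg$compartments, `[[`, 0, "conductivity"),
    priority = vapply(seg$compartments, function(c) as.integer(c$priority), 0L),
    active = vapply(seg$compartments, function(c) isTRUE(c$active), TRUE),
    stringsAsFactors = FALSE)
  tet_mesh(nodes[used, , drop = FALSE], tetra, lab,
           conductivity = comps$conductivity[lab], compartments = comps)
}

# node adjacency (pattern) from tetra edges
node_adjacency <- function(mesh) {
  tt <- mesh$tetra; n <- nrow(mesh$nodes)
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                       j = c(pairs[, 2], pairs[, 1]),
                       x = 1, dims = c(n, n), use.last.ij = TRUE) > 0
}

# faces of all elements with sorted node triples; returns list(face=matrix,
# elem=element index, count per face key)
mesh_faces <- function(mesh) {
  tt <- mesh$tetra
  f <- rbind(tt[, c(2, 3, 4)], tt[, c(1, 3, 4)],
             tt[, c(1, 2, 4)], tt[, c(1, 2, 3)])
  elem <- rep(seq_len(nrow(tt)), times = 4L)
  opp <- as.vector(tt)  # opposite node of each face, column-stacked
  fs <- t(apply(f, 1L, sort))
  n1 <- as.numeric(nrow(mesh$nodes)) + 1
  key <- (fs[, 1] * n1 + fs[, 2]) * n1 + fs[, 3]
  list(face = f, sorted = fs, elem = elem, opposite = opp, key = key)
}

#' Boundary faces of a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @return list with `face` (k x 3 node indices, outward oriented), `elem`
#'   (owning element) and `normal` (k x 3 outward unit normals), `area`,
#'   `centroid`.
#' @export
boundary_faces <- function(mesh) {
  ff <- mesh_faces(mesh)
  tab <- table(ff$key)
  bkey <- names(tab)[tab == 1L]
  sel <- which(as.character(ff$key) %in% bkey)
  face <- ff$face[sel, , drop = FALSE]
  elem <- ff$elem[sel]
  opp <- ff$opposite[sel]
  nd <- mesh$nodes
  a <- nd[face[, 1], , drop = FALSE]
  b <- nd[face[, 2], , drop = FALSE]
  cc <- nd[face[, 3], , drop = FALSE]
  nrm <- cross3(b - a, cc - a)
  area <- rownorms(nrm) / 2
  nrm <- nrm / (2 * area)
  centroid <- (a + b + cc) / 3
  flip <- rowSums(nrm * (centroid - nd[opp, , drop = FALSE])) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  list(face = face, elem = elem, normal = nrm, area = area,
       centroid = centroid)
}

#' Check mesh conformity
#'
#' A conforming mesh has every face shared by at most two elements, shared
#' faces having identical node triples (guaranteed by sorted-key counting).
#'
#' @param mesh a [tet_mesh()].
#' @return `TRUE` if conforming.
#' @export
is_conforming <- function(mesh) {
  ff <- mesh_faces(mesh)
  all(table(ff$key) <= 2L)
}

#' Smooth a labeled tetrahedral mesh
#'
#' Compartment-interface and outer-boundary nodes are evolved under the
#' Bi-Laplacian flow `x <- x - step * L(L(x))` with `L` the uniform graph
#' Laplacian restricted to nodes on the same interface; interior nodes
#' follow with ordinary Laplacian relaxation. After every iteration all
#' element volumes are checked; on inversion the iteration is rolled back
#' and the step halved (bounded retries).
#'
#' @param mesh a [tet_mesh()].
#' @param iterations number of smoothing sweeps.
#' @param step relaxation factor in (0, 1).
#' @param max_halvings how often the step may be halved before aborting.
#' @return The smoothed [tet_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations, step = 0.25, max_halvings = 10L) {
  stopifnot(step > 0, step < 1)
  if (iterations == 0L) return(mesh)
  adj <- node_adjacency(mesh)
  n <- nrow(mesh$nodes)
  # interface membership: nodes on faces shared by elements of different
  # labels, grouped per label pair; outer boundary its own interface
  ff <- mesh_faces(mesh)
  ordk <- order(ff$key)
  key_s <- ff$key[ordk]; elem_s <- ff$elem[ordk]
  dup <- which(diff(key_s) == 0)
  iface_groups <- list()
  if (length(dup)) {
    e1 <- elem_s[dup]; e2 <- elem_s[dup + 1L]
    l1 <- mesh$labels[e1]; l2 <- mesh$labels[e2]
    mixed <- which(l1 != l2)
    if (length(mixed)) {
      gkey <- paste(pmin(l1[mixed], l2[mixed]), pmax(l1[mixed], l2[mixed]))
      fsel <- ordk[dup[mixed]]
      for (g in unique(gkey)) {
        rows <- fsel[gkey == g]
        iface_groups[[g]] <- unique(as.vector(ff$face[rows, , drop = FALSE]))
      }
    }
  }
  bf <- boundary_faces(mesh)
  iface_groups[["boundary"]] <- unique(as.vector(bf$face))
  iface_all <- unique(unlist(iface_groups))
  interior <- setdiff(seq_len(n), iface_all)
  deg <- Matrix::rowSums(adj)
  lap <- function(x, A, d) {
    av <- as.matrix(A %*% x) / pmax(d, 1)
    out <- x - av
    out[d == 0, ] <- 0
    out
  }
  x <- mesh$nodes
  s <- step
  it <- 0L; halvings <- 0L
  while (it < iterations) {
    xn <- x
    for (g in iface_groups) {
      A <- adj[g, g, drop = FALSE]
      d <- Matrix::rowSums(A)
      l1 <- lap(x[g, , drop = FALSE], A, d)
      xn[g, ] <- x[g, , drop = FALSE] - s * lap(l1, A, d)
    }
    if (length(interior)) {
      A <- adj[interior, , drop = FALSE]
      av <- as.matrix(A %*% xn) / pmax(Matrix::rowSums(A), 1)
      xn[interior, ] <- (1 - s) * x[interior, , drop = FALSE] + s * av
    }
    vols <- tet_volumes(list(nodes = xn, tetra = mesh$tetra))
    if (any(vols <= 0)) {
      halvings <- halvings + 1L
      if (halvings > max_halvings)
        stop("smoothing aborted: element inversion persists after ",
             max_halvings, " step halvings at iteration ", it + 1L)
      s <- s / 2
      next
    }
    x <- xn
    it <- it + 1L
  }
  out <- mesh
  out$nodes <- x
  out
}

# unit icosphere: subdivided icosahedron, 10*4^n + 2 vertices
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / rownorms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      p <- v[i, ] + v[j, ]
      p <- p / vnorm(p)
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(cc, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Layered concentric-sphere phantom segmentation
#'
#' Builds nested icosphere compartments, outermost first, with priorities
#' decreasing inward (so inner compartments win priority ties). The
#' innermost compartment is marked active by default.
#'
#' @param radii strictly decreasing radii in meters, outermost first.
#' @param conductivities compartment conductivities in S/m (same length).
#' @param subdivisions icosphere subdivision level (vertex count per surface
#'   is `10 * 4^subdivisions + 2`).
#' @param names optional compartment names.
#' @param active logical vector; default activates only the innermost.
#' @return A [segmentation()].
#' @export
make_layered_sphere_segmentation <- function(radii, conductivities,
                                             subdivisions = 3L,
                                             names = NULL, active = NULL) {
  nl <- length(radii)
  if (nl != length(conductivities))
    stop("radii and conductivities lengths differ")
  if (nl > 1 && any(diff(radii) >= 0))
    stop("radii must be strictly decreasing (outermost first)")
  ico <- icosphere(subdivisions)
  if (is.null(names)) names <- sprintf("layer_%d", seq_len(nl))
  if (is.null(active)) active <- c(rep(FALSE, nl - 1L), TRUE)
  comps <- vector("list", nl)
  for (i in seq_len(nl)) {
    comps[[i]] <- list(
      name = names[i],
      sub_meshes = list(surface_mesh(ico$vertices * radii[i], ico$triangles,
                                     name = names[i])),
      conductivity = conductivities[i],
      priority = nl - i + 1L,   # value decreases inward
      active = isTRUE(active[i]))
  }
  segmentation(comps)
}

#' Export a tetrahedral mesh as legacy-VTK ASCII text
#'
#' Writes the node and element blocks of an unstructured grid together with
#' per-element compartment labels, for inspection in external viewers.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  nd <- mesh$nodes
  writeLines(sprintf("%.17g %.17g %.17g", nd[, 1], nd[, 2], nd[, 3]), con)
  m <- nrow(mesh$tetra)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  t0 <- mesh$tetra - 1L
  writeLines(sprintf("4 %d %d %d %d", t0[, 1], t0[, 2], t0[, 3], t0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", mesh$labels), con)
  invisible(path)
}
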