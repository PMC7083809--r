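#' Randomly placed source space
#'
#' Samples `n` source positions uniformly with respect to volume over the
#' elements of the active compartments: an element is chosen proportionally
#' to its volume, then a point is drawn uniformly in barycentric
#' coordinates. Deterministic for a given seed.
#'
#' @param mesh a [tet_mesh()].
#' @param n number of sources.
#' @param rng_seed integer seed.
#' @param active_labels compartment indices carrying sources; defaults to
#'   the compartments flagged active in the mesh.
#' @return An object of class `source_space`: `positions` (n x 3, m),
#'   `orientations` (`NULL` for the Cartesian xyz column pattern),
#'   `element_of` (containing element per source).
#' @export
place_sources <- function(mesh, n, rng_seed = 1L, active_labels = NULL) {
  if (is.null(active_labels))
    active_labels <- which(mesh$compartments$active)
  el <- which(mesh$labels %in% active_labels)
  if (!length(el)) stop("no elements in the active compartments")
  if (n == 0L)
    return(structure(list(positions = matrix(numeric(0), 0, 3),
                          orientations = NULL, element_of = integer(0)),
                     class = "source_space"))
  vols <- tet_volumes(mesh)[el]
  old <- .Random.seed_guard(rng_seed)
  on.exit(old())
  pick <- el[sample.int(length(el), n, replace = TRUE, prob = vols)]
  # uniform barycentric coordinates: spacings of 3 sorted uniforms
  u <- matrix(runif(3L * n), n, 3L)
  u <- t(apply(u, 1L, sort))
  w <- cbind(u[, 1], u[, 2] - u[, 1], u[, 3] - u[, 2], 1 - u[, 3])
  nd <- mesh$nodes; tt <- mesh$tetra[pick, , drop = FALSE]
  pos <- w[, 1] * nd[tt[, 1], , drop = FALSE] +
    w[, 2] * nd[tt[, 2], , drop = FALSE] +
    w[, 3] * nd[tt[, 3], , drop = FALSE] +
    w[, 4] * nd[tt[, 4], , drop = FALSE]
  structure(list(positions = pos, orientations = NULL, element_of = pick),
            class = "source_space")
}

# run code under a local RNG seed, restoring global state afterwards
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# neighbor element across the face opposite local node i (m x 4, NA at
# boundary)
face_neighbors <- function(mesh) {
  ff <- mesh_faces(mesh)
  m <- nrow(mesh$tetra)
  nbr <- matrix(NA_integer_, m, 4L)
  ordk <- order(ff$key)
  key_s <- ff$key[ordk]
  dup <- which(diff(key_s) == 0)
  if (length(dup)) {
    r1 <- ordk[dup]; r2 <- ordk[dup + 1L]
    # face row r corresponds to element ff$elem[r], local face (r-1)%/%m + 1
    loc1 <- (r1 - 1L) %/% m + 1L; loc2 <- (r2 - 1L) %/% m + 1L
    # local face f of element is opposite local node f (mesh_faces order)
    e1 <- ff$elem[r1]; e2 <- ff$elem[r2]
    nbr[cbind(e1, loc1)] <- e2
    nbr[cbind(e2, loc2)] <- e1
  }
  nbr
}

# moment of the RT0-type face function restricted to one tetrahedron:
# w = (x - p_opp) / (3V) integrates to (face centroid - p_opp) / 4
face_fun_tet <- function(nodes, tet_nodes, local_face) {
  opp <- tet_nodes[local_face]
  fnodes <- tet_nodes[-local_face]
  fbar <- colMeans(nodes[fnodes, , drop = FALSE])
  (fbar - nodes[opp, ]) / 4
}

#' Build an H(div) dipole stencil for one element
#'
#' `whitney4`: the 4 divergence-conforming face functions supported on the
#' element and its face neighbors (restricted to the single element and
#' flagged when a neighbor is missing). `hdiv10`: those 4 plus the 6
#' edge-associated functions supported on the element. Every basis function
#' `w_k` is returned with its nodal load vector `f_k[i] = int w_k . grad
#' phi_i dV` (exact: the integrands are piecewise linear), its dipole moment
#' `m_k = int w_k dV` and a mean position `p_k`.
#'
#' @param mesh a [tet_mesh()].
#' @param element element index.
#' @param kind `"whitney4"` or `"hdiv10"`.
#' @param neighbors optional precomputed [face_neighbors()] matrix.
#' @param active_labels if given (adaptive stencil), face functions whose
#'   neighbor element lies outside these compartments are dropped for
#'   `hdiv10` and restricted for `whitney4`.
#' @return An object of class `stencil_basis` with fields `loads` (list of
#'   `list(nodes, values)`), `moments` (K x 3), `positions` (K x 3), `h`
#'   (local element size), `flagged`.
#' @export
build_stencil <- function(mesh, element, kind = c("whitney4", "hdiv10"),
                          neighbors = NULL, active_labels = NULL) {
  kind <- match.arg(kind)
  if (is.null(neighbors)) neighbors <- face_neighbors(mesh)
  nd <- mesh$nodes
  eg_cache <- new.env()
  grads_of <- function(e) {
    key <- as.character(e)
    g <- eg_cache[[key]]
    if (is.null(g)) {
      sub <- list(nodes = nd, tetra = mesh$tetra[e, , drop = FALSE])
      g <- element_gradients(sub)
      eg_cache[[key]] <- g
    }
    g
  }
  tn <- mesh$tetra[element, ]
  vols_all <- tet_volumes(mesh)
  centroid <- function(e) colMeans(nd[mesh$tetra[e, ], , drop = FALSE])
  edges_local <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  h <- max(rownorms(nd[tn[edges_local[, 1]], , drop = FALSE] -
                      nd[tn[edges_local[, 2]], , drop = FALSE]))
  loads <- list(); moments <- NULL; positions <- NULL; flagged <- logical(0)
  add_basis <- function(tet_list, m_list, pos, flag) {
    # accumulate f[node] = m_T . grad(phi_node) over support tets
    idx <- integer(0); val <- numeric(0)
    mom <- c(0, 0, 0)
    for (t in seq_along(tet_list)) {
      e <- tet_list[[t]]; mT <- m_list[[t]]
      g <- grads_of(e)
      for (i in 1:4) {
        idx <- c(idx, mesh$tetra[e, i])
        val <- c(val, sum(mT * g$grads[[i]][1, ]))
      }
      mom <- mom + mT
    }
    agg <- tapply(val, idx, sum)
    loads[[length(loads) + 1L]] <<- list(nodes = as.integer(names(agg)),
                                         values = as.numeric(agg))
    moments <<- rbind(moments, mom)
    positions <<- rbind(positions, pos)
    flagged <<- c(flagged, flag)
  }
  active_ok <- function(e) {
    is.null(active_labels) || mesh$labels[e] %in% active_labels
  }
  # 4 face functions
  for (lf in 1:4) {
    nb <- neighbors[element, lf]
    m1 <- face_fun_tet(nd, tn, lf)
    if (is.na(nb) || (kind == "whitney4" && !active_ok(nb))) {
      add_basis(list(element), list(m1), centroid(element), TRUE)
    } else if (!active_ok(nb)) {
      next  # adaptive hdiv10: drop members whose support leaves the region
    } else {
      tn2 <- mesh$tetra[nb, ]
      shared <- tn[-lf]
      lf2 <- which(!(tn2 %in% shared))
      m2 <- -face_fun_tet(nd, tn2, lf2)
      v1 <- vols_all[element]; v2 <- vols_all[nb]
      pos <- (v1 * centroid(element) + v2 * centroid(nb)) / (v1 + v2)
      add_basis(list(element, nb), list(m1, m2), pos, FALSE)
    }
  }
  if (kind == "hdiv10") {
    g <- grads_of(element)
    V <- vols_all[element]
    for (k in 1:6) {
      a <- edges_local[k, 1]; b <- edges_local[k, 2]
      # w = lambda_a grad(lambda_b) - lambda_b grad(lambda_a)
      mom <- V / 4 * (g$grads[[b]][1, ] - g$grads[[a]][1, ])
      pos <- (nd[tn[a], ] + nd[tn[b], ]) / 2
      add_basis_edge <- function() {
        idx <- mesh$tetra[element, ]
        val <- vapply(1:4, function(i) sum(mom * g$grads[[i]][1, ]), 0)
        loads[[length(loads) + 1L]] <<- list(nodes = as.integer(idx),
                                             values = val)
        moments <<- rbind(moments, mom)
        positions <<- rbind(positions, pos)
        flagged <<- c(flagged, FALSE)
      }
      add_basis_edge()
    }
  }
  structure(list(element = element, kind = kind, loads = loads,
                 moments = moments, positions = positions, h = h,
                 flagged = flagged),
            class = "stencil_basis")
}

#' Position-based-optimization stencil coefficients
#'
#' Solves `min sum_k d_k^2 c_k^2` subject to `sum_k c_k m_k = moment`, with
#' distance weights `d_k = ||p_k - position|| + eps * h`. The exact-moment
#' constraint makes the combined stencil a dipole with the requested moment;
#' the distance weighting concentrates the coefficients on basis functions
#' near the requested position.
#'
#' @param stencil a `stencil_basis` from [build_stencil()].
#' @param position requested dipole position (3-vector, m).
#' @param moment requested dipole moment (3-vector, A m).
#' @param eps relative regularization of the distance weights.
#' @return coefficient vector `c` (length K) satisfying the moment
#'   constraint to 1e-12 relative.
#' @export
pbo_coefficients <- function(stencil, position, moment, eps = 1e-3) {
  M <- t(stencil$moments)            # 3 x K
  d <- rownorms(stencil$positions -
                  matrix(position, nrow(stencil$positions), 3,
                         byrow = TRUE)) + eps * stencil$h
  Winv <- 1 / d^2
  G <- M %*% (Winv * t(M))           # 3 x 3
  sv <- svd(G)
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    span <- sv$u[, sv$d >= 1e-12 * max(sv$d), drop = FALSE]
    stop("rank-deficient moment constraint; achievable moment subspace ",
         "spanned by columns: ",
         paste(apply(round(span, 6), 2, paste, collapse = ","),
               collapse = " | "))
  }
  lambda <- solve(G, moment)
  cc <- Winv * as.numeric(t(M) %*% lambda)
  resid <- vnorm(as.numeric(M %*% cc) - moment)
  if (resid > 1e-10 * max(vnorm(moment), 1e-300))
    stop("PBO moment constraint not satisfiable (residual ", resid, ")")
  cc
}

#' Dipole load matrix for a source space
#'
#' Builds the nodal load vectors of the requested source model. With
#' `constraint = "cartesian"` each source contributes 3 columns (unit x, y,
#' z moments, combined from the stencil by [pbo_coefficients()]), matching
#' the `position 1, xyz; position 2, xyz` column pattern. With `constraint =
#' "normal"` each source contributes a single column with a unit moment
#' along the outward surface normal. `kind = "raw_whitney"` bypasses
#' interpolation and returns one column per mesh-based face function of the
#' active compartments.
#'
#' @param space a `source_space` from [place_sources()].
#' @param mesh a [tet_mesh()].
#' @param kind `"whitney4"`, `"hdiv10"` or `"raw_whitney"`.
#' @param constraint `"cartesian"` or `"normal"`.
#' @param normals optional n x 3 matrix of unit source normals; when absent
#'   and `constraint = "normal"`, normals are taken from the nearest
#'   triangle of `surface` (outward).
#' @param surface a [surface_mesh()] of the active compartment boundary,
#'   used to derive normals.
#' @param active_labels compartments defining the adaptive stencil support
#'   (defaults to the mesh's active compartments).
#' @return An object of class `source_loads`: sparse load matrix `F`
#'   (nodes x columns, every column zero-sum), `positions`, `orientations`
#'   (per column), `layout`.
#' @export
source_load_vectors <- function(space, mesh,
                                kind = c("whitney4", "hdiv10", "raw_whitney"),
                                constraint = c("cartesian", "normal"),
                                normals = NULL, surface = NULL,
                                active_labels = NULL) {
  kind <- match.arg(kind)
  constraint <- match.arg(constraint)
  n_nodes <- nrow(mesh$nodes)
  if (is.null(active_labels))
    active_labels <- which(mesh$compartments$active)
  if (kind == "raw_whitney") {
    nbr <- face_neighbors(mesh)
    act <- which(mesh$labels %in% active_labels)
    ii <- jj <- integer(0); xx <- numeric(0)
    pos <- NULL; ori <- NULL
    col <- 0L
    seen <- new.env(hash = TRUE)
    for (e in act) for (lf in 1:4) {
      nb <- nbr[e, lf]
      if (is.na(nb) || !(mesh$labels[nb] %in% active_labels)) next
      key <- paste(min(e, nb), max(e, nb))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      st_m1 <- face_fun_tet(mesh$nodes, mesh$tetra[e, ], lf)
      tn2 <- mesh$tetra[nb, ]
      lf2 <- which(!(tn2 %in% mesh$tetra[e, -lf]))
      st_m2 <- -face_fun_tet(mesh$nodes, tn2, lf2)
      col <- col + 1L
      for (pair in list(list(e, st_m1), list(nb, st_m2))) {
        el <- pair[[1]]; mT <- pair[[2]]
        sub <- list(nodes = mesh$nodes,
                    tetra = mesh$tetra[el, , drop = FALSE])
        g <- element_gradients(sub)
        for (i in 1:4) {
          ii <- c(ii, mesh$tetra[el, i]); jj <- c(jj, col)
          xx <- c(xx, sum(mT * g$grads[[i]][1, ]))
        }
      }
      fbar <- colMeans(mesh$nodes[mesh$tetra[e, -lf], , drop = FALSE])
      mom <- st_m1 + st_m2
      pos <- rbind(pos, fbar)
      ori <- rbind(ori, mom / max(vnorm(mom), 1e-300))
    }
    F <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_nodes, col))
    return(structure(list(F = F, positions = pos, orientations = ori,
                          layout = "raw_whitney"),
                     class = "source_loads"))
  }
  n <- nrow(space$positions)
  if (constraint == "normal" && is.null(normals)) {
    if (is.null(surface))
      stop("normal constraint requested but no normals or surface given")
    normals <- surface_normals_at(surface, space$positions)
  }
  nbr <- face_neighbors(mesh)
  percol <- if (constraint == "cartesian") 3L else 1L
  ii <- jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(n)) {
    st <- build_stencil(mesh, space$element_of[s], kind, neighbors = nbr,
                        active_labels = active_labels)
    moms <- if (constraint == "cartesian") diag(3)
            else matrix(normals[s, ], 1L)
    for (d in seq_len(percol)) {
      cc <- pbo_coefficients(st, space$positions[s, ], moms[d, ])
      col <- (s - 1L) * percol + d
      for (k in seq_along(cc)) {
        if (cc[k] == 0) next
        ii <- c(ii, st$loads[[k]]$nodes)
        jj <- c(jj, rep(col, length(st$loads[[k]]$nodes)))
        xx <- c(xx, cc[k] * st$loads[[k]]$values)
      }
    }
  }
  F <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_nodes, n * percol))
  ori <- if (constraint == "normal") normals else NULL
  structure(list(F = F,
                 positions = space$positions[rep(seq_len(n), each = percol),
                                             , drop = FALSE],
                 orientations = ori,
                 layout = if (constraint == "cartesian") "cartesian3"
                          else "normal1"),
            class = "source_loads")
}

# outward unit normal of the surface triangle nearest to each point
surface_normals_at <- function(surface, points) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  ctr <- (a + b + cc) / 3
  nrm <- cross3(b - a, cc - a)
  nrm <- nrm / rownorms(nrm)
  # orient outward from the surface's own centroid
  sc <- colMeans(v)
  flip <- rowSums(nrm * (ctr - matrix(sc, nrow(ctr), 3, byrow = TRUE))) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  out <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums((ctr - matrix(points[i, ], nrow(ctr), 3, byrow = TRUE))^2)
    out[i, ] <- nrm[which.min(d2), ]
  }
  out
}

#' Barycentric interpolation indices for a source space
#'
#' For each degree of freedom, the 4 node indices of its containing element
#' and the barycentric weights reproducing the source position; these
#' connect the inverse-problem DOFs to the FE mesh.
#'
#' @param space a `source_space`.
#' @param mesh a [tet_mesh()].
#' @return list with `nodes` (n x 4) and `weights` (n x 4, rows sum to 1,
#'   entries >= 0 up to round-off).
#' @export
interpolation_indices <- function(space, mesh) {
  n <- nrow(space$positions)
  nodes <- matrix(0L, n, 4L); weights <- matrix(0, n, 4L)
  for (s in seq_len(n)) {
    e <- space$element_of[s]
    tn <- mesh$tetra[e, ]
    p <- mesh$nodes[tn, , drop = FALSE]
    Tm <- cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
    lam <- solve(Tm, space$positions[s, ] - p[1, ])
    weights[s, ] <- c(1 - sum(lam), lam)
    nodes[s, ] <- tn
  }
  list(nodes = nodes, weights = weights)
}

#' Locate the elements containing given points
#'
#' @param mesh a [tet_mesh()].
#' @param points n x 3 matrix (m).
#' @return integer vector of element indices (`NA` when a point lies in no
#'   element).
#' @export
find_containing_element <- function(mesh, points) {
  points <- as_points3(points)
  bc <- tet_barycenters(mesh)
  out <- rep(NA_integer_, nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums((bc - matrix(points[i, ], nrow(bc), 3, byrow = TRUE))^2)
    cand <- order(d2)[seq_len(min(60L, nrow(bc)))]
    for (e in cand) {
      tn <- mesh$tetra[e, ]
      p <- mesh$nodes[tn, , drop = FALSE]
      Tm <- cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
      lam <- tryCatch(solve(Tm, points[i, ] - p[1, ]),
                      error = function(e) NULL)
      if (is.null(lam)) next
      w <- c(1 - sum(lam), lam)
      if (all(w >= -1e-10)) { out[i] <- e; break }
    }
  }
  out
}

#' Manually constructed source space
#'
#' @param mesh a [tet_mesh()].
#' @param positions n x 3 matrix of source positions (m); each must lie
#'   inside some element.
#' @param orientations optional n x 3 unit orientations.
#' @return A `source_space`.
#' @export
source_space_at <- function(mesh, positions, orientations = NULL) {
  positions <- as_points3(positions)
  el <- find_containing_element(mesh, positions)
  if (anyNA(el))
    stop("position(s) outside the mesh: ",
         paste(head(which(is.na(el)), 5L), collapse = ", "))
  structure(list(positions = positions, orientations = orientations,
                 element_of = el),
            class = "source_space")
}
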