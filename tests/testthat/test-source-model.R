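test_that("source placement is uniform over volume and respects the active
           region", {
  m <- sphere_mesh_coarse()
  expect_equal(nrow(place_sources(m, 0L)$positions), 0L)

  sp <- place_sources(m, 200L, rng_seed = 2)
  expect_equal(nrow(sp$positions), 200L)
  # every position lies inside its containing element
  ii <- interpolation_indices(sp, m)
  expect_true(all(ii$weights >= -1e-10))
  expect_equal(rowSums(ii$weights), rep(1, 200), tolerance = 1e-12)

  # chi-square test of per-element counts against volume fractions
  sp2 <- place_sources(m, 10000L, rng_seed = 3)
  vols <- tet_volumes(m)
  counts <- tabulate(sp2$element_of, nbins = nrow(m$tetra))
  # aggregate elements into 20 volume bins to keep expected counts large
  grp <- cut(seq_along(vols), 20L, labels = FALSE)
  obs <- tapply(counts, grp, sum)
  expv <- tapply(vols, grp, sum) / sum(vols) * 10000
  chi2 <- sum((obs - expv)^2 / expv)
  expect_lt(chi2, qchisq(1 - 1e-4, df = 19))

  # determinism
  expect_identical(place_sources(m, 50L, rng_seed = 9)$positions,
                   place_sources(m, 50L, rng_seed = 9)$positions)
})

test_that("stencil bases have the documented sizes, zero-sum loads and
           quadrature-exact load vectors", {
  m <- sphere_mesh_coarse()
  e <- find_containing_element(m, rbind(c(0.01, 0.005, -0.01)))
  st4 <- build_stencil(m, e, "whitney4")
  st10 <- build_stencil(m, e, "hdiv10")
  expect_length(st4$loads, 4L)
  expect_length(st10$loads, 10L)
  for (st in list(st4, st10))
    for (ld in st$loads)
      expect_lt(abs(sum(ld$values)), 1e-14 * max(abs(ld$values)))
  expect_true(all(neurofem:::rownorms(st10$moments) > 0))

  # independent quadrature oracle: f_k[i] = int w_k . grad(phi_i) dV with a
  # degree-2 rule; w is linear so the rule is exact
  nd <- m$nodes
  eg_of <- function(el) {
    sub <- list(nodes = nd, tetra = m$tetra[el, , drop = FALSE])
    neurofem:::element_gradients(sub)
  }
  vols <- tet_volumes(m)
  # face function 1 of st4: support = element e and its neighbor
  nbr <- neurofem:::face_neighbors(m)[e, 1]
  w_face <- function(x, el, lf) {
    tn <- m$tetra[el, ]
    opp <- nd[tn[lf], ]
    sgn <- if (el == e) 1 else -1
    sgn * (x - opp) / (3 * vols[el])
  }
  # local face index of the shared face in the neighbor
  tn2 <- m$tetra[nbr, ]
  lf2 <- which(!(tn2 %in% m$tetra[e, -1]))
  f_num <- numeric(nrow(nd))
  for (el_lf in list(list(e, 1L), list(nbr, lf2))) {
    el <- el_lf[[1]]; lf <- el_lf[[2]]
    tn <- m$tetra[el, ]
    qp <- tet_quad_points(nd[tn[1], ], nd[tn[2], ], nd[tn[3], ], nd[tn[4], ])
    g <- eg_of(el)
    for (i in 1:4) {
      gi <- g$grads[[i]][1, ]
      val <- 0
      for (q in 1:4)
        val <- val + qp$weights[q] * sum(w_face(qp$points[q, ], el, lf) * gi)
      f_num[tn[i]] <- f_num[tn[i]] + val * vols[el]
    }
  }
  f_cf <- numeric(nrow(nd))
  f_cf[st4$loads[[1]]$nodes] <- st4$loads[[1]]$values
  expect_lt(max(abs(f_num - f_cf)), 1e-10 * max(abs(f_cf)))
})

test_that("PBO satisfies the moment constraint, concentrates on co-located
           bases and is linear", {
  m <- sphere_mesh_coarse()
  e <- find_containing_element(m, rbind(c(-0.012, 0.02, 0.008)))
  st <- build_stencil(m, e, "hdiv10")
  set.seed(4)
  for (i in 1:20) {
    mom <- rnorm(3)
    cc <- pbo_coefficients(st, c(-0.012, 0.02, 0.008), mom)
    expect_lt(neurofem:::vnorm(as.numeric(t(st$moments) %*% cc) - mom),
              1e-12 * neurofem:::vnorm(mom))
  }
  # request the moment of basis k at its own mean position
  k <- 2L
  mk <- st$moments[k, ]
  ck <- pbo_coefficients(st, st$positions[k, ], mk)
  expect_gte(abs(ck[k]) * neurofem:::vnorm(mk), 0.9 * neurofem:::vnorm(mk))
  # linearity
  c1 <- pbo_coefficients(st, c(-0.012, 0.02, 0.008), c(1, 0.5, -2))
  c2 <- pbo_coefficients(st, c(-0.012, 0.02, 0.008), 2 * c(1, 0.5, -2))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("load matrices are zero-sum with independent cartesian columns and
           consistent normal contraction", {
  m <- sphere_mesh_coarse()
  sp <- place_sources(m, 10L, rng_seed = 5)
  ld <- source_load_vectors(sp, m, kind = "hdiv10", constraint = "cartesian")
  expect_equal(ncol(ld$F), 30L)
  cs <- Matrix::colSums(ld$F)
  expect_lt(max(abs(cs)), 1e-12 * max(abs(ld$F)))
  F1 <- as.matrix(ld$F[, 1:3])
  expect_equal(qr(F1)$rank, 3L)

  # normal-constrained column equals the cartesian triple contracted with
  # the unit normal
  normals <- sp$positions / neurofem:::rownorms(sp$positions)
  ldn <- source_load_vectors(sp, m, kind = "hdiv10", constraint = "normal",
                             normals = normals)
  expect_equal(ncol(ldn$F), 10L)
  for (s in 1:10) {
    combo <- as.matrix(ld$F[, (s - 1) * 3 + 1:3]) %*% normals[s, ]
    expect_lt(max(abs(as.numeric(ldn$F[, s]) - combo)),
              1e-10 * max(abs(combo)))
  }

  # normals derived from the compartment surface when not supplied
  seg1 <- make_layered_sphere_segmentation(sphere_radius, sphere_sigma, 3)
  lds <- source_load_vectors(sp, m, kind = "whitney4", constraint = "normal",
                             surface = seg1$compartments[[1]]$sub_meshes[[1]])
  expect_equal(dim(lds$F), dim(ldn$F))
  expect_error(source_load_vectors(sp, m, constraint = "normal"),
               "no normals")
})

test_that("raw Whitney loads bypass interpolation with one zero-sum column
           per interior face", {
  seg <- one_compartment_segmentation(cube_surface(0.02))
  m <- generate_uniform_mesh(seg, 0.01)  # 6 tets, interior faces only
  ld <- source_load_vectors(list(), m, kind = "raw_whitney")
  expect_gt(ncol(ld$F), 0L)
  expect_lt(max(abs(Matrix::colSums(ld$F))), 1e-12)
  expect_equal(ld$layout, "raw_whitney")
  expect_equal(nrow(ld$positions), ncol(ld$F))
})

test_that("interpolation indices reconstruct source positions and vertex
           sources get unit weight", {
  m <- sphere_mesh_coarse()
  sp <- place_sources(m, 25L, rng_seed = 6)
  ii <- interpolation_indices(sp, m)
  rec <- matrix(0, 25, 3)
  for (s in 1:25)
    rec[s, ] <- colSums(m$nodes[ii$nodes[s, ], ] * ii$weights[s, ])
  expect_lt(max(abs(rec - sp$positions)), 1e-12)

  # a source placed exactly at an element vertex
  e <- 10L
  v1 <- m$nodes[m$tetra[e, 1], ]
  spv <- list(positions = rbind(v1), element_of = e)
  iv <- interpolation_indices(spv, m)
  expect_equal(max(iv$weights[1, ]), 1, tolerance = 1e-10)
})
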