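#' Additive white Gaussian noise model
#'
#' Exactly one of `percent` (relative std as percent of the maximum absolute
#' signal entry) or `snr_db` (signal-to-noise ratio in dB, std relative to
#' the signal RMS) must be given.
#'
#' @param percent relative standard deviation in percent of `max |y|`.
#' @param snr_db signal-to-noise ratio in decibels.
#' @param rng_seed integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(percent = NULL, snr_db = NULL, rng_seed = 1L) {
  if (is.null(percent) == is.null(snr_db))
    stop("specify exactly one of percent or snr_db")
  structure(list(percent = percent, snr_db = snr_db,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_model")
}

noise_sd_for <- function(noise, y_clean) {
  if (!is.null(noise$percent)) noise$percent / 100 * max(abs(y_clean))
  else sqrt(mean(y_clean^2)) * 10^(-noise$snr_db / 20)
}

#' Spherical conductivity anomaly
#'
#' @param center 3-vector (m).
#' @param diameter sphere diameter (m).
#' @param delta_sigma conductivity perturbation (S/m).
#' @return An object of class `anomaly`.
#' @export
conductivity_anomaly <- function(center, diameter, delta_sigma) {
  if (diameter <= 0) stop("diameter must be > 0")
  structure(list(center = as.numeric(center), diameter = diameter,
                 delta_sigma = delta_sigma),
            class = "anomaly")
}

#' Evenly spread points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param radius sphere radius (m).
#' @param cap_fraction keep only points with `z > (1 - 2 * cap_fraction) *
#'   radius` when < 1 (an electrode "cap"); default covers the full sphere.
#' @return n x 3 matrix.
#' @export
fibonacci_sphere_points <- function(n, radius = 1, cap_fraction = 1) {
  i <- seq_len(n) - 0.5
  z_lo <- 1 - 2 * cap_fraction
  z <- 1 - (1 - z_lo) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

#' Analytic dipole potential in a homogeneous conducting sphere
#'
#' Surface potential of a current dipole inside a homogeneous sphere with
#' insulating boundary, evaluated by the classical spherical-harmonic
#' series
#' `U = 1/(4 pi sigma R^2) * sum_n (2n+1)/n * f^(n-1) *
#'  [ n m_r P_n(cos g) + m_t P'_n-type term ]`
#' with `f` the dipole eccentricity; the series is truncated once the tail
#' is below machine tolerance. For a central dipole this reduces to the
#' closed form `3 (m . rhat) / (4 pi sigma R^2)`. Potentials are returned
#' zero-mean referenced.
#'
#' @param dipole_pos dipole position (m), strictly inside the sphere.
#' @param dipole_moment dipole moment (A m).
#' @param sphere_radius sphere radius (m).
#' @param conductivity conductivity (S/m).
#' @param electrode_points E x 3 matrix of points on the sphere surface.
#' @param n_terms maximum number of series terms.
#' @return zero-mean potential vector (V).
#' @export
analytic_sphere_potential <- function(dipole_pos, dipole_moment,
                                      sphere_radius, conductivity,
                                      electrode_points, n_terms = 400L) {
  R <- sphere_radius
  b <- vnorm(dipole_pos)
  if (b >= R) stop("dipole must lie strictly inside the sphere")
  electrode_points <- as_points3(electrode_points)
  xhat <- electrode_points / rownorms(electrode_points)
  if (b < 1e-12 * R) {
    u <- 3 * as.numeric(xhat %*% dipole_moment) / (4 * pi * conductivity *
                                                     R^2)
    return(u - mean(u))
  }
  zhat <- dipole_pos / b
  f <- b / R
  m_r <- sum(dipole_moment * zhat)
  mt_vec <- dipole_moment - m_r * zhat
  m_t <- vnorm(mt_vec)
  that <- if (m_t > 0) mt_vec / m_t else c(0, 0, 0)
  cosg <- as.numeric(xhat %*% zhat)
  cosg <- pmin(pmax(cosg, -1), 1)
  sing <- sqrt(pmax(1 - cosg^2, 0))
  perp <- xhat - cosg %o% zhat
  pn <- rownorms(perp)
  cosphi <- ifelse(pn > 1e-14, as.numeric(perp %*% that) / pn, 0)
  E <- nrow(xhat)
  u <- numeric(E)
  p_prev <- rep(1, E)       # P_0
  p_cur <- cosg             # P_1
  fpow <- 1                 # f^(n-1)
  for (n in seq_len(n_terms)) {
    # associated Legendre P_n^1 = sin(g) P_n'(cos g), positive convention
    pn1 <- ifelse(sing > 1e-14,
                  n * (p_prev - cosg * p_cur) / sing, 0)
    term <- (2 * n + 1) / n * fpow * (n * m_r * p_cur +
                                        m_t * pn1 * cosphi)
    u <- u + term
    if (fpow * (2 * n + 1) * (n + 1) * max(abs(m_r), m_t) <
        1e-14 * max(abs(u), 1e-300) && n > 10) break
    p_next <- ((2 * n + 1) * cosg * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur; p_cur <- p_next
    fpow <- fpow * f
  }
  u <- u / (4 * pi * conductivity * R^2)
  u - mean(u)
}

#' Relative difference measure and magnitude ratio
#'
#' `RDM = || u/||u|| - v/||v|| ||` and `MAG = ||u|| / ||v||`, the standard
#' forward-solution accuracy metrics (`v` is the reference).
#'
#' @param u,v vectors of equal length; neither may be all zero.
#' @return named list with `rdm` and `mag`.
#' @export
rdm_mag <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) stop("zero-norm input")
  list(rdm = vnorm(u / nu - v / nv), mag = nu / nv)
}

#' Simulate EEG measurements
#'
#' `y = L x_true + n` with additive white Gaussian noise per the noise
#' model; deterministic given the model's seed.
#'
#' @param L lead-field matrix (or [lead_field()]).
#' @param x_true true coefficient vector.
#' @param noise a [noise_model()], or `NULL` for noiseless data.
#' @return list with `y`, the realized `noise`, `y_clean` and `noise_sd`.
#' @export
simulate_eeg <- function(L, x_true, noise = NULL) {
  if (inherits(L, "lead_field")) L <- L$L
  y_clean <- as.numeric(L %*% x_true)
  if (is.null(noise))
    return(list(y = y_clean, noise = numeric(length(y_clean)),
                y_clean = y_clean, noise_sd = 0))
  sdn <- noise_sd_for(noise, y_clean)
  old <- .Random.seed_guard(noise$rng_seed)
  on.exit(old())
  n <- rnorm(length(y_clean), 0, sdn)
  list(y = y_clean + n, noise = n, y_clean = y_clean, noise_sd = sdn)
}

# elements whose barycenter lies inside the anomaly sphere
anomaly_elements <- function(mesh, anomaly, restrict_labels = NULL) {
  bc <- tet_barycenters(mesh)
  d <- rownorms(bc - matrix(anomaly$center, nrow(bc), 3, byrow = TRUE))
  sel <- d <= anomaly$diameter / 2
  if (!is.null(restrict_labels)) sel <- sel & mesh$labels %in% restrict_labels
  which(sel)
}

#' Simulate an EIT difference experiment
#'
#' Solves the nonlinear CEM forward problem with the background conductivity
#' and with the anomaly added, for every current pattern; the data are the
#' stacked zero-mean electrode-voltage differences plus additive white
#' Gaussian noise with `std = RMS(signal) * 10^(-snr_db/20)`.
#'
#' @param mesh background [tet_mesh()].
#' @param electrodes an [electrode_set()].
#' @param anomaly a [conductivity_anomaly()]; must hit at least one element
#'   of `restrict_labels`.
#' @param patterns current patterns ([measurement_patterns()] output or
#'   matrix).
#' @param snr_db signal-to-noise ratio (dB); `Inf` for noiseless data.
#' @param restrict_labels compartments the anomaly may occupy (default
#'   active).
#' @param rng_seed noise seed.
#' @param tol PCG tolerance.
#' @return list with `y_background`, `y_perturbed`, `data` (difference +
#'   noise), `noise_sd`, `anomaly_elements`.
#' @export
simulate_eit <- function(mesh, electrodes, anomaly, patterns, snr_db = 60,
                         restrict_labels = NULL, rng_seed = 1L, tol = 1e-8) {
  if (is.list(patterns) && !is.null(patterns$patterns))
    patterns <- patterns$patterns
  if (is.null(restrict_labels))
    restrict_labels <- which(mesh$compartments$active)
  ae <- anomaly_elements(mesh, anomaly, restrict_labels)
  if (anomaly$delta_sigma != 0 && !length(ae))
    stop("anomaly does not intersect the designated compartments")
  stack_voltages <- function(m) {
    sys <- assemble_cem(m, electrodes)
    tm <- transfer_matrix(sys, tol = tol)
    U <- tm$Te %*% patterns
    U <- sweep(U, 2L, colMeans(U))
    as.numeric(U)
  }
  y_bg <- stack_voltages(mesh)
  mesh2 <- mesh
  if (is.matrix(mesh2$conductivity)) {
    mesh2$conductivity[ae, 1:3] <- mesh2$conductivity[ae, 1:3] +
      anomaly$delta_sigma
  } else {
    mesh2$conductivity[ae] <- mesh2$conductivity[ae] + anomaly$delta_sigma
  }
  y_pe <- if (anomaly$delta_sigma == 0) y_bg else stack_voltages(mesh2)
  signal <- y_pe - y_bg
  sdn <- if (is.infinite(snr_db)) 0
         else sqrt(mean(signal^2)) * 10^(-snr_db / 20)
  old <- .Random.seed_guard(rng_seed)
  on.exit(old())
  n <- rnorm(length(signal), 0, sdn)
  list(y_background = y_bg, y_perturbed = y_pe, data = signal + n,
       noise_sd = sdn, anomaly_elements = ae)
}

#' Amplitude-weighted center of mass
#'
#' @param positions n x 3 matrix.
#' @param weights non-negative weights (e.g. per-DOF amplitudes).
#' @return 3-vector.
#' @export
center_of_mass <- function(positions, weights) {
  w <- pmax(weights, 0)
  if (sum(w) == 0) return(colMeans(as_points3(positions)))
  as.numeric(colSums(as_points3(positions) * w) / sum(w))
}

# per-location amplitudes and resultant orientation of an xyz-interleaved
# coefficient vector
dof_amplitudes <- function(x, k = 3L) {
  nloc <- length(x) / k
  xm <- matrix(x, k, nloc)
  list(amp = sqrt(colSums(xm^2)), vec = t(xm))
}

#' Hyperparameter-selection experiment on a layered-sphere phantom
#'
#' Simulates a simultaneously active pair of deep and superficial dipoles,
#' adds relative Gaussian noise, and reconstructs with ROI-restricted IAS
#' MAP for every (hypermodel, theta0) case and noise realization. The
#' reconstruction within each ROI is summarized by its amplitude-weighted
#' center of mass (position error, mm) and its amplitude-weighted resultant
#' orientation (angle error, degrees, orientation-sign agnostic).
#'
#' Dipole amplitudes are measured in nAm and lead-field columns in V/nAm:
#' with coefficients of order 1-10 the hyperprior scale grid spans the
#' transition between weak and strong shrinkage, which is where the gamma
#' and inverse-gamma hypermodels genuinely differ (in V/(A m) units both
#' collapse onto fixed minimum-norm priors).
#'
#' @param config named list overriding the defaults: `radii`,
#'   `conductivities`, `subdivisions`, `resolution`, `n_electrodes`,
#'   `n_dofs`, `deep_pos`, `superficial_pos`, `orientation`, `amplitude`
#'   (A m), `noise_percent`, `beta`, `cases` (data.frame `hypermodel`,
#'   `theta0`), `n_realizations`, `roi_diameter`, `n_ias_steps`, `seed`.
#' @param context optional precomputed list (`mesh`, `lf`, `space`) reused
#'   across calls; built from the config when absent.
#' @return list with `errors` (data.frame: case, hypermodel, theta0, source,
#'   realization, pos_error_mm, ori_error_deg), `context`, `config`.
#' @export
hyperparameter_experiment <- function(config = list(), context = NULL) {
  cfg <- utils::modifyList(list(
    radii = c(0.092, 0.085, 0.080),
    conductivities = c(0.43, 0.0064, 0.33),
    subdivisions = 3L,
    resolution = 0.008,
    n_electrodes = 32L,
    n_dofs = 1200L,
    deep_pos = c(0, 0, 0.025),
    superficial_pos = c(0, 0, 0.068),
    orientation = c(1, 0, 0),
    amplitude = 10,
    noise_percent = 2,
    beta = 1.5,
    cases = data.frame(hypermodel = c("G", "IG", "G", "IG"),
                       theta0 = c(1e-5, 1e-5, 1e-9, 1e-9),
                       stringsAsFactors = FALSE),
    n_realizations = 50L,
    roi_diameter = 0.030,
    n_ias_steps = 2L,
    seed = 1L,
    noise_seed_base = NULL), config)
  # modifyList merges data.frames column-wise; take a user grid verbatim
  if (!is.null(config$cases)) cfg$cases <- config$cases
  if (is.null(context)) {
    seg <- make_layered_sphere_segmentation(cfg$radii, cfg$conductivities,
                                            subdivisions = cfg$subdivisions,
                                            names = c("scalp", "skull",
                                                      "brain"))
    mesh <- generate_uniform_mesh(seg, cfg$resolution)
    electrodes <- electrode_set(
      fibonacci_sphere_points(cfg$n_electrodes, cfg$radii[1]),
      impedances = 1000, outer_diameter = 0.010)
    sys <- assemble_cem(mesh, electrodes)
    # re-draw the source cloud if a ROI would be empty (rare at the default
    # density, but the experiment must be robust to any seed)
    roi_r0 <- cfg$roi_diameter / 2
    space <- NULL
    for (try in 0:9) {
      cand <- place_sources(mesh, cfg$n_dofs, rng_seed = cfg$seed + 131L * try)
      ok <- all(vapply(list(cfg$deep_pos, cfg$superficial_pos), function(p)
        any(rownorms(cand$positions -
                       matrix(p, nrow(cand$positions), 3, byrow = TRUE)) <=
              roi_r0), TRUE))
      if (ok) { space <- cand; break }
    }
    if (is.null(space))
      stop("a ROI contains no DOFs; increase n_dofs or roi_diameter")
    loads <- source_load_vectors(space, mesh, kind = "hdiv10",
                                 constraint = "cartesian")
    lf <- eeg_leadfield(sys, loads)
    lf$L <- lf$L * 1e-9           # V per nAm
    truth_space <- source_space_at(mesh, rbind(cfg$deep_pos,
                                               cfg$superficial_pos))
    truth_loads <- source_load_vectors(truth_space, mesh, kind = "hdiv10",
                                       constraint = "cartesian")
    lf_truth <- eeg_leadfield(sys, truth_loads)
    lf_truth$L <- lf_truth$L * 1e-9
    context <- list(mesh = mesh, lf = lf, space = space,
                    lf_truth = lf_truth)
  }
  lf <- context$lf; space <- context$space; lf_truth <- context$lf_truth
  ori <- cfg$orientation / vnorm(cfg$orientation)
  x_truth <- cfg$amplitude * c(ori, ori)   # deep xyz, superficial xyz
  y_clean <- as.numeric(lf_truth$L %*% x_truth)
  sdn <- cfg$noise_percent / 100 * max(abs(y_clean))
  truth_pos <- rbind(deep = cfg$deep_pos, superficial = cfg$superficial_pos)
  roi_r <- cfg$roi_diameter / 2
  in_roi <- lapply(1:2, function(s)
    which(rownorms(space$positions -
                     matrix(truth_pos[s, ], nrow(space$positions), 3,
                            byrow = TRUE)) <= roi_r))
  if (any(vapply(in_roi, length, 0L) == 0L))
    stop("a ROI contains no DOFs; increase n_dofs or roi_diameter")
  roi_mask <- logical(nrow(space$positions))
  roi_mask[unlist(in_roi)] <- TRUE
  rows <- list()
  for (ci in seq_len(nrow(cfg$cases))) {
    par <- hbm_params(hypermodel = cfg$cases$hypermodel[ci],
                      beta = cfg$beta, theta0 = cfg$cases$theta0[ci],
                      noise_std = sdn, n_ias_steps = cfg$n_ias_steps)
    for (r in seq_len(cfg$n_realizations)) {
      old <- .Random.seed_guard((cfg$noise_seed_base %||%
                                   (cfg$seed * 1000L)) + r)
      noise <- rnorm(length(y_clean), 0, sdn)
      old()
      y <- y_clean + noise
      st <- ias_map_roi(lf$L, y, roi_mask, par, k = 3L)
      da <- dof_amplitudes(st$x, 3L)
      for (s in 1:2) {
        sel <- in_roi[[s]]
        com <- center_of_mass(space$positions[sel, , drop = FALSE],
                              da$amp[sel])
        resultant <- colSums(da$vec[sel, , drop = FALSE])
        cosang <- if (vnorm(resultant) > 0)
          abs(sum(resultant * ori)) / vnorm(resultant) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          case = ci, hypermodel = cfg$cases$hypermodel[ci],
          theta0 = cfg$cases$theta0[ci],
          source = rownames(truth_pos)[s], realization = r,
          pos_error_mm = 1000 * vnorm(com - truth_pos[s, ]),
          ori_error_deg = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(errors = do.call(rbind, rows), context = context, config = cfg)
}
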