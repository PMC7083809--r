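#' Hierarchical-Bayesian model parameters
#'
#' The prior on the coefficients is conditionally Gaussian with per-DOF
#' variances `theta`, which carry a gamma (`"G"`) or inverse-gamma (`"IG"`)
#' hyperprior with shape `beta` and scale `theta0`. The likelihood is
#' Gaussian with standard deviation `noise_std`.
#'
#' @param hypermodel `"G"` or `"IG"`.
#' @param beta hyperprior shape; must exceed 1 for `"IG"`, 0 for `"G"`.
#' @param theta0 hyperprior scale (> 0).
#' @param noise_std likelihood standard deviation in measurement units.
#' @param n_ias_steps number of IAS iterations (each one x-update followed
#'   by one theta-update).
#' @param rng_seed seed for stochastic variants.
#' @return An object of class `hbm_params`.
#' @export
hbm_params <- function(hypermodel = c("IG", "G"), beta = 1.5, theta0,
                       noise_std = NULL, n_ias_steps = 2L, rng_seed = 1L) {
  hypermodel <- match.arg(hypermodel)
  if (hypermodel == "IG" && beta <= 1) stop("IG hypermodel needs beta > 1")
  if (hypermodel == "G" && beta <= 0) stop("G hypermodel needs beta > 0")
  if (theta0 <= 0) stop("theta0 must be > 0")
  if (!is.null(noise_std) && noise_std <= 0) stop("noise_std must be > 0")
  structure(list(hypermodel = hypermodel, beta = beta, theta0 = theta0,
                 noise_std = noise_std, n_ias_steps = as.integer(n_ias_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "hbm_params")
}

#' Likelihood standard deviation from data
#'
#' `sigma_n = (percent / 100) * max_i |y_i|`.
#'
#' @param y measurement vector or matrix.
#' @param percent relative standard deviation in percent.
#' @return the likelihood standard deviation.
#' @export
noise_std_from_data <- function(y, percent) {
  m <- max(abs(y))
  if (m == 0) stop("all-zero measurement vector")
  percent / 100 * m
}

#' IAS coefficient update (x-step)
#'
#' Conditionally Gaussian MAP of the coefficients given the variances, in
#' the data-space form `x = D L' (L D L' + sigma_n^2 I)^{-1} y` with
#' `D = diag(theta)`; the matrix inverted is only `n_sensors` square.
#'
#' @param L lead-field matrix (sensors x DOF columns).
#' @param y measurement vector.
#' @param theta per-column variance vector (> 0).
#' @param noise_std likelihood standard deviation.
#' @return coefficient vector `x`.
#' @export
ias_x_step <- function(L, y, theta, noise_std) {
  if (any(theta <= 0)) stop("theta must be positive")
  DLt <- theta * t(L)                    # DOF x sensors
  S <- L %*% DLt + diag(noise_std^2, nrow(L))
  # S is SPD by construction; Cholesky tolerates the strong
  # prior-to-noise conditioning that a generic solve rejects
  R <- tryCatch(chol(S), error = function(e)
    stop("singular data-space system: ", conditionMessage(e)))
  sol <- backsolve(R, forwardsolve(t(R), y))
  as.numeric(DLt %*% sol)
}

#' IAS variance update (theta-step)
#'
#' Closed-form conditional-posterior maximizer of each location's variance
#' given its coefficients. With `s_i = ||x_i||^2` over the location's `k`
#' components and `eta = beta - (k + 2) / 2`:
#' gamma hyperprior `theta_i = theta0 (eta/2 + sqrt(eta^2/4 + s_i/(2
#' theta0)))`; inverse-gamma `theta_i = (theta0 + s_i/2) / (beta + (k +
#' 2)/2)`. A floor of `1e-12 * theta0` keeps the variances positive.
#'
#' @param x coefficient vector (xyz-interleaved when `k = 3`).
#' @param params an [hbm_params()].
#' @param k components per location (1 or 3).
#' @return per-location variance vector.
#' @export
ias_theta_step <- function(x, params, k = 1L) {
  s <- location_norms2(x, k)
  theta0 <- params$theta0; beta <- params$beta
  th <- if (params$hypermodel == "G") {
    eta <- beta - (k + 2) / 2
    theta0 * (eta / 2 + sqrt(eta^2 / 4 + s / (2 * theta0)))
  } else {
    (theta0 + s / 2) / (beta + (k + 2) / 2)
  }
  pmax(th, 1e-12 * theta0)
}

# squared Euclidean norm per location over k interleaved components
location_norms2 <- function(x, k) {
  if (k == 1L) return(x^2)
  nloc <- length(x) / k
  colSums(matrix(x, k, nloc)^2)
}

# expand per-location values to per-column (xyz interleaving)
expand_theta <- function(theta, k) {
  if (k == 1L) theta else rep(theta, each = k)
}

# negative log posterior of (x, theta) up to an additive constant
ias_objective <- function(L, y, x, theta, params, k = 1L) {
  r <- y - as.numeric(L %*% x)
  s <- location_norms2(x, k)
  lik <- sum(r^2) / (2 * params$noise_std^2)
  pri <- sum(s / (2 * theta) + (k / 2) * log(theta))
  hyp <- if (params$hypermodel == "G")
    sum(-(params$beta - 1) * log(theta) + theta / params$theta0)
  else
    sum((params$beta + 1) * log(theta) + params$theta0 / theta)
  lik + pri + hyp
}

#' IAS MAP estimate
#'
#' Iterated alternating sequential scheme: initialize every variance at
#' `theta0`, then repeat `n_ias_steps` times (x-step, theta-step). The step
#' count is the number of theta-updates; `n_ias_steps = 0` returns the
#' single x-step at `theta = theta0`. Both steps are exact conditional
#' maximizers, so the posterior objective is non-increasing.
#'
#' @param L lead-field matrix.
#' @param y measurement vector.
#' @param params an [hbm_params()]; `noise_std` must be set.
#' @param k components per location (1 or 3; columns xyz-interleaved for 3).
#' @param theta_init optional initial per-location variance vector.
#' @return An object of class `hyper_state`: `x`, `theta`, `objective`
#'   (trace, one value per iterate), `k`.
#' @export
ias_map <- function(L, y, params, k = 1L, theta_init = NULL) {
  if (is.null(params$noise_std)) stop("params$noise_std is not set")
  nloc <- ncol(L) / k
  theta <- theta_init %||% rep(params$theta0, nloc)
  x <- ias_x_step(L, y, expand_theta(theta, k), params$noise_std)
  obj <- ias_objective(L, y, x, theta, params, k)
  if (params$n_ias_steps >= 1L) {
    for (it in seq_len(params$n_ias_steps)) {
      theta <- ias_theta_step(x, params, k)
      x <- ias_x_step(L, y, expand_theta(theta, k), params$noise_std)
      obj <- c(obj, ias_objective(L, y, x, theta, params, k))
    }
  }
  structure(list(x = x, theta = theta, objective = obj, k = k),
            class = "hyper_state")
}

#' @export
print.hyper_state <- function(x, ...) {
  cat(sprintf("hyper_state: %d coefficients (k = %d), max |x| = %g\n",
              length(x$x), x$k, max(abs(x$x))))
  invisible(x)
}

#' Region-of-interest IAS MAP estimate
#'
#' Identical to [ias_map()] on the column-restricted lead field; off-ROI
#' coefficients are exactly zero.
#'
#' @param L lead-field matrix.
#' @param y measurements.
#' @param roi_mask logical per-location mask (length `ncol(L) / k`).
#' @param params an [hbm_params()].
#' @param k components per location.
#' @return A `hyper_state` over the full DOF set.
#' @export
ias_map_roi <- function(L, y, roi_mask, params, k = 1L) {
  roi_mask <- as.logical(roi_mask)
  if (!any(roi_mask)) stop("empty ROI")
  colmask <- if (k == 1L) roi_mask else rep(roi_mask, each = k)
  st <- ias_map(L[, colmask, drop = FALSE], y, params, k = k)
  x <- numeric(ncol(L)); x[colmask] <- st$x
  theta <- rep(params$theta0, ncol(L) / k); theta[roi_mask] <- st$theta
  structure(list(x = x, theta = theta, objective = st$objective, k = k),
            class = "hyper_state")
}

#' Randomized domain decomposition
#'
#' Draws `n_subsets` center points uniformly from the DOF bounding volume
#' and assigns every DOF to its nearest center (Euclidean, ties to the
#' lowest index). Decompositions with empty subsets are redrawn.
#'
#' @param dof_positions n x 3 matrix of DOF positions.
#' @param n_subsets number of subsets (<= number of DOFs).
#' @param rng_seed integer seed.
#' @param max_retries redraw budget for empty subsets.
#' @return An object of class `decomposition`: `centers`, `assignment`
#'   (subset index per DOF), `n_subsets`.
#' @export
randomized_decomposition <- function(dof_positions, n_subsets, rng_seed = 1L,
                                     max_retries = 100L) {
  dof_positions <- as_points3(dof_positions)
  n <- nrow(dof_positions)
  if (n_subsets > n) stop("n_subsets exceeds number of DOFs")
  if (n_subsets == n)  # finest resolution: centers at the DOFs themselves
    return(structure(list(centers = dof_positions,
                          assignment = seq_len(n), n_subsets = n),
                     class = "decomposition"))
  lo <- apply(dof_positions, 2, min); hi <- apply(dof_positions, 2, max)
  old <- .Random.seed_guard(rng_seed)
  on.exit(old())
  draw <- function(k) cbind(runif(k, lo[1], hi[1]),
                            runif(k, lo[2], hi[2]),
                            runif(k, lo[3], hi[3]))
  centers <- draw(n_subsets)
  for (try in seq_len(max_retries)) {
    assignment <- nearest_index(dof_positions, centers)
    empty <- setdiff(seq_len(n_subsets), unique(assignment))
    if (!length(empty))
      return(structure(list(centers = centers, assignment = assignment,
                            n_subsets = n_subsets),
                       class = "decomposition"))
    centers[empty, ] <- draw(length(empty))  # re-draw empty subsets only
  }
  stop("could not draw a decomposition without empty subsets in ",
       max_retries, " retries")
}

#' Multiresolution IAS MAP with decomposition averaging
#'
#' For each of `n_decompositions` randomized decompositions the lead-field
#' columns of every subset are summed into one low-resolution column, the
#' IAS MAP estimate is computed on the reduced problem and broadcast back to
#' the member DOFs. Decompositions are chained serially: the previous
#' full-resolution estimate, projected onto the new decomposition by subset
#' means, initializes the variances. The final estimate is the mean of the
#' per-decomposition MAP estimates; averaging suppresses
#' decomposition-related artifacts, which are close to independent across
#' random decompositions.
#'
#' @param L lead-field matrix (k = 1 column layout).
#' @param y measurements.
#' @param params an [hbm_params()].
#' @param n_subsets subsets per decomposition.
#' @param n_decompositions number of randomized decompositions averaged.
#' @param dof_positions DOF positions backing the columns.
#' @return A `hyper_state` with the averaged `x`; fields `x_single` (the
#'   first decomposition's estimate) and `n_decompositions` are attached.
#' @export
ias_multiresolution <- function(L, y, params, n_subsets, n_decompositions,
                                dof_positions) {
  if (n_decompositions < 1L) stop("n_decompositions must be >= 1")
  n <- ncol(L)
  x_prev <- NULL
  x_acc <- numeric(n)
  x_single <- NULL
  theta_last <- NULL
  for (j in seq_len(n_decompositions)) {
    dec <- randomized_decomposition(dof_positions, n_subsets,
                                    rng_seed = params$rng_seed + j)
    agg <- Matrix::sparseMatrix(i = seq_len(n), j = dec$assignment, x = 1,
                                dims = c(n, n_subsets))
    Lred <- as.matrix(L %*% agg)
    theta_init <- NULL
    if (!is.null(x_prev)) {
      cnt <- as.numeric(Matrix::colSums(agg))
      x_proj <- as.numeric(Matrix::crossprod(agg, x_prev)) / cnt
      theta_init <- ias_theta_step(x_proj, params, k = 1L)
    }
    st <- ias_map(Lred, y, params, k = 1L, theta_init = theta_init)
    x_full <- st$x[dec$assignment]
    if (j == 1L) x_single <- x_full
    x_acc <- x_acc + x_full
    x_prev <- x_full
    theta_last <- st$theta[dec$assignment]
  }
  structure(list(x = x_acc / n_decompositions, theta = theta_last,
                 objective = NULL, k = 1L, x_single = x_single,
                 n_decompositions = n_decompositions),
            class = "hyper_state")
}

# generalized inverse-Gaussian sampler, density ~ x^(lambda-1)
# exp(-(chi/x + psi x)/2). Shifted ratio-of-uniforms with numeric bounds;
# chi = 0 falls back to a gamma draw, psi = 0 to an inverse gamma.
rgig1 <- function(lambda, chi, psi) {
  if (chi <= 0) {
    if (lambda <= 0) stop("GIG with chi = 0 needs lambda > 0")
    return(rgamma(1L, shape = lambda, rate = psi / 2))
  }
  if (psi <= 0) {
    if (lambda >= 0) stop("GIG with psi = 0 needs lambda < 0")
    return(1 / rgamma(1L, shape = -lambda, rate = chi / 2))
  }
  alpha <- sqrt(chi / psi)
  omega <- sqrt(chi * psi)
  lam <- lambda
  flip <- FALSE
  if (lam < 0) { lam <- -lam; flip <- TRUE }
  # standardized density g(z) ~ z^(lam-1) exp(-omega (z + 1/z) / 2)
  lg <- function(z) (lam - 1) * log(z) - omega * (z + 1 / z) / 2
  zm <- ((lam - 1) + sqrt((lam - 1)^2 + omega^2)) / omega  # mode
  lgm <- lg(zm)
  h <- function(z) exp(0.5 * (lg(z) - lgm))  # sqrt(g/g(mode)) <= 1
  vminus <- stats::optimize(function(z) (z - zm) * h(z),
                            interval = c(1e-12, zm))$objective
  # upper tail: search on an expanding interval
  hi <- zm + 1
  while ((hi - zm) * h(hi) > 1e-14 * abs(vminus) + 1e-300 && hi < 1e12)
    hi <- hi * 2
  vplus <- -stats::optimize(function(z) -(z - zm) * h(z),
                            interval = c(zm, hi))$objective
  repeat {
    u <- runif(1L)
    v <- runif(1L, vminus, vplus)
    z <- zm + v / u
    if (z > 0 && 2 * log(u) <= lg(z) - lgm) break
  }
  if (flip) z <- 1 / z
  alpha * z
}

#' Gibbs-sampler conditional-mean estimate
#'
#' Alternately samples the coefficients given the variances (exact Gaussian
#' draw in data-space form: `x = xt + D L' (L D L' + sigma^2 I)^{-1} (y - L
#' xt - n)` with `xt ~ N(0, D)`, `n ~ N(0, sigma^2 I)`) and the variances
#' given the coefficients (inverse-gamma conditional under the IG
#' hypermodel; generalized inverse-Gaussian under G). The conditional mean
#' is the post-burn-in sample mean.
#'
#' @param L lead-field matrix.
#' @param y measurements.
#' @param params an [hbm_params()]; `noise_std` must be set.
#' @param n_samples total Gibbs sweeps.
#' @param burn_in sweeps discarded (< `n_samples`).
#' @param k components per location.
#' @param keep_samples if `TRUE`, the post-burn-in coefficient draws are
#'   returned (`n_kept` x DOF matrix).
#' @return list with `cm` (conditional-mean coefficients), `theta_mean`,
#'   `samples` (or `NULL`), `n_kept`.
#' @export
gibbs_cm <- function(L, y, params, n_samples = 2000L, burn_in = 500L,
                     k = 1L, keep_samples = FALSE) {
  if (n_samples <= burn_in) stop("n_samples must exceed burn_in")
  if (is.null(params$noise_std)) stop("params$noise_std is not set")
  m <- nrow(L); p <- ncol(L); nloc <- p / k
  sigma <- params$noise_std
  old <- .Random.seed_guard(params$rng_seed)
  on.exit(old())
  theta <- rep(params$theta0, nloc)
  x_acc <- numeric(p); th_acc <- numeric(nloc)
  kept <- 0L
  samples <- if (keep_samples)
    matrix(0, n_samples - burn_in, p) else NULL
  for (it in seq_len(n_samples)) {
    d <- expand_theta(theta, k)
    xt <- rnorm(p, 0, sqrt(d))
    nn <- rnorm(m, 0, sigma)
    S <- L %*% (d * t(L)) + diag(sigma^2, m)
    R <- chol(S)
    rhs <- y - as.numeric(L %*% xt) - nn
    x <- xt + as.numeric((d * t(L)) %*%
                           backsolve(R, forwardsolve(t(R), rhs)))
    s <- location_norms2(x, k)
    if (params$hypermodel == "IG") {
      theta <- 1 / rgamma(nloc, shape = params$beta + k / 2,
                          rate = params$theta0 + s / 2)
    } else {
      theta <- vapply(s, function(si)
        rgig1(params$beta - k / 2, max(si, 1e-300), 2 / params$theta0), 0)
    }
    if (it > burn_in) {
      kept <- kept + 1L
      x_acc <- x_acc + x
      th_acc <- th_acc + theta
      if (keep_samples) samples[kept, ] <- x
    }
  }
  list(cm = x_acc / kept, theta_mean = th_acc / kept, samples = samples,
       n_kept = kept)
}

#' Draws from the gamma / inverse-gamma hypermodel coupling
#'
#' Utility used to exercise the reciprocity between the two hypermodels:
#' the elementwise reciprocal of a G(beta, theta0) variable is IG(beta,
#' 1/theta0) distributed.
#'
#' @param n number of draws.
#' @param hypermodel `"G"` or `"IG"`.
#' @param beta shape.
#' @param theta0 scale.
#' @param rng_seed seed.
#' @return numeric vector of draws.
#' @export
rhyperprior <- function(n, hypermodel = c("G", "IG"), beta, theta0,
                        rng_seed = 1L) {
  hypermodel <- match.arg(hypermodel)
  old <- .Random.seed_guard(rng_seed)
  on.exit(old())
  if (hypermodel == "G") rgamma(n, shape = beta, scale = theta0)
  else theta0 / rgamma(n, shape = beta)  # scale-theta0 inverse gamma
}

#' Read / write measurement matrices as delimited text
#'
#' Rows are sensors, columns time steps.
#'
#' @param path file path.
#' @param y measurement matrix or vector.
#' @return `read_measurements` returns a numeric matrix.
#' @export
read_measurements <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_measurements
#' @export
write_measurements <- function(y, path) {
  utils::write.table(as.matrix(y), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
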