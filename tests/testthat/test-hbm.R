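test_that("likelihood std follows the percent-of-maximum rule", {
  y <- c(-10, 3, 7)
  expect_equal(noise_std_from_data(y, 3), 0.3)
  expect_equal(noise_std_from_data(y, 12), 1.2)
  expect_equal(noise_std_from_data(-5 * y, 3), 5 * 0.3)
  expect_error(noise_std_from_data(numeric(3), 3), "all-zero")
})

test_that("hbm_params validates hypermodel-specific shapes", {
  expect_error(hbm_params("IG", beta = 0.9, theta0 = 1), "beta > 1")
  expect_error(hbm_params("G", beta = -1, theta0 = 1), "beta > 0")
  expect_error(hbm_params("G", beta = 1.5, theta0 = 0), "theta0")
  expect_s3_class(hbm_params("G", beta = 0.99, theta0 = 1), "hbm_params")
})

test_that("the x-step is the conditionally Gaussian MAP in both algebraic
           forms", {
  # noiseless scalar identity
  expect_equal(ias_x_step(matrix(1), 3, theta = 1, noise_std = 1e-9), 3,
               tolerance = 1e-12)
  # theta -> 0 shrinks to zero
  expect_lt(abs(ias_x_step(matrix(1), 3, theta = 1e-14, noise_std = 1)),
            1e-10)
  # data-space vs DOF-space identity on random systems
  set.seed(21)
  for (i in 1:10) {
    L <- matrix(rnorm(60), 5, 12)
    y <- rnorm(5); th <- rexp(12); sn <- runif(1, 0.05, 2)
    x1 <- ias_x_step(L, y, th, sn)
    x2 <- as.numeric(solve(crossprod(L) / sn^2 + diag(1 / th),
                           crossprod(L, y) / sn^2))
    expect_lt(max(abs(x1 - x2)), 1e-8 * max(abs(x2), 1))
  }
})

test_that("theta updates equal brute-force conditional-posterior maximizers
           and reproduce the closed-form examples", {
  # closed-form spot checks
  expect_equal(ias_theta_step(1, hbm_params("G", 1.5, 0.02, 1), k = 1), 0.1,
               tolerance = 1e-12)
  expect_equal(ias_theta_step(1, hbm_params("IG", 1.5, 0.5, 1), k = 1),
               1 / 3, tolerance = 1e-12)
  # zero-signal fixed points
  expect_equal(ias_theta_step(0, hbm_params("IG", 1.5, 0.3, 1), k = 1),
               0.3 / 3, tolerance = 1e-12)
  expect_equal(ias_theta_step(0, hbm_params("G", 1.5, 0.02, 1), k = 1),
               1e-12 * 0.02)  # eta = 0: documented floor

  # brute-force 1-D maximizer over a wide bracket
  grid_max <- function(s, beta, theta0, k, hm) {
    f <- function(th) {
      -k / 2 * log(th) - s / (2 * th) +
        if (hm == "G") (beta - 1) * log(th) - th / theta0
        else -(beta + 1) * log(th) - theta0 / th
    }
    optimize(f, c(1e-12, 1e8), maximum = TRUE, tol = 1e-14)$maximum
  }
  set.seed(22)
  for (i in 1:100) {
    k <- sample(c(1L, 3L), 1)
    hm <- sample(c("G", "IG"), 1)
    beta <- runif(1, 1.05, 4)
    theta0 <- 10^runif(1, -6, 1)
    x <- rnorm(k, sd = 10^runif(1, -2, 1))
    th <- ias_theta_step(x, hbm_params(hm, beta, theta0, 1), k = k)
    gm <- grid_max(sum(x^2), beta, theta0, k, hm)
    expect_lt(abs(th - gm) / gm, 1e-5)
  }
})

test_that("IAS MAP honors the step-count convention, is deterministic, and
           its objective never increases", {
  set.seed(23)
  L <- matrix(rnorm(8 * 30), 8)
  y <- rnorm(8)
  p0 <- hbm_params("IG", 1.5, 0.01, noise_std = 0.1, n_ias_steps = 0L)
  st0 <- ias_map(L, y, p0)
  expect_equal(st0$x, ias_x_step(L, y, rep(0.01, 30), 0.1))

  p <- hbm_params("IG", 1.5, 0.01, noise_std = 0.1, n_ias_steps = 8L)
  st <- ias_map(L, y, p)
  expect_true(all(diff(st$objective) <= 1e-9 * abs(st$objective[1])))
  expect_identical(st$x, ias_map(L, y, p)$x)
  expect_equal(ias_map(L, numeric(8), p)$x, numeric(30))

  pg <- hbm_params("G", 1.5, 0.01, noise_std = 0.1, n_ias_steps = 8L)
  stg <- ias_map(L, y, pg)
  expect_true(all(diff(stg$objective) <= 1e-9 * abs(stg$objective[1])))
})

test_that("ROI-restricted IAS equals the full solve on a full ROI, zeroes
           off-ROI coefficients and matches the scalar closed form", {
  set.seed(24)
  L <- matrix(rnorm(6 * 20), 6)
  y <- rnorm(6)
  p <- hbm_params("IG", 1.5, 0.05, noise_std = 0.2, n_ias_steps = 3L)
  full <- ias_map(L, y, p)
  roi_all <- ias_map_roi(L, y, rep(TRUE, 20), p)
  expect_equal(roi_all$x, full$x)

  mask <- rep(FALSE, 20); mask[c(4, 9)] <- TRUE
  st <- ias_map_roi(L, y, mask, p)
  expect_true(all(st$x[!mask] == 0))

  # single-DOF ROI against the 1-D fixed-point iteration
  mask1 <- rep(FALSE, 20); mask1[7] <- TRUE
  st1 <- ias_map_roi(L, y, mask1, p)
  l <- L[, 7]; th <- 0.05
  for (it in 1:3) {
    xs <- th * sum(l * y) / (th * sum(l * l) + 0.2^2)
    th <- max((0.05 + xs^2 / 2) / 3, 1e-12 * 0.05)
    xs <- th * sum(l * y) / (th * sum(l * l) + 0.2^2)
  }
  expect_lt(abs(st1$x[7] - xs), 1e-10 * abs(xs))
  expect_error(ias_map_roi(L, y, rep(FALSE, 20), p), "empty ROI")
})

test_that("randomized decompositions partition the DOFs with near-equal
           expected subset sizes", {
  set.seed(25)
  pos <- matrix(runif(300 * 3, -1, 1), 300)
  dec <- randomized_decomposition(pos, 30L, rng_seed = 1)
  expect_equal(sort(unique(dec$assignment)), 1:30)
  expect_length(dec$assignment, 300L)

  # with n_subsets = n_DOFs every subset is a singleton (identity partition
  # up to labels)
  dec_id <- randomized_decomposition(pos[1:40, ], 40L, rng_seed = 2)
  expect_identical(dec_id$assignment, 1:40)
  expect_identical(dec_id$centers, pos[1:40, ])

  # empirical subset-size expectation ~ n/n_subsets over 100 seeds
  sizes <- unlist(lapply(1:100, function(s)
    tabulate(randomized_decomposition(pos, 10L, rng_seed = s)$assignment,
             10L)))
  expect_lt(abs(mean(sizes) - 30), 4 * sd(sizes) / sqrt(length(sizes)))
  expect_error(randomized_decomposition(pos, 301L), "exceeds")
})

test_that("multiresolution IAS reduces to the plain MAP for one identity
           decomposition and is deterministic", {
  set.seed(26)
  n <- 25L
  pos <- matrix(runif(3 * n, -1, 1), n)
  L <- matrix(rnorm(7 * n), 7)
  y <- rnorm(7)
  p <- hbm_params("IG", 1.5, 0.02, noise_std = 0.15, n_ias_steps = 2L,
                  rng_seed = 5)
  st_mr <- ias_multiresolution(L, y, p, n_subsets = n, n_decompositions = 1L,
                               dof_positions = pos)
  st <- ias_map(L, y, p)
  # identity partition up to subset relabeling: same coefficients per DOF
  expect_equal(st_mr$x, st$x, tolerance = 1e-10)
  st_mr2 <- ias_multiresolution(L, y, p, n_subsets = n,
                                n_decompositions = 1L, dof_positions = pos)
  expect_identical(st_mr$x, st_mr2$x)

  st_avg <- ias_multiresolution(L, y, p, n_subsets = 8L,
                                n_decompositions = 5L, dof_positions = pos)
  expect_length(st_avg$x, n)
  expect_length(st_avg$x_single, n)
})

test_that("the Gibbs sampler stays in support, is seed-reproducible and
           matches a quadrature posterior mean on the 1-DOF model", {
  l <- 0.8; yv <- 1.2; sn <- 0.4
  p <- hbm_params("IG", 1.5, 0.5, noise_std = sn, rng_seed = 31)
  g1 <- gibbs_cm(matrix(l), yv, p, n_samples = 3000, burn_in = 500,
                 keep_samples = TRUE)
  g2 <- gibbs_cm(matrix(l), yv, p, n_samples = 3000, burn_in = 500,
                 keep_samples = TRUE)
  expect_identical(g1$samples, g2$samples)
  expect_true(all(g1$theta_mean > 0))
  expect_error(gibbs_cm(matrix(l), yv, p, n_samples = 10, burn_in = 10),
               "exceed")

  # quadrature oracle over (x, theta) for the exact posterior mean
  post <- function(x, th)
    exp(-(l * x - yv)^2 / (2 * sn^2)) * th^(-0.5) * exp(-x^2 / (2 * th)) *
      th^(-1.5 - 1) * exp(-0.5 / th)
  xs <- seq(-4, 6, length.out = 400)
  ths <- exp(seq(log(1e-4), log(50), length.out = 400))
  W <- outer(xs, ths, post) %*% diag(ths)  # log-spacing weight ~ theta
  pm <- sum(W * xs) / sum(W)
  p20 <- hbm_params("IG", 1.5, 0.5, noise_std = sn, rng_seed = 32)
  g <- gibbs_cm(matrix(l), yv, p20, n_samples = 20000, burn_in = 2000,
                keep_samples = TRUE)
  # MC standard error with an autocorrelation (batch-means) correction
  bm <- tapply(g$samples[, 1], rep(1:60, length.out = g$n_kept), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(g$cm - pm), 3 * se)
})

test_that("the G-hypermodel Gibbs conditional uses a correct GIG sampler", {
  # MC moments of the standardized GIG against numerical integration
  set.seed(33)
  for (par in list(c(0.5, 2, 3), c(-0.25, 1.5, 0.8), c(1.2, 0.3, 4))) {
    dr <- replicate(8000, neurofem:::rgig1(par[1], par[2], par[3]))
    f <- function(x) x^(par[1] - 1) * exp(-(par[2] / x + par[3] * x) / 2)
    xs <- seq(1e-6, 60, length.out = 2e5)
    m1 <- sum(xs * f(xs)) / sum(f(xs))
    expect_lt(abs(mean(dr) - m1) / m1, 0.05)
  }
  # chi = 0 reduces to a gamma draw; the full G-model sampler runs
  p <- hbm_params("G", 1.5, 0.5, noise_std = 0.4, rng_seed = 34)
  g <- gibbs_cm(matrix(0.8), 1.2, p, n_samples = 500, burn_in = 100)
  expect_true(is.finite(g$cm))
})

test_that("reciprocals of gamma hyperprior draws are inverse-gamma
           distributed", {
  theta <- rhyperprior(1e5, "G", beta = 1.5, theta0 = 0.3, rng_seed = 35)
  # IG(beta, 1/theta0... scale s) CDF: P(1/theta <= t) = 1 - pgamma(1/t)
  ks <- suppressWarnings(
    ks.test(1 / theta, function(q) 1 - pgamma(1 / q, shape = 1.5,
                                              scale = 0.3)))
  expect_gt(ks$p.value, 0.001)
  # and the direct IG generator agrees in distribution with inverted G draws
  ig <- rhyperprior(1e5, "IG", beta = 1.5, theta0 = 1 / 0.3, rng_seed = 36)
  ks2 <- suppressWarnings(ks.test(1 / theta, ig))
  expect_gt(ks2$p.value, 0.001)
})

test_that("measurement matrices round-trip through delimited text", {
  f <- withr::local_tempfile(fileext = ".txt")
  y <- matrix(rnorm(12), 4)
  write_measurements(y, f)
  expect_equal(unname(read_measurements(f)), y, tolerance = 1e-12)
})
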