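# Analytic potentials and the overdamped sampler.

test_that("bundled potentials match their closed forms at landmark points", {
  h1 <- make_standard_system("harmonic_nd", list(k = 2, dimension = 1))
  expect_equal(potential_energy(h1, 0), 0)
  expect_equal(drop(potential_gradient(h1, 0)), 0)
  expect_equal(potential_energy(h1, 3), 0.5 * 2 * 9)

  q <- make_standard_system("quartic_1d", list(h = 3))
  expect_equal(potential_energy(q, c(-1, 1)), c(0, 0))
  expect_equal(potential_energy(q, 0), 3)

  dw <- make_standard_system("double_well_nd", list(dimension = 3, h = 2, k = 5))
  expect_equal(potential_energy(dw, c(1, 0, 0)), 0)
  expect_equal(potential_energy(dw, c(0, 1, 1)), 2 + 5)
})

test_that("invalid system parameters are rejected", {
  expect_error(make_standard_system("nope"), "arg")
  expect_error(make_standard_system("harmonic_nd", list(k = -1)), "positive")
  expect_error(make_standard_system("quartic_1d", list(h = 0)), "positive")
  expect_error(make_standard_system("harmonic_nd", list(dimension = 0)), ">= 1")
  expect_error(make_standard_system("quartic_1d", list(kT = -2)), "kT")
})

test_that("analytic gradients agree with central finite differences", {
  systems <- list(
    make_standard_system("harmonic_nd", list(k = c(1, 3, 0.5), dimension = 3)),
    make_standard_system("quartic_1d", list(h = 4)),
    make_standard_system("double_well_nd", list(dimension = 4, h = 3, k = 2)),
    make_standard_system("mueller_brown"))
  withr::with_seed(11, {
    for (sys in systems) {
      d <- sys$dimension
      X <- matrix(runif(6 * d, -1.2, 1.4), 6, d)
      G <- potential_gradient(sys, X)
      eps <- 1e-6
      for (j in seq_len(d)) {
        Xp <- X; Xm <- X
        Xp[, j] <- Xp[, j] + eps
        Xm[, j] <- Xm[, j] - eps
        fd <- (potential_energy(sys, Xp) - potential_energy(sys, Xm)) / (2 * eps)
        expect_lt(max(abs(fd - G[, j]) / pmax(abs(fd), 1)), 1e-5)
      }
    }
  })
})

test_that("Mueller-Brown stationary points match a grid + descent oracle", {
  sys <- make_standard_system("mueller_brown")
  oracle <- grid_stationary_points(sys, c(-1.8, 1.2), c(-0.4, 2.2), n = 90L)
  found <- rbind(sys$minima, sys$saddles)
  # every documented point is recovered by the oracle
  for (i in seq_len(nrow(found))) {
    dists <- vapply(oracle, function(p) sqrt(sum((p - found[i, ])^2)),
                    numeric(1L))
    expect_lt(min(dists), 1e-4)
  }
  # and the Newton refiner classifies them correctly
  for (i in seq_len(nrow(sys$minima))) {
    expect_identical(refine_stationary_point(sys, sys$minima[i, ])$type,
                     "minimum")
  }
  for (i in seq_len(nrow(sys$saddles))) {
    expect_identical(refine_stationary_point(sys, sys$saddles[i, ])$type,
                     "saddle")
  }
})

test_that("unrestrained harmonic sampling reproduces the Gaussian variance", {
  sys <- make_standard_system("harmonic_nd", list(k = 1, dimension = 1))
  b <- sample_restrained(sys, n_steps = 50000L, step_size = 0.05, seed = 7L)
  v <- var(b$positions[, 1L])
  # effective sample size from the integrator correlation time
  g <- statistical_inefficiency(b$positions[, 1L])
  se <- sqrt(2 / (50000 / g))
  expect_lt(abs(v - 1), 3 * se + 0.05 / 2)  # 3 sigma plus the O(dt) bias
})

test_that("a dominant restraint pins the sampled CV mean to its center", {
  sys <- make_standard_system("harmonic_nd", list(k = 1, dimension = 2))
  center <- c(0.7, -0.3)
  b <- sample_restrained(sys, center = center, spring = 1e4,
                         n_steps = 20000L, step_size = 2e-5, seed = 3L)
  m <- colMeans(b$positions)
  g <- statistical_inefficiency(b$positions[, 1L])
  se <- sd(b$positions[, 1L]) * sqrt(g / 20000)
  expect_lt(max(abs(m - center * 1e4 / (1e4 + 1))), 3 * se)
})

test_that("sampling is bit-reproducible and leaves the caller's RNG alone", {
  sys <- make_standard_system("quartic_1d")
  set.seed(999)
  before <- .Random.seed
  b1 <- sample_restrained(sys, n_steps = 500L, step_size = 1e-3, seed = 42L)
  expect_identical(.Random.seed, before)
  b2 <- sample_restrained(sys, n_steps = 500L, step_size = 1e-3, seed = 42L)
  expect_identical(b1$positions, b2$positions)
  b3 <- sample_restrained(sys, n_steps = 500L, step_size = 1e-3, seed = 43L)
  expect_false(identical(b1$positions, b3$positions))
})

test_that("diverging integration aborts with the step index", {
  sys <- make_standard_system("harmonic_nd", list(k = 1, dimension = 1))
  expect_error(
    sample_restrained(sys, n_steps = 200L, step_size = 10, seed = 1L,
                      x0 = 5, divergence_bound = 100),
    "diverged at step")
  expect_error(
    sample_restrained(sys, center = 0, spring = -1, n_steps = 10L,
                      step_size = 1e-3, seed = 1L),
    "nonnegative")
})

test_that("1D quartic samples pass a Boltzmann goodness-of-fit check", {
  # a 1 kT barrier keeps the well-hopping time short enough that 1e5 steps
  # hold many independent crossings; the position series is subsampled by
  # its own inefficiency before the chi-square test
  sys <- make_standard_system("quartic_1d", list(h = 1))
  b <- sample_restrained(sys, n_steps = 100000L, step_size = 5e-3, seed = 17L)
  x <- b$positions[, 1L]
  g <- statistical_inefficiency(x)
  xs <- x[seq(1L, length(x), by = ceiling(g))]
  expect_gt(length(xs), 100L)
  edges <- seq(-1.8, 1.8, length.out = 19L)
  obs <- tabulate(findInterval(xs, edges, rightmost.closed = TRUE),
                  length(edges) - 1L)
  # expected bin probabilities by dense quadrature
  fine <- seq(-2.5, 2.5, length.out = 20001L)
  w <- exp(-potential_energy(sys, matrix(fine)))
  cdf <- cumsum(w) / sum(w)
  pb <- diff(approx(fine, cdf, edges, rule = 2)$y)
  keep <- pb * length(xs) >= 5
  ct <- suppressWarnings(chisq.test(obs[keep], p = pb[keep] / sum(pb[keep])))
  expect_gt(ct$p.value, 0.01)
})

test_that("quadrature CV free energy matches closed forms", {
  # identity CV on the quartic well: profile equals the potential
  q <- make_standard_system("quartic_1d", list(h = 3))
  grid <- seq(-1.2, 1.2, length.out = 25L)
  pm <- analytic_cv_pmf(q, NULL, grid)
  u <- potential_energy(q, matrix(grid))
  expect_equal(pm, u - min(u), tolerance = 1e-10)

  # harmonic marginal: quadratic with the same stiffness along the CV
  h2 <- make_standard_system("harmonic_nd", list(k = c(2, 5), dimension = 2))
  cvm <- cv_map(matrix(c(1, 0), 1L), c(0, 0))
  pmh <- analytic_cv_pmf(h2, cvm, grid)
  expect_equal(pmh, 0.5 * 2 * grid^2 - min(0.5 * 2 * grid^2), tolerance = 1e-6)

  # separable double well: barrier equals h minus the transverse-entropy
  # correction, itself computed by a second independent quadrature
  dw <- make_standard_system("double_well_nd", list(dimension = 2, h = 3, k = 2))
  cvm1 <- cv_map(matrix(c(1, 0), 1L), c(0, 0))
  grid2 <- c(-1, 0, 1)
  pm2 <- analytic_cv_pmf(dw, cvm1, grid2)
  yy <- seq(-8, 8, length.out = 4001L)
  entropy_at <- function(x1) {
    -log(sum(exp(-(potential_energy(dw, cbind(x1, yy)) -
                     potential_energy(dw, c(x1, 0))))))
  }
  correction <- entropy_at(0) - entropy_at(1)   # zero for a separable well
  expect_equal(pm2[2] - pm2[1], 3 - correction, tolerance = 1e-6)
  expect_equal(correction, 0, tolerance = 1e-8)
})

test_that("non-converged quadrature is reported with its refinement level", {
  # a genuinely z-dependent transverse integrand (separable systems cancel
  # the transverse factor in the min-shift and can never trigger this)
  mb <- make_standard_system("mueller_brown")
  cvm <- cv_map(matrix(c(1, 0), 1L), c(0, 0))
  expect_error(
    analytic_cv_pmf(mb, cvm, c(-0.5, 0.5), lower = -1, upper = 2.5,
                    n_quad = 11L, conv_tol = 1e-6),
    "not converged")
})
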