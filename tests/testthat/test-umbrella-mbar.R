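# Umbrella sampling, subsampling, and the MBAR estimator.

test_that("statistical inefficiency matches its analytic limits", {
  withr::with_seed(6, {
    expect_lt(abs(statistical_inefficiency(rnorm(10000)) - 1), 0.1)
  })
  withr::with_seed(5, {
    ar <- as.numeric(arima.sim(list(ar = 0.9), 100000L))
    g <- statistical_inefficiency(ar)
    expect_lt(abs(g - 19) / 19, 0.1)
  })
  expect_warning(g0 <- statistical_inefficiency(rep(2, 4L)), "constant")
  expect_identical(g0, 1)
  expect_error(statistical_inefficiency(c(1, 2, 3)), "length")
})

test_that("umbrella windows store recomputable reduced potentials", {
  sys <- make_standard_system("quartic_1d", list(h = 3, kT = 0.5))
  path <- linear_interpolation_path(-1, 1, 5L)
  ss <- run_umbrella_windows(sys, NULL, path, spring = 20, n_steps = 400L,
                             equilibration = 100L, step_size = 1e-3, seed = 4L)
  expect_s3_class(ss, "SampleSet")
  expect_identical(sum(ss$counts), nrow(ss$cv_values))
  # definition check: row k is U/kT plus the reduced window restraint
  U <- potential_energy(sys, ss$positions)
  for (k in c(1L, 3L, 5L)) {
    d2 <- (drop(ss$cv_values) - drop(path$images)[k])^2
    expect_equal(ss$reduced_potentials[k, ], U / 0.5 + 20 / (2 * 0.5) * d2,
                 tolerance = 1e-12)
  }
  # restrained mean within 3 standard errors of the Gaussian closed form
  h <- make_standard_system("harmonic_nd", list(k = 1, dimension = 1))
  hp <- linear_interpolation_path(-0.5, 0.5, 3L)
  hs <- run_umbrella_windows(h, NULL, hp, spring = 50, n_steps = 20000L,
                             equilibration = 1000L, step_size = 2e-3, seed = 9L)
  m <- tapply(drop(hs$cv_values), hs$window_index, mean)
  sigma <- sqrt(1 / 51)
  se <- sigma / sqrt(hs$counts)
  expected <- 50 * drop(hp$images) / 51
  expect_true(all(abs(m - expected) < 3.5 * se))
  # determinism
  ss2 <- run_umbrella_windows(sys, NULL, path, spring = 20, n_steps = 400L,
                              equilibration = 100L, step_size = 1e-3, seed = 4L)
  expect_identical(ss$positions, ss2$positions)
  expect_identical(ss$reduced_potentials, ss2$reduced_potentials)
})

test_that("MBAR handles gauge cases and the two-harmonic closed form", {
  # K = 1: free energy fixed at the gauge, uncertainty zero
  withr::with_seed(1, x <- rnorm(200L))
  one <- sample_set(matrix(x), matrix(x^2 / 2, 1L), 200L, rep(1L, 200L),
                    u_unbiased = x^2 / 2)
  r1 <- solve_mbar(one)
  expect_identical(r1$free_energies, 0)
  expect_equal(r1$covariance, matrix(0, 1L, 1L))
  expect_equal(r1$weights, rep(1 / 200, 200L), tolerance = 1e-12)

  # two states with identical reduced potentials: delta f is exactly zero
  two <- sample_set(matrix(x), rbind(x^2 / 2, x^2 / 2), c(100L, 100L),
                    rep(1:2, each = 100L), u_unbiased = x^2 / 2)
  r2 <- solve_mbar(two)
  expect_lt(abs(r2$free_energies[2L]), 1e-12)

  # analytic benchmark: k = 1 vs 4, delta f = 0.5 ln 4
  ss <- two_harmonic_fixture(5000L, seed = 33L)
  res <- solve_mbar(ss)
  se <- sqrt(res$covariance[1L, 2L])
  expect_lt(abs(res$free_energies[2L] - 0.5 * log(4)), 3 * se)
  expect_equal(sum(res$weights), 1, tolerance = 1e-10)
  expect_true(all(res$weights >= 0))
  # recovered unbiased expectation of theta and equipartition of x^2
  e1 <- mbar_expectation(res$weights, drop(ss$cv_values))
  expect_lt(abs(e1$estimate), 3 * e1$se)
  e2 <- mbar_expectation(res$weights, drop(ss$cv_values)^2)
  expect_lt(abs(e2$estimate - 1), 3 * e2$se)
})

test_that("all solvers agree with each other and with independent references", {
  ss <- two_harmonic_fixture(3000L, seed = 14L)
  f_h <- solve_mbar(ss, solver = "hybrid")$free_energies
  f_n <- solve_mbar(ss, solver = "newton")$free_energies
  f_s <- solve_mbar(ss, solver = "self_consistent")$free_energies
  expect_equal(f_h, f_n, tolerance = 1e-7)
  expect_equal(f_h, f_s, tolerance = 1e-7)
  # independent reference 1: BFGS minimization of the pooled likelihood
  f_ref <- mbar_reference(ss$reduced_potentials, ss$counts)
  expect_lt(abs(f_h[2L] - f_ref[2L]), 1e-6)
  # independent reference 2: Bennett acceptance ratio by root finding
  n <- ss$counts[1L]
  du <- ss$reduced_potentials[2L, ] - ss$reduced_potentials[1L, ]
  du1 <- du[ss$window_index == 1L]     # forward work values
  du2 <- -du[ss$window_index == 2L]    # reverse work values
  bar <- uniroot(function(C) {
    sum(1 / (1 + exp(du1 - C))) - sum(1 / (1 + exp(du2 + C)))
  }, c(-10, 10), tol = 1e-12)$root
  expect_lt(abs(f_h[2L] - bar), 1e-6)
})

test_that("gauge invariance: shifting one state's reduced potential shifts its f", {
  ss <- two_harmonic_fixture(1000L, seed = 2L)
  base <- solve_mbar(ss, compute_uncertainty = FALSE)$free_energies
  u2 <- ss$reduced_potentials
  u2[2L, ] <- u2[2L, ] + 1.7
  ss2 <- sample_set(ss$cv_values, u2, ss$counts, ss$window_index,
                    u_unbiased = ss$u_unbiased)
  shifted <- solve_mbar(ss2, compute_uncertainty = FALSE)$free_energies
  expect_equal(shifted[2L] - base[2L], 1.7, tolerance = 1e-7)
})

test_that("zero-count states get perturbation free energies", {
  withr::with_seed(21, x <- rnorm(4000L))
  u <- rbind(x^2 / 2, 2 * x^2, 8 * x^2)
  ss <- sample_set(matrix(x), u, c(4000L, 0L, 0L), rep(1L, 4000L),
                   u_unbiased = x^2 / 2)
  res <- solve_mbar(ss, compute_uncertainty = FALSE)
  expect_lt(abs(res$free_energies[2L] - 0.5 * log(4)), 0.05)
  expect_lt(abs(res$free_energies[3L] - 0.5 * log(16)), 0.1)
})

test_that("disconnected umbrella states are reported as such", {
  # two far-apart stiff windows with no phase-space overlap
  withr::with_seed(3, {
    x <- c(rnorm(300L, -20, 0.05), rnorm(300L, 20, 0.05))
  })
  u <- rbind(200 * (x + 20)^2, 200 * (x - 20)^2)
  ss <- sample_set(matrix(x), pmin(u, 690), c(300L, 300L),
                   rep(1:2, each = 300L))
  expect_error(solve_mbar(ss, max_iter = 200L), "disconnected")
})

test_that("MBAR uncertainties scale as 1/sqrt(n) and bracket replicate scatter", {
  se_n <- sqrt(solve_mbar(two_harmonic_fixture(2000L, seed = 7L))$covariance[1L, 2L])
  se_4n <- sqrt(solve_mbar(two_harmonic_fixture(8000L, seed = 7L))$covariance[1L, 2L])
  expect_lt(abs(se_n / se_4n - 2), 0.4)
  # coverage study: nominal 2-sigma intervals catch the truth >= 80% of runs
  hits <- vapply(1:50, function(r) {
    res <- solve_mbar(two_harmonic_fixture(800L, seed = 100L + r))
    abs(res$free_energies[2L] - 0.5 * log(4)) <
      2 * sqrt(res$covariance[1L, 2L])
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})

test_that("weighted expectations reduce to plain averages for uniform weights", {
  withr::with_seed(4, a <- rnorm(500L))
  w <- rep(1 / 500, 500L)
  e <- mbar_expectation(w, a)
  expect_equal(e$estimate, mean(a), tolerance = 1e-12)
  expect_equal(e$ess, 500, tolerance = 1e-9)
  ec <- mbar_expectation(w, rep(3.2, 500L))
  expect_identical(ec$estimate, 3.2)
  expect_identical(ec$se, 0)
  expect_error(mbar_expectation(c(0.5, 0.4), c(1, 2)), "normalized")
})

test_that("subsampled and full estimates agree on iid window data", {
  sys <- make_standard_system("harmonic_nd", list(k = 1, dimension = 1))
  hp <- linear_interpolation_path(-0.4, 0.4, 3L)
  full <- run_umbrella_windows(sys, NULL, hp, spring = 30, n_steps = 8000L,
                               equilibration = 500L, step_size = 5e-3,
                               seed = 13L, subsample = FALSE)
  sub <- run_umbrella_windows(sys, NULL, hp, spring = 30, n_steps = 8000L,
                              equilibration = 500L, step_size = 5e-3,
                              seed = 13L, subsample = TRUE)
  f_full <- solve_mbar(full)$free_energies
  r_sub <- solve_mbar(sub)
  se <- sqrt(pmax(r_sub$covariance[, 1L], 1e-12))
  expect_true(all(abs(f_full - r_sub$free_energies) <= 3 * se + 0.02))
})

test_that("fine-bin WHAM and MBAR give the same quartic profile", {
  sys <- make_standard_system("quartic_1d", list(h = 3))
  path <- linear_interpolation_path(-1, 1, 17L)
  ss <- run_umbrella_windows(sys, NULL, path, spring = 60, n_steps = 5000L,
                             equilibration = 500L, step_size = 2e-3, seed = 8L)
  res <- solve_mbar(ss, compute_uncertainty = FALSE)
  edges <- seq(-1.45, 1.45, by = 0.02)
  wh <- wham_oracle(drop(ss$cv_values), ss$window_index, ss$counts,
                    drop(path$images), 60, edges)
  pp <- projected_pmf(drop(ss$cv_values), res$weights, edges)
  sel <- wh$counts > 50 & is.finite(pp$pmf)
  pmf_wham <- -log(wh$rho)
  dev <- pp$pmf[sel] - pmf_wham[sel]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.05)
})
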