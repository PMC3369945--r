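# Voronoi assignment, cell probabilities and volumes, the volume-corrected
# PMF, per-cell structure statistics, densities and projections.

test_that("Voronoi assignment is exact nearest-neighbor with the cutoff rule", {
  Z <- as.matrix(expand.grid(seq(-1, 1, 0.5), seq(-1, 1, 0.5)))
  # a sample exactly at an image lands in that cell
  a <- assign_voronoi(Z[7L, , drop = FALSE], Z, cutoff = 1)
  expect_identical(a$cell_index, 7L)
  # far samples are outliers
  far <- matrix(c(50, 50), 1L)
  expect_true(is.na(assign_voronoi(far, Z, cutoff = 1)$cell_index))
  # brute-force oracle agreement on random samples, ties to lowest index
  withr::with_seed(10, X <- matrix(runif(4000, -1.6, 1.6), 2000L, 2L))
  a2 <- assign_voronoi(X, Z, cutoff = 0.6)
  oracle <- brute_nearest(X, Z, 0.6)
  expect_identical(a2$cell_index, as.integer(oracle[, "cell"]))
  expect_identical(a2$n_outliers, sum(is.na(oracle[, "cell"])))
  expect_error(assign_voronoi(X, Z[0L, , drop = FALSE], 1), "empty")
  expect_error(assign_voronoi(X, Z, cutoff = 0), "positive")
})

test_that("cell probabilities conserve mass and match direct summation", {
  withr::with_seed(11, {
    X <- matrix(rnorm(3000L), 1500L, 2L)
    Z <- rbind(c(-1, 0), c(0, 0), c(1, 0))
    asg <- assign_voronoi(X, Z, cutoff = 1.5)
    w <- runif(1500L); w <- w / sum(w)
    p <- cell_probabilities(w, asg)
    # direct per-cell summation oracle
    for (k in 1:3) {
      expect_equal(p[k],
                   sum(w[!is.na(asg$cell_index) & asg$cell_index == k]),
                   tolerance = 1e-12)
    }
    expect_equal(sum(p) + attr(p, "outlier_mass"), 1, tolerance = 1e-10)
  })
  # all samples in one cell
  one <- assign_voronoi(matrix(rep(0, 10L), 5L, 2L), rbind(c(0, 0), c(5, 5)), 1)
  p1 <- cell_probabilities(rep(0.2, 5L), one)
  expect_equal(as.numeric(p1), c(1, 0))
})

test_that("ellipsoidal volumes track per-axis scatter products", {
  withr::with_seed(12, {
    # two well-separated clouds with per-axis sd (2,1) and (1,1)
    A <- cbind(rnorm(10000L, -20, 2), rnorm(10000L, 0, 1))
    B <- cbind(rnorm(10000L, 20, 1), rnorm(10000L, 0, 1))
    X <- rbind(A, B)
    Z <- rbind(c(-20, 0), c(20, 0))
    asg <- assign_voronoi(X, Z, cutoff = 50)
    V <- cell_volumes_ellipsoid(X, asg)
    expect_equal(V[1L] / V[2L], 2, tolerance = 0.1)
    # sigma_power = 2 squares the ratio
    V2 <- cell_volumes_ellipsoid(X, asg, sigma_power = 2)
    expect_equal(V2[1L] / V2[2L], 4, tolerance = 0.2)
    # full-covariance variant agrees for uncorrelated clouds
    Vf <- cell_volumes_ellipsoid(X, asg, full_covariance = TRUE)
    expect_equal(Vf[1L] / Vf[2L], V[1L] / V[2L], tolerance = 0.05)
    # symmetric split of one isotropic cloud: volume ratio 1
    C <- matrix(rnorm(20000L), 10000L, 2L)
    asgC <- assign_voronoi(C, rbind(c(-0.5, 0), c(0.5, 0)), cutoff = 10)
    VC <- cell_volumes_ellipsoid(C, asgC)
    expect_equal(VC[1L] / VC[2L], 1, tolerance = 0.1)
  })
  # single-sample cell falls back to the median volume with a warning
  X <- rbind(matrix(rnorm(400L), 200L, 2L), c(30, 30))
  Z <- rbind(c(0, 0), c(30, 30))
  asg <- assign_voronoi(X, Z, cutoff = 40)
  expect_warning(V <- cell_volumes_ellipsoid(X, asg), "fallback")
  expect_identical(attr(V, "fallback"), 2L)
  expect_identical(V[2L], V[1L])
})

test_that("the cell PMF obeys its closed forms and the volume decomposition", {
  # flat landscape
  flat <- pmf_along_path(rep(0.25, 4L), rep(1, 4L))
  expect_equal(flat$pmf, rep(0, 4L))
  # probability ratio 2:1 gives ln 2
  two <- pmf_along_path(c(2 / 3, 1 / 3), c(1, 1))
  expect_equal(two$pmf[2L] - two$pmf[1L], log(2), tolerance = 1e-12)
  # with and without volume correction differ by exactly -ln V per cell
  withr::with_seed(13, {
    p <- runif(8L); p <- p / sum(p)
    V <- runif(8L, 0.5, 2)
    corr <- pmf_along_path(p, V, shift_min = FALSE)
    raw <- pmf_along_path(p, NULL, shift_min = FALSE)
    expect_equal(corr$pmf - raw$pmf, log(V), tolerance = 1e-10)
    # after min-shifting the difference is -ln V plus one constant
    corr_s <- pmf_along_path(p, V)
    raw_s <- pmf_along_path(p, NULL)
    dd <- corr_s$pmf - raw_s$pmf - log(V)
    expect_lt(max(dd) - min(dd), 1e-10)
  })
  # zero-probability cells are absent, not imputed
  z <- pmf_along_path(c(0.5, 0, 0.5), c(1, 1, 1))
  expect_identical(z$absent, 2L)
  expect_true(is.na(z$pmf[2L]))
})

test_that("per-cell structure statistics match brute force and chi moments", {
  withr::with_seed(14, {
    # identical structures give zero fluctuation
    n <- 50L
    pos <- array(rep(matrix(1:12, 4L, 3L), each = n), c(n, 4L, 3L))
    asg <- assign_voronoi(matrix(0, n, 1L), matrix(0, 1L, 1L), 1)
    st <- cell_structure_stats(pos, rep(1 / n, n), asg)
    expect_equal(st$rmsf[1L, ], rep(0, 4L))
    # isotropic 3D Gaussian displacements: rmsf -> sigma * sqrt(3)
    sigma <- 0.7
    n2 <- 10000L
    pos2 <- array(rnorm(n2 * 4L * 3L, sd = sigma), c(n2, 4L, 3L))
    asg2 <- assign_voronoi(matrix(0, n2, 1L), matrix(0, 1L, 1L), 1)
    st2 <- cell_structure_stats(pos2, rep(1 / n2, n2), asg2)
    expect_lt(max(abs(st2$rmsf[1L, ] - sigma * sqrt(3)) / (sigma * sqrt(3))),
              0.05)
    # uniform weights equal the plain mean / sd oracle (matrix form)
    X <- matrix(rnorm(600L), 200L, 3L)
    asg3 <- assign_voronoi(X[, 1L, drop = FALSE], matrix(c(-1, 1), 2L), 5)
    st3 <- cell_structure_stats(X, rep(1 / 200, 200L), asg3)
    for (k in 1:2) {
      idx <- which(asg3$cell_index == k)
      expect_equal(st3$average[[k]], colMeans(X[idx, , drop = FALSE]),
                   tolerance = 1e-12)
      pop_sd <- sqrt(colMeans(sweep(X[idx, , drop = FALSE], 2L,
                                    colMeans(X[idx, , drop = FALSE]))^2))
      expect_equal(st3$rmsf[k, ], pop_sd, tolerance = 1e-12)
    }
  })
})

test_that("grid densities conserve counts and recover a known pdf", {
  # every sample puts one point into the same voxel
  pts <- matrix(rep(c(0.25, 0.25, 0.25), 6L), 6L, 3L, byrow = TRUE)
  asg <- assign_voronoi(matrix(0, 6L, 1L), matrix(0, 1L, 1L), 1)
  g <- grid_density(pts, rep(1 / 6, 6L), asg, origin = c(0, 0, 0),
                    spacing = 0.5, shape = c(2L, 2L, 2L))
  expect_equal(max(g$density[1L, ]), 1 / 0.125)
  expect_equal(sum(g$density[1L, ] > 0), 1L)
  # conservation: per-cell voxel sum times voxel volume = mean point count
  withr::with_seed(15, {
    sets <- lapply(1:40, function(i) matrix(runif(3 * sample(1:5, 1L)), ncol = 3L))
    w <- runif(40L); w <- w / sum(w)
    asg2 <- assign_voronoi(matrix(rnorm(40L), 40L, 1L),
                           matrix(c(-1, 1), 2L), 5)
    g2 <- grid_density(sets, w, asg2, origin = c(0, 0, 0), spacing = 0.25,
                       shape = c(4L, 4L, 4L))
    for (k in 1:2) {
      idx <- which(asg2$cell_index == k)
      expected <- sum(w[idx] * vapply(sets[idx], nrow, integer(1L))) /
        sum(w[idx])
      expect_equal(sum(g2$density[k, ]) * g2$voxel_volume, expected,
                   tolerance = 1e-12)
    }
    expect_identical(g2$out_of_grid, 0L)
  })
  # a known 3D Gaussian pdf is recovered on well-populated voxels
  withr::with_seed(16, {
    n <- 60000L
    pts3 <- matrix(rnorm(3 * n, sd = 0.5), n, 3L)
    asg3 <- assign_voronoi(matrix(0, n, 1L), matrix(0, 1L, 1L), 1)
    g3 <- grid_density(pts3, rep(1 / n, n), asg3, origin = rep(-1, 3L),
                       spacing = 0.25, shape = rep(8L, 3L))
    mids <- -1 + 0.25 * (seq_len(8L) - 0.5)
    centers <- as.matrix(expand.grid(mids, mids, mids))
    pdf <- apply(centers, 1L, function(m) prod(dnorm(m, 0, 0.5)))
    expected_count <- pdf * g3$voxel_volume * n
    sel <- expected_count >= 25
    rel <- abs(g3$density[1L, sel] - pdf[sel]) / pdf[sel]
    expect_lt(mean(rel), 0.1)
  })
})

test_that("binned projections follow the weighted histogram", {
  # all mass in one bin
  one <- projected_pmf(rep(0.5, 10L), rep(0.1, 10L), breaks = c(0, 1))
  expect_equal(one$pmf, 0)
  # 4:1 split gives ln 4
  v <- c(rep(0.25, 4L), 0.75)
  sp <- projected_pmf(v, rep(0.2, 5L), breaks = c(0, 0.5, 1))
  expect_equal(sp$pmf[2L] - sp$pmf[1L], log(4), tolerance = 1e-12)
  # 2D projection of the quartic double well puts its minima at +/-1
  sys <- make_standard_system("quartic_1d", list(h = 3))
  b <- sample_restrained(sys, n_steps = 30000L, step_size = 1e-3, seed = 19L)
  x <- b$positions[, 1L]
  w <- rep(1 / length(x), length(x))
  br <- seq(-1.6, 1.6, by = 0.2)
  p2 <- projected_pmf(cbind(x, x), w, breaks = list(br, br))
  idx <- which(p2$pmf == 0, arr.ind = TRUE)
  expect_true(all(abs(abs(p2$mids[[1L]][idx[, 1L]]) - 1) < 0.21))
  # empty bins are absent
  expect_true(anyNA(p2$pmf))
  expect_error(projected_pmf(x, w, breaks = c(1, 0)), "increasing")
})
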