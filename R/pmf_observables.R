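# Everything computed "along the path": Voronoi assignment of samples to
# string images with an outlier cutoff, cell probabilities, ellipsoidal
# cell-volume estimates, the volume-corrected PMF, per-cell average
# structures and fluctuations, reweighted grid densities, and binned PMF
# projections.

#' Assign samples to the Voronoi cells of the string images
#'
#' Each sample is assigned to its nearest image by Euclidean distance in CV
#' space (ties broken to the lowest image index); samples farther than
#' `cutoff` from every image are flagged as outliers and excluded from all
#' downstream per-cell sums.
#'
#' @param cv_values `N x M` matrix of sample CV values.
#' @param images a `StringPath` or plain `K x M` image matrix.
#' @param cutoff positive outlier radius in CV units.
#' @return a `VoronoiAssignment`: list with `cell_index` (`NA` for
#'   outliers), `cutoff`, `n_outliers`, `n_cells`, and `distance` (distance
#'   to the assigned/nearest image).
#' @export
assign_voronoi <- function(cv_values, images, cutoff) {
  Z <- if (inherits(images, "StringPath")) images$images else as.matrix(images)
  if (nrow(Z) == 0L) stop("empty image set", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  X <- as.matrix(cv_values)
  if (ncol(X) != ncol(Z)) stop("CV dimension mismatch", call. = FALSE)
  K <- nrow(Z)
  # squared distances sample x image, built column-wise
  D2 <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    D2[, k] <- rowSums(sweep(X, 2L, Z[k, ])^2)
  }
  nearest <- max.col(-D2, ties.method = "first")
  dmin <- sqrt(D2[cbind(seq_len(nrow(X)), nearest)])
  out <- dmin > cutoff
  cell <- nearest
  cell[out] <- NA_integer_
  structure(list(cell_index = cell, cutoff = cutoff,
                 n_outliers = sum(out), n_cells = K, distance = dmin),
            class = "VoronoiAssignment")
}

#' @export
print.VoronoiAssignment <- function(x, ...) {
  cat(sprintf("VoronoiAssignment: %d samples, %d cells, %d outliers (cutoff %g)\n",
              length(x$cell_index), x$n_cells, x$n_outliers, x$cutoff))
  invisible(x)
}

#' Reweighted cell probabilities
#'
#' `p_B = sum_n W_n * chi_B(n)` over the non-outlier samples.  Outlier mass
#' is excluded, not renormalized, so cell mass plus outlier mass equals 1.
#'
#' @param weights normalized per-sample equilibrium weights.
#' @param assignment a `VoronoiAssignment`.
#' @param n_cells number of cells (defaults to `assignment$n_cells`).
#' @return numeric vector of cell probabilities with attribute
#'   `"outlier_mass"`.
#' @export
cell_probabilities <- function(weights, assignment, n_cells = assignment$n_cells) {
  stopifnot(inherits(assignment, "VoronoiAssignment"))
  if (length(weights) != length(assignment$cell_index)) {
    stop("weights and assignment lengths differ", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must be normalized", call. = FALSE)
  p <- numeric(n_cells)
  ok <- !is.na(assignment$cell_index)
  tab <- rowsum(weights[ok], assignment$cell_index[ok])
  p[as.integer(rownames(tab))] <- tab[, 1L]
  attr(p, "outlier_mass") <- sum(weights[!ok])
  p
}

#' Ellipsoidal relative cell volumes
#'
#' Approximates each (cutoff-truncated) Voronoi cell by the ellipsoid of the
#' sample scatter: the relative volume of cell `B` is the product over CV
#' axes of the per-axis sample standard deviation (the common unit-ball
#' factor cancels between equal-dimensional cells).  `sigma_power = 2`
#' multiplies variances instead of standard deviations;
#' `full_covariance = TRUE` uses `sqrt(det(cov))`, which also captures
#' correlated scatter.  Cells with fewer than `min_samples` samples fall
#' back to the median volume of the well-populated cells, with a warning.
#'
#' @param cv_values `N x M` sample CV values.
#' @param assignment a `VoronoiAssignment`.
#' @param min_samples minimum samples for a direct estimate.
#' @param sigma_power 1 (standard deviations) or 2 (variances).
#' @param full_covariance use the full-covariance determinant instead of the
#'   per-axis (diagonal) product.
#' @return numeric vector of relative volumes, attribute `"fallback"` giving
#'   the indices of cells that used the median fallback.
#' @export
cell_volumes_ellipsoid <- function(cv_values, assignment, min_samples = 10L,
                                   sigma_power = 1, full_covariance = FALSE) {
  stopifnot(inherits(assignment, "VoronoiAssignment"))
  X <- as.matrix(cv_values)
  K <- assignment$n_cells
  if (!sigma_power %in% c(1, 2)) stop("sigma_power must be 1 or 2", call. = FALSE)
  V <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- which(!is.na(assignment$cell_index) & assignment$cell_index == k)
    if (length(idx) >= max(min_samples, 2L)) {
      Xi <- X[idx, , drop = FALSE]
      if (full_covariance) {
        dt <- det(cov(Xi))
        V[k] <- if (dt > 0) sqrt(dt)^sigma_power else NA_real_
      } else {
        V[k] <- prod(apply(Xi, 2L, sd)^sigma_power)
      }
    }
  }
  bad <- which(!is.finite(V) | V <= 0)
  if (length(bad)) {
    good <- V[is.finite(V) & V > 0]
    if (!length(good)) stop("no cell has enough samples for a volume estimate",
                            call. = FALSE)
    V[bad] <- median(good)
    warning(sprintf("%d cell(s) with fewer than %d samples: median-volume fallback (%s)",
                    length(bad), min_samples,
                    paste(bad, collapse = ", ")))
  }
  attr(V, "fallback") <- bad
  V
}

#' Potential of mean force over cells
#'
#' `pmf_B = -ln(p_B / V_B)` in kT units.  Passing `volumes = NULL` gives the
#' uncorrected profile (`V_B = 1`), exposed for sensitivity comparisons:
#' corrected and uncorrected profiles differ by exactly `-ln V_B` per cell
#' (before any shift).  Zero-probability cells are reported absent (`NA`),
#' never imputed.
#'
#' @param probabilities cell probabilities (from [cell_probabilities()]).
#' @param volumes relative cell volumes, or `NULL` for no correction.
#' @param uncertainties optional per-cell PMF uncertainties to carry along.
#' @param shift_min subtract the minimum so the lowest cell sits at 0
#'   (default); `FALSE` returns the raw `-ln(p/V)` values.
#' @return a `CellPMF`: list with `probabilities`, `volumes`, `pmf` (kT),
#'   `uncertainties`, `absent` (indices of zero-probability cells).
#' @export
pmf_along_path <- function(probabilities, volumes = NULL, uncertainties = NULL,
                           shift_min = TRUE) {
  p <- as.numeric(probabilities)
  n <- length(p)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (is.null(volumes)) volumes <- rep(1, n)
  if (length(volumes) != n) stop("volumes length mismatch", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  pmf <- ifelse(p > 0, -log(p / volumes), NA_real_)
  if (shift_min && any(is.finite(pmf))) pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(list(probabilities = p, volumes = volumes, pmf = pmf,
                 uncertainties = uncertainties,
                 absent = which(p == 0)),
            class = "CellPMF")
}

#' @export
print.CellPMF <- function(x, ...) {
  n <- length(x$pmf)
  cat(sprintf("CellPMF: %d cells (%d absent), range %.3g kT\n",
              n, length(x$absent),
              diff(range(x$pmf, na.rm = TRUE))))
  invisible(x)
}

#' Per-cell average structures and fluctuations
#'
#' Weight-normalized mean coordinates per cell, and the per-atom root-mean-
#' square fluctuation about that mean:
#' `rmsf_i(B) = sqrt( sum_{n in B} W_n ||x_{n,i} - xbar_i(B)||^2 /
#' sum_{n in B} W_n )`.
#'
#' @param positions samples: an `n x A x 3` array (structures) or an
#'   `n x d` matrix (each column treated as a one-dimensional "atom").
#' @param weights normalized per-sample weights.
#' @param assignment a `VoronoiAssignment`.
#' @return a `CellStructureStats`: list with `average` (list per cell, `NULL`
#'   for absent cells), `rmsf` (`n_cells x A` matrix, `NA` rows for absent
#'   cells), `cell_weight`, `absent`.
#' @export
cell_structure_stats <- function(positions, weights, assignment) {
  stopifnot(inherits(assignment, "VoronoiAssignment"))
  three_d <- is.array(positions) && length(dim(positions)) == 3L
  n <- if (three_d) dim(positions)[1L] else nrow(positions)
  A <- if (three_d) dim(positions)[2L] else ncol(positions)
  if (length(weights) != n || length(assignment$cell_index) != n) {
    stop("positions, weights and assignment sizes differ", call. = FALSE)
  }
  K <- assignment$n_cells
  avg <- vector("list", K)
  rmsf <- matrix(NA_real_, K, A)
  cw <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(!is.na(assignment$cell_index) & assignment$cell_index == k)
    if (!length(idx)) next
    w <- weights[idx]
    cw[k] <- sum(w)
    if (cw[k] <= 0) next
    wn <- w / cw[k]
    if (three_d) {
      sub <- positions[idx, , , drop = FALSE]
      m <- apply(sub * array(wn, dim(sub)), c(2L, 3L), sum)
      avg[[k]] <- m
      dev2 <- vapply(seq_len(A), function(i) {
        di <- sweep(matrix(sub[, i, ], ncol = 3L), 2L, m[i, ])
        sum(wn * rowSums(di^2))
      }, numeric(1L))
      rmsf[k, ] <- sqrt(dev2)
    } else {
      sub <- positions[idx, , drop = FALSE]
      m <- colSums(sub * wn)
      avg[[k]] <- m
      rmsf[k, ] <- sqrt(colSums(wn * sweep(sub, 2L, m)^2))
    }
  }
  structure(list(average = avg, rmsf = rmsf, cell_weight = cw,
                 absent = which(cw == 0)),
            class = "CellStructureStats")
}

#' Reweighted per-cell voxel densities
#'
#' For each sample, the instantaneous density on a regular lattice is the
#' voxel count divided by the voxel volume; the per-cell average is the
#' weight-normalized mean over the samples assigned to that cell.  Points
#' falling outside the lattice are counted and reported, never silently
#' dropped.
#'
#' @param point_sets list of per-sample point matrices (`m_n x D`), or a
#'   single `n x D` matrix (one point per sample).
#' @param weights normalized per-sample weights.
#' @param assignment a `VoronoiAssignment`.
#' @param origin lattice origin (length `D`).
#' @param spacing voxel edge length(s), positive.
#' @param shape integer voxel counts per axis (length `D`).
#' @return a `DensityGrid`: list with `origin`, `spacing`, `shape`,
#'   `voxel_volume`, `density` (`n_cells x n_voxels` matrix of averaged
#'   densities, voxels in array order), `cell_weight`, `out_of_grid`.
#' @export
grid_density <- function(point_sets, weights, assignment, origin, spacing,
                         shape) {
  stopifnot(inherits(assignment, "VoronoiAssignment"))
  D <- length(shape)
  spacing <- rep_len(spacing, D)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  origin <- rep_len(as.numeric(origin), D)
  shape <- as.integer(shape)
  if (is.matrix(point_sets)) {
    point_sets <- lapply(seq_len(nrow(point_sets)),
                         function(i) point_sets[i, , drop = FALSE])
  }
  n <- length(point_sets)
  if (length(weights) != n || length(assignment$cell_index) != n) {
    stop("point_sets, weights and assignment sizes differ", call. = FALSE)
  }
  nvox <- prod(shape)
  vvol <- prod(spacing)
  K <- assignment$n_cells
  acc <- matrix(0, K, nvox)
  cw <- numeric(K)
  out_count <- 0L
  mult <- c(1L, cumprod(shape)[-D])
  for (i in seq_len(n)) {
    k <- assignment$cell_index[i]
    if (is.na(k)) next
    P <- as.matrix(point_sets[[i]])
    ij <- floor(sweep(sweep(P, 2L, origin), 2L, spacing, "/"))
    inside <- rowSums(ij >= 0 & sweep(ij, 2L, shape, "<")) == D
    out_count <- out_count + sum(!inside)
    lin <- as.integer(ij[inside, , drop = FALSE] %*% mult) + 1L
    counts <- tabulate(lin, nbins = nvox)
    acc[k, ] <- acc[k, ] + weights[i] * counts / vvol
    cw[k] <- cw[k] + weights[i]
  }
  dens <- acc
  pos <- cw > 0
  dens[pos, ] <- acc[pos, , drop = FALSE] / cw[pos]
  dens[!pos, ] <- NA_real_
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 voxel_volume = vvol, density = dens, cell_weight = cw,
                 out_of_grid = out_count),
            class = "DensityGrid")
}

#' Binned PMF projection
#'
#' The negative log of the weighted histogram of one or two per-sample
#' observables (CV components, distances, any numeric column), shifted so
#' the minimum occupied bin is 0.  Empty bins are `NA` (absent), never 0.
#'
#' @param values numeric vector (1D) or two-column matrix (2D) of per-sample
#'   observables.
#' @param weights normalized per-sample weights.
#' @param breaks bin edges: a monotone numeric vector (1D) or a list of two
#'   such vectors (2D).
#' @return a `ProjectedPMF`: list with `breaks`, `mids`, `mass` (weighted
#'   histogram) and `pmf` (kT units); matrices in the 2D case.
#' @export
projected_pmf <- function(values, weights, breaks) {
  two_d <- !is.null(dim(values)) && ncol(as.matrix(values)) == 2L
  check_breaks <- function(b) {
    if (is.unsorted(b, strictly = TRUE)) {
      stop("breaks must be strictly increasing", call. = FALSE)
    }
    b
  }
  if (!two_d) {
    v <- as.numeric(values)
    b <- check_breaks(if (is.list(breaks)) breaks[[1L]] else breaks)
    nb <- length(b) - 1L
    idx <- findInterval(v, b, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx <= nb
    mass <- numeric(nb)
    tab <- rowsum(weights[ok], idx[ok])
    mass[as.integer(rownames(tab))] <- tab[, 1L]
    pmf <- ifelse(mass > 0, -log(mass), NA_real_)
    pmf <- pmf - min(pmf, na.rm = TRUE)
    structure(list(breaks = b, mids = (b[-1L] + b[-length(b)]) / 2,
                   mass = mass, pmf = pmf),
              class = "ProjectedPMF")
  } else {
    V <- as.matrix(values)
    stopifnot(is.list(breaks), length(breaks) == 2L)
    b1 <- check_breaks(breaks[[1L]]); b2 <- check_breaks(breaks[[2L]])
    n1 <- length(b1) - 1L; n2 <- length(b2) - 1L
    i1 <- findInterval(V[, 1L], b1, rightmost.closed = TRUE)
    i2 <- findInterval(V[, 2L], b2, rightmost.closed = TRUE)
    ok <- i1 >= 1L & i1 <= n1 & i2 >= 1L & i2 <= n2
    mass <- matrix(0, n1, n2)
    lin <- (i2[ok] - 1L) * n1 + i1[ok]
    tab <- rowsum(weights[ok], lin)
    mass[as.integer(rownames(tab))] <- tab[, 1L]
    pmf <- ifelse(mass > 0, -log(mass), NA_real_)
    pmf <- pmf - min(pmf, na.rm = TRUE)
    structure(list(breaks = list(b1, b2),
                   mids = list((b1[-1L] + b1[-length(b1)]) / 2,
                               (b2[-1L] + b2[-length(b2)]) / 2),
                   mass = mass, pmf = pmf),
              class = "ProjectedPMF")
  }
}
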