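# Linear collective-variable maps: Kabsch superposition, iterative average
# structures, combined-ensemble PCA, projection, and the subspace-convergence
# diagnostic.  Because the CV map is an orthonormal linear transform of the
# (superposed) coordinates, the metric tensor of the string formalism is the
# identity and all downstream modules may treat CV space as Euclidean.

#' Construct a structure ensemble
#'
#' @param coordinates numeric array `n_frames x n_atoms x 3`, or a single
#'   `n_atoms x 3` matrix (one frame).  Length units must be consistent
#'   across frames.
#' @param atom_labels optional character vector of atom labels.
#' @param source optional tag recording provenance.
#' @return a `StructureEnsemble`.
#' @export
structure_ensemble <- function(coordinates, atom_labels = NULL, source = NULL) {
  if (is.matrix(coordinates)) {
    coordinates <- array(coordinates, c(1L, nrow(coordinates), 3L))
  }
  stopifnot(is.array(coordinates), length(dim(coordinates)) == 3L,
            dim(coordinates)[3L] == 3L, dim(coordinates)[1L] >= 1L)
  n_atoms <- dim(coordinates)[2L]
  if (is.null(atom_labels)) atom_labels <- paste0("A", seq_len(n_atoms))
  if (length(atom_labels) != n_atoms) {
    stop("atom_labels length must equal the atom count", call. = FALSE)
  }
  structure(list(coordinates = coordinates, atom_labels = atom_labels,
                 source = source),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("StructureEnsemble: %d frames x %d atoms%s\n", d[1L], d[2L],
              if (is.null(x$source)) "" else paste0(" (", x$source, ")")))
  invisible(x)
}

.ens_frame <- function(ens, i) matrix(ens$coordinates[i, , ], ncol = 3L)
.flatten_frame <- function(m) as.vector(t(m))           # x1,y1,z1,x2,...
.unflatten_frame <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `mobile` onto `reference`.  Reflections are excluded by construction.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices.
#' @param weights optional nonnegative per-atom weights (default uniform).
#' @return list with `rotation` (3x3, acting on row vectors), `translation`
#'   (length 3), `rmsd`, and `superposed` (`mobile` after the transform:
#'   `sweep(mobile, 2, mobile_center) %*% rotation + reference_center`).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms for superposition", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  Mc <- sweep(mobile, 2L, cm); Rc <- sweep(reference, 2L, cr)
  H <- t(Mc * w) %*% Rc
  sv <- svd(H)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300)) {
    stop("degenerate geometry: atoms are (nearly) collinear", call. = FALSE)
  }
  s <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  sup <- Mc %*% R
  rmsd <- sqrt(sum(w * rowSums((sup - Rc)^2)))
  list(rotation = R, translation = cr - drop(cm %*% R), rmsd = rmsd,
       superposed = sweep(sup, 2L, cr, "+"))
}

#' Iterative average structure of an ensemble
#'
#' Alternates between superposing every frame onto the current average and
#' re-averaging, until the average moves by less than `tol` (RMSD) or
#' `max_iter` is reached.  This removes global rotation/translation before
#' any covariance analysis.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param weights optional per-atom superposition weights.
#' @param tol RMSD convergence tolerance for the average structure.
#' @param max_iter maximum iterations; non-convergence yields a warning and
#'   the last iterate.
#' @return list with `average` (`n_atoms x 3`), `ensemble` (superposed
#'   frames), `iterations`, `converged`.
#' @export
iterative_average_structure <- function(ensemble, weights = NULL,
                                        tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  n <- dim(ensemble$coordinates)[1L]
  A <- dim(ensemble$coordinates)[2L]
  avg <- .ens_frame(ensemble, 1L)
  sup <- ensemble$coordinates
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {
      sup[i, , ] <- kabsch_superpose(.ens_frame(ensemble, i), avg,
                                     weights)$superposed
    }
    new_avg <- apply(sup, c(2L, 3L), mean)
    delta <- sqrt(sum((new_avg - avg)^2) / A)
    avg <- new_avg
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("average structure not converged in %d iterations", max_iter))
  }
  out <- ensemble
  out$coordinates <- sup
  list(average = avg, ensemble = out, iterations = it, converged = converged)
}

#' Construct a collective-variable map
#'
#' @param modes `M x D` matrix with orthonormal rows (checked).
#' @param reference_mean length-`D` reference (subtracted before projection).
#' @param explained_variance optional nonincreasing nonnegative eigenvalues.
#' @param superpose logical: superpose structures onto the reference before
#'   projecting (`TRUE` for maps built from structure ensembles, `FALSE`
#'   for plain linear maps on model-system coordinates).
#' @param atom_labels optional labels carried along for structure maps.
#' @return a `CollectiveVariableMap`.
#' @export
cv_map <- function(modes, reference_mean, explained_variance = NULL,
                   superpose = FALSE, atom_labels = NULL) {
  modes <- as.matrix(modes)
  M <- nrow(modes)
  if (length(reference_mean) != ncol(modes)) {
    stop("reference_mean length must match mode columns", call. = FALSE)
  }
  G <- modes %*% t(modes)
  if (max(abs(G - diag(M))) > 1e-8) {
    stop("mode rows are not orthonormal", call. = FALSE)
  }
  if (!is.null(explained_variance)) {
    if (length(explained_variance) != M || any(explained_variance < -1e-12) ||
        is.unsorted(rev(explained_variance))) {
      stop("explained_variance must be M nonincreasing nonnegative values",
           call. = FALSE)
    }
  }
  structure(list(modes = modes, reference_mean = as.numeric(reference_mean),
                 M = M, explained_variance = explained_variance,
                 superpose = isTRUE(superpose), atom_labels = atom_labels),
            class = "CollectiveVariableMap")
}

#' Identity collective-variable map
#'
#' The degenerate map used with model systems, where the coordinates are the
#' collective variables.  Every downstream module accepts it.
#'
#' @param dimension ambient (and CV) dimension.
#' @return a `CollectiveVariableMap` with `modes = I`, zero reference.
#' @export
cv_map_identity <- function(dimension) {
  cv_map(diag(dimension), rep(0, dimension), superpose = FALSE)
}

#' @export
print.CollectiveVariableMap <- function(x, ...) {
  cat(sprintf("CollectiveVariableMap: %d modes in %d dimensions%s\n",
              x$M, ncol(x$modes),
              if (x$superpose) " (with superposition)" else ""))
  if (!is.null(x$explained_variance)) {
    cat("  explained variance:",
        paste(signif(head(x$explained_variance, 5L), 3L), collapse = ", "),
        if (x$M > 5L) "..." else "", "\n")
  }
  invisible(x)
}

#' Combined-ensemble principal component analysis
#'
#' Pools several structure ensembles (sharing atom ordering), removes rigid
#' body motion by iterative superposition onto the pooled average, and
#' diagonalizes the covariance of the flattened coordinates.  The leading
#' `M` eigenvectors become the collective variables.
#'
#' The leading mode of a two-state pool typically encodes the displacement
#' between the states; by default it is kept (the CV set must span that
#' displacement for path finding).  `drop_first = TRUE` instead discards it
#' and returns the next `M` modes, the convention used when bookkeeping
#' fluctuation variance only.
#'
#' @param ensembles a `StructureEnsemble` or list of them.
#' @param M number of principal components to keep.
#' @param drop_first drop the leading mode before selecting `M` modes.
#' @param weights,tol,max_iter passed to [iterative_average_structure()].
#' @return a `CollectiveVariableMap` with `superpose = TRUE`; mode signs are
#'   fixed so each mode's largest-magnitude component is positive.
#' @export
combined_pca <- function(ensembles, M, drop_first = FALSE, weights = NULL,
                         tol = 1e-6, max_iter = 100L) {
  if (inherits(ensembles, "StructureEnsemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L)
  counts <- vapply(ensembles, function(e) dim(e$coordinates)[2L], integer(1L))
  if (length(unique(counts)) != 1L) {
    stop("ensembles have mismatched atom counts", call. = FALSE)
  }
  A <- counts[1L]
  frames <- do.call(abind3, lapply(ensembles, `[[`, "coordinates"))
  pooled <- structure_ensemble(frames, ensembles[[1L]]$atom_labels, "pooled")
  n <- dim(frames)[1L]
  n_keep <- M + if (drop_first) 1L else 0L
  if (n <= n_keep) stop("need more frames than requested modes", call. = FALSE)
  if (n_keep > 3L * A) stop("M exceeds the ambient dimension", call. = FALSE)

  fit <- iterative_average_structure(pooled, weights, tol, max_iter)
  X <- t(vapply(seq_len(n),
                function(i) .flatten_frame(.ens_frame(fit$ensemble, i)),
                numeric(3L * A)))
  mu <- colMeans(X)
  C <- cov(X)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (n_keep > rank) {
    stop(sprintf("requested %d modes but covariance rank is %d", n_keep, rank),
         call. = FALSE)
  }
  sel <- if (drop_first) 2L:(M + 1L) else 1L:M
  modes <- t(eg$vectors[, sel, drop = FALSE])
  # reproducible sign convention
  for (j in seq_len(nrow(modes))) {
    i <- which.max(abs(modes[j, ]))
    if (modes[j, i] < 0) modes[j, ] <- -modes[j, ]
  }
  cv_map(modes, mu, explained_variance = ev[sel], superpose = TRUE,
         atom_labels = ensembles[[1L]]$atom_labels)
}

# bind ensembles along the frame axis
abind3 <- function(...) {
  parts <- list(...)
  d2 <- dim(parts[[1L]])[2L]
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1L],
                                      integer(1L))), d2, 3L))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1L]
    out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' Project configurations onto collective variables
#'
#' Computes `modes %*% (x - reference_mean)` for each configuration, after
#' optional rigid-body superposition onto the reference (for maps built from
#' structure ensembles).
#'
#' @param cvmap a `CollectiveVariableMap`.
#' @param coords a flattened configuration vector, a matrix of flattened
#'   configurations (one per row), or a `StructureEnsemble`.
#' @return CV vector, or matrix with one CV row per frame.
#' @export
project_cv <- function(cvmap, coords) {
  stopifnot(inherits(cvmap, "CollectiveVariableMap"))
  D <- ncol(cvmap$modes)
  if (inherits(coords, "StructureEnsemble")) {
    n <- dim(coords$coordinates)[1L]
    coords <- t(vapply(seq_len(n),
                       function(i) .flatten_frame(.ens_frame(coords, i)),
                       numeric(D)))
  }
  single <- is.null(dim(coords))
  X <- .coerce_rows(coords, D, "coords")
  if (cvmap$superpose) {
    refm <- .unflatten_frame(cvmap$reference_mean)
    X <- t(apply(X, 1L, function(v) {
      .flatten_frame(kabsch_superpose(.unflatten_frame(v), refm)$superposed)
    }))
  }
  out <- sweep(X, 2L, cvmap$reference_mean, "-") %*% t(cvmap$modes)
  if (single) drop(out) else out
}

#' Embed CV values back into configuration space
#'
#' Right-inverse of [project_cv()] on the CV subspace:
#' `reference_mean + t(modes) %*% z`.  Projecting the result returns `z`
#' exactly (orthonormal modes).
#'
#' @param cvmap a `CollectiveVariableMap`.
#' @param z CV vector or matrix of CV rows.
#' @return configuration vector or matrix of configuration rows.
#' @export
embed_cv <- function(cvmap, z) {
  stopifnot(inherits(cvmap, "CollectiveVariableMap"))
  single <- is.null(dim(z))
  Z <- .coerce_rows(z, cvmap$M, "z")
  out <- sweep(Z %*% cvmap$modes, 2L, cvmap$reference_mean, "+")
  if (single) drop(out) else out
}

#' Sum of canonical correlations between two CV subspaces
#'
#' The sum of singular values of `modesA %*% t(modesB)`, a number in
#' `[0, M]`: `M` for identical subspaces, 0 for mutually orthogonal ones.
#' Used as a convergence diagnostic for PCA subspaces estimated from
#' different halves of a trajectory.
#'
#' @param mapA,mapB `CollectiveVariableMap`s over the same ambient space.
#' @return the canonical-correlation sum.
#' @export
canonical_correlation_sum <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "CollectiveVariableMap"),
            inherits(mapB, "CollectiveVariableMap"))
  if (ncol(mapA$modes) != ncol(mapB$modes)) {
    stop("ambient dimensions differ", call. = FALSE)
  }
  sum(svd(mapA$modes %*% t(mapB$modes))$d)
}
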