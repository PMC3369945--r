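# On-the-fly string method: a discretized curve of images in CV space is
# relaxed toward the minimum free energy path.  Each image carries a
# persistent restrained walker; the image drifts along the smoothed
# restraint force while an equal-arc-length reparametrization keeps the
# images equidistant and the endpoints fixed.

#' Construct a string path
#'
#' @param images `N x M` matrix of CV-space images, ordered reactant to
#'   product (`N >= 3`).
#' @param endpoint_fixed logical pair; fixed endpoints are never moved by
#'   any update or reparametrization.
#' @return a `StringPath` with `images`, `endpoint_fixed`, and
#'   `arc_parameter` (normalized cumulative arc length in `[0, 1]`).
#' @export
string_path <- function(images, endpoint_fixed = c(TRUE, TRUE)) {
  images <- as.matrix(images)
  if (nrow(images) < 3L) stop("a string needs at least 3 images", call. = FALSE)
  if (!all(is.finite(images))) stop("images must be finite", call. = FALSE)
  seg <- sqrt(rowSums((images[-1L, , drop = FALSE] -
                         images[-nrow(images), , drop = FALSE])^2))
  tot <- sum(seg)
  arc <- if (tot > 0) c(0, cumsum(seg)) / tot else seq(0, 1, length.out = nrow(images))
  structure(list(images = images,
                 endpoint_fixed = rep_len(as.logical(endpoint_fixed), 2L),
                 arc_parameter = arc),
            class = "StringPath")
}

#' @export
print.StringPath <- function(x, ...) {
  cat(sprintf("StringPath: %d images in %d CVs (endpoints fixed: %s, %s)\n",
              nrow(x$images), ncol(x$images),
              x$endpoint_fixed[1L], x$endpoint_fixed[2L]))
  invisible(x)
}

#' Straight-line initial path
#'
#' `N` images equally spaced on the segment from `start_cv` to `end_cv`.
#'
#' @param start_cv,end_cv CV vectors of the two endpoint states.
#' @param N number of images (`>= 3`).
#' @return a `StringPath`.
#' @export
linear_interpolation_path <- function(start_cv, end_cv, N) {
  start_cv <- as.numeric(start_cv); end_cv <- as.numeric(end_cv)
  stopifnot(length(start_cv) == length(end_cv))
  if (N < 3L) stop("N must be >= 3", call. = FALSE)
  if (all(start_cv == end_cv)) stop("start and end coincide", call. = FALSE)
  tt <- seq(0, 1, length.out = N)
  string_path(outer(1 - tt, start_cv) + outer(tt, end_cv))
}

# equal-arc-length redistribution of images along their own polyline;
# iterated because redistributing along the polyline changes the chord
# lengths slightly on curved paths.
.reparam_once <- function(Z) {
  N <- nrow(Z)
  seg <- sqrt(rowSums((Z[-1L, , drop = FALSE] - Z[-N, , drop = FALSE])^2))
  L <- c(0, cumsum(seg))
  tot <- L[N]
  if (tot <= 0) stop("degenerate path: zero total arc length", call. = FALSE)
  target <- seq(0, tot, length.out = N)
  out <- Z
  for (j in 2L:(N - 1L)) {
    i <- findInterval(target[j], L, rightmost.closed = TRUE)
    i <- min(max(i, 1L), N - 1L)
    w <- if (seg[i] > 0) (target[j] - L[i]) / seg[i] else 0
    out[j, ] <- Z[i, ] + w * (Z[i + 1L, ] - Z[i, ])
  }
  out
}

#' Equal-arc-length reparametrization
#'
#' Redistributes the images along the piecewise-linear curve through them so
#' that adjacent-image distances are equal (relative spread below `tol`);
#' endpoints are bit-identical to the input.  The redistribution is iterated
#' to a fixed point because a single arc-length pass leaves small chord-length
#' imbalances on curved paths.
#'
#' @param path a `StringPath` (or plain image matrix).
#' @param tol relative tolerance on the adjacent-distance spread.
#' @param max_iter maximum redistribution passes.
#' @return a `StringPath` with equalized spacing.
#' @export
reparametrize <- function(path, tol = 1e-8, max_iter = 100L) {
  Z <- if (inherits(path, "StringPath")) path$images else as.matrix(path)
  ef <- if (inherits(path, "StringPath")) path$endpoint_fixed else c(TRUE, TRUE)
  N <- nrow(Z)
  if (N < 3L) stop("a string needs at least 3 images", call. = FALSE)
  for (it in seq_len(max_iter)) {
    seg <- sqrt(rowSums((Z[-1L, , drop = FALSE] - Z[-N, , drop = FALSE])^2))
    if (mean(seg) <= 0) stop("degenerate path: zero total arc length", call. = FALSE)
    if ((max(seg) - min(seg)) / mean(seg) < tol) break
    Z <- .reparam_once(Z)
  }
  string_path(Z, ef)
}

#' String evolution configuration
#'
#' Collects the parameters of [evolve_string()].  The image drift per update
#' is `(z_step / friction) * spring * (theta_bar - z)`, i.e. an explicit
#' Euler step on the string equation of motion; `friction` slows the string
#' relative to the walkers.  Defaults are stability-oriented choices for the
#' bundled model potentials, exposed rather than hard-wired.
#'
#' @param spring restraint stiffness kappa tying each walker to its image
#'   (energy per CV-unit squared).
#' @param friction string friction gamma; larger values slow the images.
#' @param z_step time step of the string update.
#' @param step_size time step of the walker integrator.
#' @param x_steps_per_z_update walker steps between consecutive image
#'   updates; the restraint force is averaged over this batch when
#'   `force_mode = "batch_mean"` (batch size 1 with `"instantaneous"`
#'   recovers the strict on-the-fly limit).
#' @param reparam_interval reparametrize every this many updates.
#' @param total_updates number of image updates.
#' @param snapshot_stride record a snapshot every this many updates.
#' @param convergence_tol if positive, stop early when the RMSD between
#'   snapshots `convergence_window` apart falls below this value.
#' @param convergence_window snapshot separation for the stopping rule.
#' @param force_mode `"batch_mean"` or `"instantaneous"`.
#' @param seed integer seed for the walkers.
#' @return a `StringConfig`.
#' @export
string_config <- function(spring = 100, friction = 100, z_step = 0.01,
                          step_size = 1e-4, x_steps_per_z_update = 10L,
                          reparam_interval = 1L, total_updates = 500L,
                          snapshot_stride = max(1L, total_updates %/% 50L),
                          convergence_tol = 0, convergence_window = 5L,
                          force_mode = c("batch_mean", "instantaneous"),
                          seed = 1L) {
  force_mode <- match.arg(force_mode)
  vals <- c(spring = spring, friction = friction, z_step = z_step,
            step_size = step_size, x_steps_per_z_update = x_steps_per_z_update,
            reparam_interval = reparam_interval, total_updates = total_updates,
            snapshot_stride = snapshot_stride)
  bad <- names(vals)[vals <= 0]
  if (length(bad)) {
    stop("string_config fields must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(spring = spring, friction = friction, z_step = z_step,
                 step_size = step_size,
                 x_steps_per_z_update = as.integer(x_steps_per_z_update),
                 reparam_interval = as.integer(reparam_interval),
                 total_updates = as.integer(total_updates),
                 snapshot_stride = as.integer(snapshot_stride),
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 force_mode = force_mode, seed = as.integer(seed)),
            class = "StringConfig")
}

#' Relaxed initial path by dragged restrained sampling
#'
#' Emulates a targeted-dynamics stage: a single walker is dragged along the
#' straight interpolation, restrained to each image in turn, and the relaxed
#' image is the mean CV of the post-equilibration segment.  Endpoints are
#' pinned to the input endpoints exactly.  With `steps_per_image = 0` the
#' interpolation is returned unchanged.
#'
#' @param system a `ModelSystem`.
#' @param cvmap a `CollectiveVariableMap` or `NULL` (identity).
#' @param interpolation a `StringPath` (typically from
#'   [linear_interpolation_path()]).
#' @param spring restraint stiffness of the drag.
#' @param steps_per_image walker steps spent restrained to each image.
#' @param equilibration_steps leading steps per image excluded from the mean.
#' @param seed integer seed.
#' @return a `StringPath` of relaxed images.
#' @export
targeted_initial_path <- function(system, cvmap = NULL, interpolation, spring,
                                  steps_per_image, equilibration_steps = 0L,
                                  seed = 1L) {
  stopifnot(inherits(interpolation, "StringPath"))
  if (steps_per_image == 0L) return(interpolation)
  if (spring <= 0) stop("spring must be positive", call. = FALSE)
  if (equilibration_steps >= steps_per_image) {
    stop("equilibration_steps must be below steps_per_image", call. = FALSE)
  }
  Z <- interpolation$images
  N <- nrow(Z)
  if (is.null(cvmap)) cvmap <- cv_map_identity(system$dimension)
  relaxed <- Z
  x <- drop(embed_cv(cvmap, Z[1L, ]))
  step_size <- 0.25 / (spring + 1)  # conservative for the restraint stiffness
  for (alpha in seq_len(N)) {
    b <- sample_restrained(system, cvmap, center = Z[alpha, ], spring = spring,
                           n_steps = steps_per_image, step_size = step_size,
                           seed = derive_seed(seed, alpha), x0 = x)
    x <- b$positions[nrow(b$positions), ]
    keep <- b$positions[(equilibration_steps + 1L):nrow(b$positions), ,
                        drop = FALSE]
    relaxed[alpha, ] <- colMeans(project_cv(cvmap, keep))
  }
  if (interpolation$endpoint_fixed[1L]) relaxed[1L, ] <- Z[1L, ]
  if (interpolation$endpoint_fixed[2L]) relaxed[N, ] <- Z[N, ]
  string_path(relaxed, interpolation$endpoint_fixed)
}

#' Evolve a string toward the minimum free energy path
#'
#' On-the-fly scheme: each image keeps a persistent restrained walker.  Per
#' update, every walker advances `x_steps_per_z_update` integration steps
#' under its image's restraint; the image then drifts by
#' `(z_step / friction) * spring * (theta - z)` with `theta` the walker's
#' batch-mean (or instantaneous) CV, which for stiff restraints estimates
#' the negative free-energy gradient.  Images are redistributed to equal arc
#' length every `reparam_interval` updates; fixed endpoints never move.
#' Snapshots (always recorded after reparametrization) and per-update mean
#' restraint-force norms are returned.  Fully reproducible under a fixed
#' seed.
#'
#' @param system a `ModelSystem`.
#' @param cvmap a `CollectiveVariableMap` or `NULL` (identity).
#' @param initial a `StringPath`.
#' @param config a `StringConfig`.
#' @return a `StringTrajectory`: list with `times` (update indices),
#'   `paths` (list of `StringPath` snapshots, the first at time 0),
#'   `force_norms`, `converged`, `config`.
#' @export
evolve_string <- function(system, cvmap = NULL, initial, config) {
  stopifnot(inherits(system, "ModelSystem"), inherits(initial, "StringPath"),
            inherits(config, "StringConfig"))
  if (is.null(cvmap)) cvmap <- cv_map_identity(system$dimension)
  initial <- reparametrize(initial)   # enforce the equal-spacing invariant
  Z <- initial$images
  N <- nrow(Z); M <- ncol(Z)
  if (M != cvmap$M) stop("path and CV map dimensions differ", call. = FALSE)
  ef <- initial$endpoint_fixed
  z0 <- Z[1L, ]; zN <- Z[N, ]
  eta <- config$z_step * config$spring / config$friction
  X <- embed_cv(cvmap, Z)
  times <- 0L
  paths <- list(string_path(Z, ef))
  force_norms <- numeric(config$total_updates)
  converged <- FALSE

  with_rng_seed(config$seed, {
    for (u in seq_len(config$total_updates)) {
      st <- .em_batch(system, cvmap, X, centers = Z, spring = config$spring,
                      n_steps = config$x_steps_per_z_update,
                      step_size = config$step_size,
                      accumulate_cv = (config$force_mode == "batch_mean"),
                      label = "image")
      X <- st$X
      theta <- if (config$force_mode == "batch_mean") st$cv_mean else st$cv_last
      force <- config$spring * (theta - Z)
      if (!all(is.finite(force))) {
        stop(sprintf("NaN in string force at update %d", u), call. = FALSE)
      }
      interior <- 2L:(N - 1L)
      force_norms[u] <- mean(sqrt(rowSums(force[interior, , drop = FALSE]^2)))
      Z <- Z + (eta / config$spring) * force
      if (ef[1L]) Z[1L, ] <- z0
      if (ef[2L]) Z[N, ] <- zN
      record <- (u %% config$snapshot_stride == 0L) || u == config$total_updates
      if (u %% config$reparam_interval == 0L) {
        # one redistribution pass per update: enough to hold the spacing
        # near-equal without the corner-cutting of a full equalization
        Z <- .reparam_once(Z)
      }
      if (record) {
        Z <- reparametrize(string_path(Z, ef))$images
        if (ef[1L]) Z[1L, ] <- z0
        if (ef[2L]) Z[N, ] <- zN
      }
      if (record) {
        times <- c(times, u)
        paths[[length(paths) + 1L]] <- string_path(Z, ef)
        nw <- config$convergence_window
        if (config$convergence_tol > 0 && length(paths) > nw) {
          r <- string_rmsd(paths[[length(paths)]], paths[[length(paths) - nw]])
          if (r < config$convergence_tol) { converged <- TRUE; break }
        }
      }
    }
  })
  structure(list(times = times, paths = paths,
                 force_norms = force_norms[seq_len(max(times))],
                 converged = converged, config = config, initial = initial),
            class = "StringTrajectory")
}

#' @export
print.StringTrajectory <- function(x, ...) {
  cat(sprintf("StringTrajectory: %d snapshots over %d updates (converged: %s)\n",
              length(x$paths), max(x$times), x$converged))
  invisible(x)
}

#' RMSD between two strings
#'
#' `sqrt( sum_alpha ||z_alpha_A - z_alpha_B||^2 / (N M) )`: the per-degree-
#' of-freedom root-mean-square displacement between two strings with the
#' same discretization.
#'
#' @param a,b `StringPath`s (or image matrices) of identical shape.
#' @return the RMSD in CV units.
#' @export
string_rmsd <- function(a, b) {
  A <- if (inherits(a, "StringPath")) a$images else as.matrix(a)
  B <- if (inherits(b, "StringPath")) b$images else as.matrix(b)
  stopifnot(all(dim(A) == dim(B)))
  sqrt(mean((A - B)^2))
}

#' String displacement from the initial path over time
#'
#' @param trajectory a `StringTrajectory`.
#' @return data frame with `time` and `rmsd` (the [string_rmsd()] of each
#'   snapshot from the time-0 path); `rmsd[1]` is 0.
#' @export
string_rmsd_from_initial <- function(trajectory) {
  stopifnot(inherits(trajectory, "StringTrajectory"))
  ref <- trajectory$paths[[1L]]
  data.frame(
    time = trajectory$times,
    rmsd = vapply(trajectory$paths, string_rmsd, numeric(1L), b = ref))
}
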