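# Committor diagnostics.  The "lite" test launches unbiased trajectories
# from umbrella samples of a candidate barrier cell and bins the endpoints
# by nearest string image: at a transition state the endpoint distribution
# splits roughly evenly to the two sides.  The full estimator integrates
# until first passage into explicit basin regions.

#' Committor-lite transition-state test
#'
#' Draws initial configurations from the umbrella-sample pool restricted to
#' `start_cell` (without replacement until the pool is exhausted, then with
#' replacement), runs unbiased trajectories of `n_steps`, Voronoi-assigns
#' the endpoints with the same cutoff machinery as the PMF layer (endpoints
#' beyond the cutoff are counted as unassigned, never dropped), and reports
#' the endpoint histogram together with the split of committed endpoints to
#' the two sides of the start cell.
#'
#' @param system a `ModelSystem`.
#' @param cvmap a `CollectiveVariableMap` or `NULL` (identity).
#' @param path the `StringPath` defining the cells.
#' @param start_cell image index of the launch cell.
#' @param n_traj number of trajectories.
#' @param n_steps unbiased integration steps per trajectory (0 keeps the
#'   initial configurations).
#' @param sample_pool a `SampleSet` holding positions (e.g. from
#'   [run_umbrella_windows()]).
#' @param seed integer seed (drawing and dynamics).
#' @param cutoff Voronoi outlier radius for initial and final assignment.
#' @param step_size integration time step.
#' @return a `CommittorResult`: list with `start_cell`, `final_cell` (`NA`
#'   for unassigned endpoints), `histogram` (counts per cell plus
#'   `unassigned`; sums to `n_traj`), `fractions` (`lower`, `upper`, `same`,
#'   `unassigned`), `upper_fraction` of committed (lower+upper) endpoints
#'   with its 95% binomial confidence interval, `median_shift` (signed
#'   median of `final - start` cell index), `n_traj`, `n_steps`, `seed`.
#' @export
committor_lite <- function(system, cvmap = NULL, path, start_cell, n_traj,
                           n_steps, sample_pool, seed = 1L, cutoff,
                           step_size = 1e-3) {
  stopifnot(inherits(system, "ModelSystem"), inherits(path, "StringPath"),
            inherits(sample_pool, "SampleSet"))
  if (n_traj < 1L) stop("n_traj must be >= 1", call. = FALSE)
  if (is.null(sample_pool$positions)) {
    stop("sample_pool carries no positions", call. = FALSE)
  }
  if (is.null(cvmap)) cvmap <- cv_map_identity(system$dimension)
  K <- nrow(path$images)
  if (start_cell < 1L || start_cell > K) stop("start_cell out of range", call. = FALSE)
  pool_assign <- assign_voronoi(sample_pool$cv_values, path, cutoff)
  idx <- which(!is.na(pool_assign$cell_index) &
                 pool_assign$cell_index == start_cell)
  if (!length(idx)) {
    stop(sprintf("no pool samples assigned to cell %d", start_cell), call. = FALSE)
  }
  # without replacement until the pool is exhausted, then fresh permutations
  draw <- with_rng_seed(derive_seed(seed, 0L), {
    reps <- ceiling(n_traj / length(idx))
    sel <- unlist(lapply(seq_len(reps), function(r) {
      if (length(idx) == 1L) idx else sample(idx)
    }))
    sel[seq_len(n_traj)]
  })
  X <- sample_pool$positions[draw, , drop = FALSE]
  if (n_steps > 0L) {
    X <- with_rng_seed(derive_seed(seed, 1L), {
      .em_batch(system, cvmap, X, centers = NULL, spring = 0,
                n_steps = n_steps, step_size = step_size,
                label = "trajectory")$X
    })
  }
  cv_end <- project_cv(cvmap, X)
  final_assign <- assign_voronoi(cv_end, path, cutoff)
  fc <- final_assign$cell_index
  hist_counts <- c(tabulate(fc[!is.na(fc)], nbins = K),
                   unassigned = sum(is.na(fc)))
  names(hist_counts)[seq_len(K)] <- as.character(seq_len(K))
  lower <- sum(fc < start_cell, na.rm = TRUE)
  upper <- sum(fc > start_cell, na.rm = TRUE)
  same <- sum(fc == start_cell, na.rm = TRUE)
  committed <- lower + upper
  ci <- if (committed > 0) binom.test(upper, committed)$conf.int else c(NA, NA)
  structure(list(
    start_cell = start_cell, final_cell = fc, histogram = hist_counts,
    fractions = c(lower = lower, upper = upper, same = same,
                  unassigned = sum(is.na(fc))) / n_traj,
    upper_fraction = if (committed > 0) upper / committed else NA_real_,
    upper_ci = as.numeric(ci),
    median_shift = median(fc - start_cell, na.rm = TRUE),
    n_traj = as.integer(n_traj), n_steps = as.integer(n_steps),
    seed = as.integer(seed), cutoff = cutoff),
    class = "CommittorResult")
}

#' @export
print.CommittorResult <- function(x, ...) {
  cat(sprintf("CommittorResult: %d trajectories from cell %d\n",
              x$n_traj, x$start_cell))
  cat(sprintf("  lower / same / upper / unassigned: %.2f / %.2f / %.2f / %.2f\n",
              x$fractions["lower"], x$fractions["same"], x$fractions["upper"],
              x$fractions["unassigned"]))
  if (is.finite(x$upper_fraction)) {
    cat(sprintf("  upper fraction of committed: %.3f (95%% CI %.3f-%.3f)\n",
                x$upper_fraction, x$upper_ci[1L], x$upper_ci[2L]))
  }
  invisible(x)
}

#' First-passage committor estimate between two basins
#'
#' Runs unbiased trajectories from a single starting configuration and
#' reports the fraction that enters the product basin before the reactant
#' basin.  Basins are caller-supplied predicates on configurations; they
#' must be disjoint and must not contain the starting point.  Trajectories
#' exceeding `max_steps` without committing are counted separately, never
#' folded into either fraction.
#'
#' @param system a `ModelSystem`.
#' @param start_point starting configuration.
#' @param basin_reactant,basin_product vectorized predicates: functions
#'   taking an `n x d` matrix of configurations and returning `n` logicals.
#' @param n_traj number of trajectories.
#' @param max_steps step budget per trajectory.
#' @param seed integer seed.
#' @param step_size integration time step.
#' @return list with `p_commit_product`, `ci` (95% binomial interval),
#'   `n_product`, `n_reactant`, `n_timeout`, `n_traj`, `seed`.
#' @export
committor_estimate <- function(system, start_point, basin_reactant,
                               basin_product, n_traj, max_steps, seed = 1L,
                               step_size = 1e-3) {
  stopifnot(inherits(system, "ModelSystem"))
  x0 <- matrix(as.numeric(start_point), 1L)
  inR <- basin_reactant(x0); inP <- basin_product(x0)
  if (inR && inP) stop("basins overlap at the starting point", call. = FALSE)
  if (inR || inP) stop("start_point lies inside a basin", call. = FALSE)
  d <- system$dimension
  n <- as.integer(n_traj)
  X <- matrix(rep(as.numeric(start_point), each = n), n, d)
  state <- integer(n)                      # 0 active, 1 reactant, 2 product
  inv_m <- 1 / system$masses
  noise_sd <- sqrt(2 * system$kT * step_size * inv_m)
  with_rng_seed(seed, {
    for (t in seq_len(max_steps)) {
      act <- state == 0L
      if (!any(act)) break
      G <- system$gradient(X[act, , drop = FALSE])
      X[act, ] <- X[act, , drop = FALSE] -
        step_size * sweep(G, 2L, inv_m, "*") +
        matrix(rnorm(sum(act) * d), ncol = d) %*% diag(noise_sd, d, d)
      if (!all(is.finite(X[act, ]))) {
        stop(sprintf("integration diverged at step %d", t), call. = FALSE)
      }
      sub <- X[act, , drop = FALSE]
      r <- basin_reactant(sub); p <- basin_product(sub)
      if (any(r & p)) stop("basins overlap", call. = FALSE)
      st <- integer(nrow(sub)); st[r] <- 1L; st[p] <- 2L
      state[act] <- st
    }
  })
  nR <- sum(state == 1L); nP <- sum(state == 2L); nT <- sum(state == 0L)
  committed <- nR + nP
  ci <- if (committed > 0) as.numeric(binom.test(nP, committed)$conf.int)
        else c(NA_real_, NA_real_)
  list(p_commit_product = if (committed > 0) nP / committed else NA_real_,
       ci = ci, n_product = nP, n_reactant = nR, n_timeout = nT,
       n_traj = n, seed = as.integer(seed))
}
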