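# Umbrella sampling around string images and the MBAR estimator.  All
# potentials are stored in reduced (dimensionless) form, pre-divided by kT;
# the free energies f_k are dimensionless with the gauge f_1 = 0.

#' Construct a pooled umbrella sample set
#'
#' @param cv_values `N_total x M` CV values of the pooled samples.
#' @param reduced_potentials `K x N_total` matrix: row `k` is the reduced
#'   potential of umbrella state `k` evaluated at every pooled sample
#'   (dimensionless, i.e. energy over kT).
#' @param counts integer vector of per-state sample counts `N_k`
#'   (post-subsampling); must sum to `N_total`.
#' @param window_index integer state of origin of each pooled sample.
#' @param positions optional raw configurations (`N_total x d`).
#' @param u_unbiased optional reduced potential of the unrestrained system at
#'   each sample (needed for equilibrium reweighting).
#' @param inefficiencies optional per-state statistical inefficiencies.
#' @param windows optional metadata list (centers, spring, seeds, kT).
#' @return a `SampleSet`.
#' @export
sample_set <- function(cv_values, reduced_potentials, counts, window_index,
                       positions = NULL, u_unbiased = NULL,
                       inefficiencies = NULL, windows = NULL) {
  cv_values <- as.matrix(cv_values)
  reduced_potentials <- as.matrix(reduced_potentials)
  N <- nrow(cv_values)
  K <- nrow(reduced_potentials)
  if (ncol(reduced_potentials) != N) {
    stop("reduced_potentials must have one column per pooled sample", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (length(counts) != K || any(counts < 0) || !any(counts > 0)) {
    stop("counts must be K nonnegative integers with at least one positive",
         call. = FALSE)
  }
  if (sum(counts) != N) stop("counts must sum to the pooled sample count", call. = FALSE)
  if (!all(is.finite(reduced_potentials))) {
    stop("reduced potentials must be finite", call. = FALSE)
  }
  if (length(window_index) != N) stop("window_index length mismatch", call. = FALSE)
  structure(list(cv_values = cv_values, reduced_potentials = reduced_potentials,
                 counts = counts, window_index = as.integer(window_index),
                 positions = positions, u_unbiased = u_unbiased,
                 inefficiencies = inefficiencies, windows = windows),
            class = "SampleSet")
}

#' @export
print.SampleSet <- function(x, ...) {
  cat(sprintf("SampleSet: %d pooled samples from %d umbrella states\n",
              nrow(x$cv_values), length(x$counts)))
  if (!is.null(x$inefficiencies)) {
    cat(sprintf("  statistical inefficiency: median %.2f, max %.2f\n",
                median(x$inefficiencies), max(x$inefficiencies)))
  }
  invisible(x)
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum_t (1 - t/n) C(t)` with `C(t)` the normalized
#' autocorrelation function, summed up to the first nonpositive value.
#' `ceiling(g)` is the subsampling stride that renders the retained samples
#' effectively independent.  A constant series carries no correlation
#' information and returns 1 with a warning.
#'
#' @param series numeric vector, length >= 4.
#' @return the statistical inefficiency `g >= 1`.
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 4L) stop("series must have length >= 4", call. = FALSE)
  x <- series - mean(series)
  v <- mean(x^2)
  if (v == 0) {
    warning("constant series: returning statistical inefficiency 1")
    return(1)
  }
  # autocovariance via FFT (zero-padded to avoid circular wrap)
  m <- 2L^ceiling(log2(2L * n))
  ft <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(Mod(ft)^2, inverse = TRUE))[seq_len(n)] / m
  C <- ac / ac[1L]
  g <- 1
  for (t in seq_len(n - 1L)) {
    if (C[t + 1L] <= 0) break
    g <- g + 2 * (1 - t / n) * C[t + 1L]
  }
  max(g, 1)
}

#' Umbrella sampling around every image of a string
#'
#' Runs one restrained sampling window per string image (seeded
#' independently and deterministically from `seed`), discards the
#' equilibration segment, optionally subsamples each window by the
#' statistical inefficiency of its potential-energy series, pools the
#' windows, and assembles the `K x N_total` reduced-potential matrix
#' `u_k(x_n) = U(x_n)/kT + spring/(2 kT) * ||theta(x_n) - c_k||^2`.
#'
#' @param system a `ModelSystem`.
#' @param cvmap a `CollectiveVariableMap` or `NULL` (identity).
#' @param path a `StringPath`; each image is an umbrella center.
#' @param spring umbrella stiffness (energy per CV-unit squared), `> 0`.
#' @param n_steps integration steps per window.
#' @param equilibration leading steps discarded per window.
#' @param step_size walker time step.
#' @param seed master seed.
#' @param subsample logical; subsample by the potential-energy
#'   autocorrelation (the default) or keep every post-equilibration sample.
#' @param subsample_signal `"energy"` (default) or `"cv"`: series used for
#'   the inefficiency estimate (first CV component for `"cv"`).
#' @return a `SampleSet` with positions, CV values, reduced potentials,
#'   per-window counts and inefficiencies, and window metadata.
#' @export
run_umbrella_windows <- function(system, cvmap = NULL, path, spring, n_steps,
                                 equilibration = 0L, step_size = 1e-3,
                                 seed = 1L, subsample = TRUE,
                                 subsample_signal = c("energy", "cv")) {
  stopifnot(inherits(system, "ModelSystem"), inherits(path, "StringPath"))
  subsample_signal <- match.arg(subsample_signal)
  if (spring <= 0) stop("spring must be positive", call. = FALSE)
  if (n_steps <= equilibration) {
    stop("n_steps must exceed equilibration", call. = FALSE)
  }
  if (is.null(cvmap)) cvmap <- cv_map_identity(system$dimension)
  Z <- path$images
  K <- nrow(Z)
  kT <- system$kT
  pos_list <- vector("list", K)
  en_list <- vector("list", K)
  g <- numeric(K)
  seeds <- integer(K)
  for (k in seq_len(K)) {
    seeds[k] <- derive_seed(seed, k)
    b <- tryCatch(
      sample_restrained(system, cvmap, center = Z[k, ], spring = spring,
                        n_steps = n_steps, step_size = step_size,
                        seed = seeds[k]),
      error = function(e) {
        stop(sprintf("window %d: %s", k, conditionMessage(e)), call. = FALSE)
      })
    keep <- (equilibration + 1L):n_steps
    P <- b$positions[keep, , drop = FALSE]
    E <- b$energies[keep]
    if (subsample) {
      series <- if (subsample_signal == "energy") E
                else project_cv(cvmap, P)[, 1L]
      g[k] <- statistical_inefficiency(series)
      idx <- seq(1L, nrow(P), by = as.integer(ceiling(g[k])))
      P <- P[idx, , drop = FALSE]
      E <- E[idx]
    } else {
      g[k] <- 1
    }
    pos_list[[k]] <- P
    en_list[[k]] <- E
  }
  positions <- do.call(rbind, pos_list)
  energies <- unlist(en_list)
  counts <- vapply(pos_list, nrow, integer(1L))
  window_index <- rep(seq_len(K), counts)
  cvs <- project_cv(cvmap, positions)
  u0 <- energies / kT
  U <- matrix(NA_real_, K, nrow(positions))
  for (k in seq_len(K)) {
    d2 <- rowSums(sweep(cvs, 2L, Z[k, ])^2)
    U[k, ] <- u0 + spring / (2 * kT) * d2
  }
  sample_set(cv_values = cvs, reduced_potentials = U, counts = counts,
             window_index = window_index, positions = positions,
             u_unbiased = u0, inefficiencies = g,
             windows = list(centers = Z, spring = spring, kT = kT,
                            seeds = seeds, step_size = step_size,
                            equilibration = equilibration))
}

# log(sum(exp(v))) guarded against overflow
.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# column-wise logsumexp of (f_k + logN_k - u_kn); returns length-N vector.
# The column maximum is computed by a pmax reduction over the K rows, which
# is far faster than apply() for the K << N matrices seen here.
.log_denominator <- function(u, f, logN) {
  S <- (f + logN) - u
  m <- S[1L, ]
  K <- nrow(S)
  if (K > 1L) for (k in 2L:K) m <- pmax(m, S[k, ])
  m[!is.finite(m)] <- 0          # all-(-Inf) columns cannot occur (counts > 0)
  m + log(colSums(exp(S - rep(m, each = K))))
}

# the convex MBAR objective whose stationary point is the solution
.mbar_objective <- function(u, f, logN, counts) {
  sum(.log_denominator(u, f, logN)) - sum(counts * f)
}

#' Solve the MBAR equations
#'
#' Finds the dimensionless free energies `f_k` of `K` umbrella states that
#' satisfy the MBAR self-consistency equations for the pooled samples, with
#' the gauge `f_1 = 0`.  All evaluations use log-sum-exp so reduced
#' potentials up to about +/-700 are handled without overflow.  Solvers:
#' `"self_consistent"` iteration, damped `"newton"` (Newton-Raphson on the
#' convex MBAR objective), or the default `"hybrid"` (self-consistent warm
#' start, then Newton).  States with zero samples are valid perturbation
#' targets: they receive free energies but do not enter the denominator.
#'
#' @param samples a `SampleSet`.
#' @param tol convergence tolerance on the maximum self-consistency
#'   residual `|1 - sum_n W_kn|`.
#' @param max_iter maximum iterations.
#' @param solver `"hybrid"`, `"self_consistent"` or `"newton"`.
#' @param compute_uncertainty also compute the asymptotic covariance of
#'   free-energy differences (see [mbar_uncertainty()]).
#' @return an `MBARResult`: list with `free_energies` (`f`, `f[1] = 0`),
#'   `log_denominator` (per-sample normalization, reused for reweighting),
#'   `weights` (equilibrium weights when the sample set carries
#'   `u_unbiased`), `residual`, `iterations`, `converged`, `counts`, and
#'   `covariance` (variance matrix of `f_i - f_j`) when requested.
#' @export
solve_mbar <- function(samples, tol = 1e-8, max_iter = 10000L,
                       solver = c("hybrid", "newton", "self_consistent"),
                       compute_uncertainty = TRUE) {
  stopifnot(inherits(samples, "SampleSet"))
  solver <- match.arg(solver)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  u <- samples$reduced_potentials
  counts <- samples$counts
  K <- nrow(u)
  active <- counts > 0L
  logN <- ifelse(active, log(counts), -Inf)
  f <- numeric(K)

  residual_of <- function(f) {
    ld <- .log_denominator(u, f, logN)
    W <- exp((f - u) - rep(ld, each = K))                # K x N
    r <- rowSums(W)
    list(ld = ld, W = W, resid = max(abs(r[active] - 1)), rowsum = r)
  }

  sc_update <- function(f) {
    ld <- .log_denominator(u, f, logN)
    S <- -u - rep(ld, each = K)
    fn <- -apply(S, 1L, .logsumexp)
    fn - fn[1L]
  }

  newton_step <- function(f) {
    st <- residual_of(f)
    W <- st$W
    r <- st$rowsum
    grad <- counts * (r - 1)
    H <- diag(counts * r, K, K) - outer(counts, counts) * (W %*% t(W))
    idx <- which(active)[-1L]           # gauge: f of the first active state
    if (!length(idx)) return(f)
    delta <- numeric(K)
    step <- tryCatch(solve(H[idx, idx, drop = FALSE], -grad[idx]),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    delta[idx] <- step
    obj0 <- .mbar_objective(u, f, logN, counts)
    lam <- 1
    for (half in 1:20) {
      fn <- f + lam * delta
      if (.mbar_objective(u, fn, logN, counts) < obj0 + 1e-13) {
        return(fn - fn[1L])
      }
      lam <- lam / 2
    }
    NULL
  }

  if (K > 1L && sum(active) > 1L) {
    comp <- .overlap_components(u[active, , drop = FALSE], counts[active])
    if (comp$n_components > 1L) {
      lab <- lapply(comp$members, function(m) which(active)[m])
      stop(sprintf(paste0("umbrella states form %d disconnected overlap ",
                          "components: %s"), comp$n_components,
                   paste(vapply(lab, paste, character(1L), collapse = ","),
                         collapse = " | ")),
           call. = FALSE)
    }
  }
  if (K == 1L) {
    res <- residual_of(f)
    out <- list(f = f, ld = res$ld, resid = res$resid, it = 1L, conv = TRUE)
  } else {
    it <- 0L
    resid <- Inf
    mode <- if (solver == "newton") "newton" else "sc"
    sc_budget <- if (solver == "self_consistent") max_iter else
      if (solver == "hybrid") 20L else 0L
    repeat {
      it <- it + 1L
      if (mode == "sc") {
        f <- sc_update(f)
        if (solver == "hybrid" && it >= sc_budget) mode <- "newton"
      } else {
        fn <- newton_step(f)
        if (is.null(fn)) { mode <- "sc"; f <- sc_update(f) } else f <- fn
      }
      resid <- residual_of(f)$resid
      if (resid < tol || it >= max_iter) break
    }
    if (resid >= tol) {
      comp <- .overlap_components(u, counts)
      if (comp$n_components > 1L) {
        stop(sprintf(paste0("MBAR did not converge (residual %.3g): the ",
                            "umbrella states form %d disconnected overlap ",
                            "components: %s"), resid, comp$n_components,
                     paste(vapply(comp$members, paste, character(1L),
                                  collapse = ","), collapse = " | ")),
             call. = FALSE)
      }
      stop(sprintf("MBAR did not converge in %d iterations (residual %.3g)",
                   it, resid), call. = FALSE)
    }
    res <- residual_of(f)
    out <- list(f = f, ld = res$ld, resid = res$resid, it = it, conv = TRUE)
  }

  # perturbation free energies for zero-count states
  if (any(!active)) {
    for (k in which(!active)) {
      out$f[k] <- -.logsumexp(-u[k, ] - out$ld)
    }
  }
  weights <- NULL
  if (!is.null(samples$u_unbiased)) {
    lw <- -samples$u_unbiased - out$ld
    weights <- exp(lw - .logsumexp(lw))
  }
  result <- structure(
    list(free_energies = out$f - out$f[1L], log_denominator = out$ld,
         weights = weights, residual = out$resid, iterations = out$it,
         converged = out$conv, counts = counts, solver = solver,
         covariance = NULL),
    class = "MBARResult")
  if (compute_uncertainty) {
    result$covariance <- mbar_uncertainty(result, samples)$var_diff
  }
  result
}

# connected components of the pairwise-overlap graph, used for error
# reporting when the solve fails: two states overlap when some sample has a
# non-negligible Boltzmann factor in both.
.overlap_components <- function(u, counts, thresh = 30) {
  K <- nrow(u)
  umin <- apply(u, 2L, min)
  close <- sweep(u, 2L, umin, "-") < thresh       # K x N
  adj <- close %*% t(close) > 0
  comp <- rep(0L, K)
  cid <- 0L
  for (k in seq_len(K)) {
    if (comp[k] > 0L) next
    cid <- cid + 1L
    queue <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  list(n_components = cid,
       members = split(seq_len(K), comp))
}

#' @export
print.MBARResult <- function(x, ...) {
  K <- length(x$free_energies)
  cat(sprintf("MBARResult: %d states, residual %.2e after %d iterations\n",
              K, x$residual, x$iterations))
  show <- head(seq_len(K), 8L)
  cat("  f:", paste(signif(x$free_energies[show], 4L), collapse = ", "),
      if (K > 8L) "..." else "", "\n")
  invisible(x)
}

#' Per-sample equilibrium weights from a converged MBAR result
#'
#' `W_n` proportional to `exp(-u_target(x_n)) / sum_k N_k exp(f_k - u_k(x_n))`,
#' normalized to sum to 1.  The default target is the unrestrained reduced
#' potential stored in the sample set.
#'
#' @param result a converged `MBARResult`.
#' @param samples the `SampleSet` the result was computed from.
#' @param u_target optional reduced potential of the target state at every
#'   pooled sample; defaults to `samples$u_unbiased`.
#' @return numeric vector of normalized weights.
#' @export
mbar_weights <- function(result, samples, u_target = NULL) {
  stopifnot(inherits(result, "MBARResult"), inherits(samples, "SampleSet"))
  if (!isTRUE(result$converged)) stop("MBAR result is not converged", call. = FALSE)
  if (is.null(u_target)) u_target <- samples$u_unbiased
  if (is.null(u_target)) {
    stop("no target potential: supply u_target or a sample set with u_unbiased",
         call. = FALSE)
  }
  lw <- -u_target - result$log_denominator
  w <- exp(lw - .logsumexp(lw))
  w / sum(w)
}

#' Weighted expectation with standard error
#'
#' Weighted mean of a per-sample observable under normalized weights, with a
#' standard error from the weighted variance: `se^2 = sum_n W_n^2 (a_n -
#' abar)^2`, which reduces to `var(a)/n` for uniform weights and accounts
#' for the effective sample size otherwise.
#'
#' @param weights normalized per-sample weights.
#' @param observable numeric vector of the same length.
#' @return list with `estimate`, `se`, and `ess` (effective sample size
#'   `1 / sum W_n^2`).
#' @export
mbar_expectation <- function(weights, observable) {
  stopifnot(length(weights) == length(observable))
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must be normalized", call. = FALSE)
  }
  est <- sum(weights * observable)
  se <- sqrt(sum(weights^2 * (observable - est)^2))
  list(estimate = est, se = se, ess = 1 / sum(weights^2))
}

#' Asymptotic uncertainty of MBAR free-energy differences
#'
#' Large-sample covariance of the estimated free energies from the weight
#' matrix `W_nk = exp(f_k - u_kn) / sum_j N_j exp(f_j - u_jn)`: with the
#' thin SVD `W = U S V'`, `Theta = V S (I - S V' N V S)^+ S V'` and
#' `var(f_i - f_j) = Theta_ii + Theta_jj - 2 Theta_ij`.  Only `W'W` (a
#' `K x K` matrix) is ever formed.
#'
#' @param result a converged `MBARResult`.
#' @param samples the `SampleSet` it came from.
#' @return list with `theta` (`K x K`) and `var_diff` (`K x K` matrix of
#'   variances of `f_i - f_j`; the diagonal is 0).
#' @export
mbar_uncertainty <- function(result, samples) {
  stopifnot(inherits(result, "MBARResult"), inherits(samples, "SampleSet"))
  u <- samples$reduced_potentials
  K <- nrow(u)
  f <- result$free_energies
  Wk <- exp(sweep(sweep(-u, 2L, result$log_denominator, "-"), 1L, f, "+"))
  WtW <- Wk %*% t(Wk)                       # = t(W) %*% W for W (N x K)
  eg <- eigen(WtW, symmetric = TRUE)
  s2 <- pmax(eg$values, 0)
  S <- sqrt(s2)
  V <- eg$vectors
  Nd <- samples$counts
  SVt <- S * t(V)                            # S V', rows scaled by S
  Minner <- diag(K) - SVt %*% (Nd * V) %*% diag(S, K, K)
  # pseudo-inverse
  sv <- svd(Minner)
  tolr <- max(sv$d) * 1e-10
  dinv <- ifelse(sv$d > tolr, 1 / sv$d, 0)
  Mpinv <- sv$v %*% (dinv * t(sv$u))
  theta <- t(SVt) %*% Mpinv %*% SVt
  vd <- outer(diag(theta), diag(theta), "+") - 2 * theta
  vd <- pmax(vd, 0)
  diag(vd) <- 0
  list(theta = theta, var_diff = vd)
}
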