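# End-to-end driver: initial path -> string -> umbrella -> MBAR -> PMF ->
# committor, with checkpointed artifacts and a manifest.  Stages are skipped
# when their artifacts are present and were produced under the same resolved
# configuration; deleting an intermediate artifact recomputes that stage and
# everything downstream.

.stage_order <- c("string", "umbrella", "mbar", "pmf", "committor")

.manifest_path <- function(outdir) file.path(outdir, "manifest.json")

.read_manifest <- function(outdir) {
  mp <- .manifest_path(outdir)
  if (!file.exists(mp)) return(NULL)
  jsonlite::read_json(mp, simplifyVector = FALSE)
}

.artifacts_intact <- function(stage_rec, outdir) {
  if (is.null(stage_rec) || !identical(stage_rec$status, "done")) return(FALSE)
  for (nm in names(stage_rec$artifacts)) {
    f <- file.path(outdir, nm)
    if (!file.exists(f)) return(FALSE)
    if (!identical(unname(tools::md5sum(f)), stage_rec$artifacts[[nm]])) {
      return(FALSE)
    }
  }
  TRUE
}

.record_stage <- function(manifest, stage, files, outdir, seed, elapsed) {
  art <- lapply(files, function(f) unname(tools::md5sum(file.path(outdir, f))))
  names(art) <- files
  manifest$stages[[stage]] <- list(status = "done", artifacts = art,
                                   seed = seed, elapsed_s = round(elapsed, 3L))
  manifest
}

#' Run the full MFEP pipeline
#'
#' Executes the stages of a resolved configuration in order — initial-path
#' construction, string evolution, umbrella sampling around the converged
#' string, MBAR solve, Voronoi PMF (with the automatic volume-correction
#' robustness re-run at 1.17 times the cutoff), and optionally the
#' committor-lite test — writing plain-text artifacts plus a JSON manifest
#' into the output directory.  Re-running with an unchanged configuration
#' recomputes nothing; deleting an intermediate artifact recomputes it and
#' all downstream stages.  Every stochastic stage derives its seed from the
#' master seed, so reruns are bit-identical.
#'
#' @param config a `RunConfig` from [validate_config()], or a path/list
#'   accepted by it.
#' @param quiet suppress progress messages.
#' @return the manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  chash <- attr(config, "config_hash")
  say <- function(...) if (!quiet) message(sprintf(...))

  old <- .read_manifest(outdir)
  manifest <- list(config_hash = chash, stages = list())
  reuse_ok <- !is.null(old) && identical(old$config_hash, chash)

  write_resolved_config(config, file.path(outdir, "config_resolved.yaml"))

  system <- make_standard_system(config$system$name, config$system$params)
  cvmap <- cv_map_identity(system$dimension)
  ep <- config$string$endpoints
  if (identical(ep, "minima")) {
    if (is.null(system$minima) || nrow(system$minima) < 2L) {
      stop("system has no pair of documented minima for 'endpoints: minima'",
           call. = FALSE)
    }
    start_cv <- drop(project_cv(cvmap, system$minima[1L, ]))
    end_cv <- drop(project_cv(cvmap, system$minima[nrow(system$minima), ]))
  } else {
    start_cv <- as.numeric(unlist(ep[[1L]]))
    end_cv <- as.numeric(unlist(ep[[2L]]))
  }
  initial <- linear_interpolation_path(start_cv, end_cv, config$string$n_images)

  dirty <- FALSE  # once a stage recomputes, everything downstream does too
  stage_needed <- function(stage, files) {
    if (dirty || !reuse_ok) return(TRUE)
    !(.artifacts_intact(old$stages[[stage]], outdir) &&
        all(file.exists(file.path(outdir, files))))
  }

  ## --- string stage ------------------------------------------------------
  string_files <- c("path_initial.tsv", "path_initial.json",
                    "path_final.tsv", "path_final.json", "string_rmsd.tsv")
  string_seed <- derive_seed(config$seed, 101L)
  if (stage_needed("string", string_files)) {
    dirty <- TRUE
    say("stage string: evolving %d images", config$string$n_images)
    t0 <- proc.time()[3L]
    scfg <- string_config(
      spring = config$string$spring, friction = config$string$friction,
      z_step = config$string$z_step, step_size = config$string$step_size,
      x_steps_per_z_update = config$string$x_steps_per_z_update,
      total_updates = config$string$total_updates,
      snapshot_stride = config$string$snapshot_stride,
      convergence_tol = config$string$convergence_tol,
      force_mode = config$string$force_mode, seed = string_seed)
    traj <- evolve_string(system, cvmap, initial, scfg)
    final <- traj$paths[[length(traj$paths)]]
    write_string_path(initial, file.path(outdir, "path_initial.tsv"))
    write_string_path(final, file.path(outdir, "path_final.tsv"))
    write.table(string_rmsd_from_initial(traj),
                file.path(outdir, "string_rmsd.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .record_stage(manifest, "string", string_files, outdir,
                              string_seed, proc.time()[3L] - t0)
  } else {
    say("stage string: up to date, skipping")
    final <- read_string_path(file.path(outdir, "path_final.tsv"))
    manifest$stages$string <- old$stages$string
  }

  ## --- umbrella stage ----------------------------------------------------
  umb_files <- c("samples.tsv", "samples.json")
  umb_seed <- derive_seed(config$seed, 202L)
  if (stage_needed("umbrella", umb_files)) {
    dirty <- TRUE
    say("stage umbrella: %d windows x %d steps",
        nrow(final$images), config$umbrella$n_steps)
    t0 <- proc.time()[3L]
    samples <- run_umbrella_windows(
      system, cvmap, final, spring = config$umbrella$spring,
      n_steps = config$umbrella$n_steps,
      equilibration = config$umbrella$equilibration,
      step_size = config$umbrella$step_size, seed = umb_seed,
      subsample = isTRUE(config$umbrella$subsample))
    write_sample_set(samples, file.path(outdir, "samples.tsv"))
    manifest <- .record_stage(manifest, "umbrella", umb_files, outdir,
                              umb_seed, proc.time()[3L] - t0)
  } else {
    say("stage umbrella: up to date, skipping")
    samples <- read_sample_set(file.path(outdir, "samples.tsv"))
    manifest$stages$umbrella <- old$stages$umbrella
  }

  ## --- mbar stage --------------------------------------------------------
  mbar_files <- "mbar.json"
  if (stage_needed("mbar", mbar_files)) {
    dirty <- TRUE
    say("stage mbar: solving %d states", length(samples$counts))
    t0 <- proc.time()[3L]
    mbar <- solve_mbar(samples, tol = config$mbar$tol,
                       max_iter = config$mbar$max_iter,
                       solver = config$mbar$solver)
    jsonlite::write_json(
      list(free_energies = mbar$free_energies, residual = mbar$residual,
           iterations = mbar$iterations,
           se_vs_first = sqrt(mbar$covariance[, 1L])),
      file.path(outdir, "mbar.json"), auto_unbox = TRUE, digits = NA)
    weights <- mbar$weights
    manifest <- .record_stage(manifest, "mbar", mbar_files, outdir,
                              NA, proc.time()[3L] - t0)
  } else {
    say("stage mbar: up to date, skipping")
    weights <- NULL  # resolved lazily if a downstream stage needs it
    manifest$stages$mbar <- old$stages$mbar
  }

  ## --- pmf stage ---------------------------------------------------------
  pmf_files <- c("pmf.tsv", "pmf_meta.json")
  if (stage_needed("pmf", pmf_files)) {
    dirty <- TRUE
    say("stage pmf: Voronoi PMF over %d cells", nrow(final$images))
    t0 <- proc.time()[3L]
    if (is.null(weights)) {
      weights <- solve_mbar(samples, tol = config$mbar$tol,
                            max_iter = config$mbar$max_iter,
                            solver = config$mbar$solver,
                            compute_uncertainty = FALSE)$weights
    }
    cutoff <- config$voronoi$cutoff
    assign <- assign_voronoi(samples$cv_values, final, cutoff)
    p <- cell_probabilities(weights, assign)
    vols <- suppressWarnings(cell_volumes_ellipsoid(
      samples$cv_values, assign, min_samples = config$voronoi$min_samples,
      sigma_power = config$voronoi$sigma_power))
    pmf <- pmf_along_path(p, vols)
    pmf_raw <- pmf_along_path(p, NULL)
    # robustness re-run at 1.17x cutoff
    assign2 <- assign_voronoi(samples$cv_values, final, 1.17 * cutoff)
    p2 <- cell_probabilities(weights, assign2)
    vols2 <- suppressWarnings(cell_volumes_ellipsoid(
      samples$cv_values, assign2, min_samples = config$voronoi$min_samples,
      sigma_power = config$voronoi$sigma_power))
    pmf2 <- pmf_along_path(p2, vols2)
    max_change <- max(abs(pmf$pmf - pmf2$pmf), na.rm = TRUE)
    write_cell_pmf(pmf, file.path(outdir, "pmf.tsv"),
                   extra = list(pmf_uncorrected_kT = pmf_raw$pmf))
    jsonlite::write_json(
      list(cutoff = cutoff, n_outliers = assign$n_outliers,
           outlier_mass = attr(p, "outlier_mass"),
           robustness_cutoff = 1.17 * cutoff,
           robustness_max_pmf_change_kT = max_change),
      file.path(outdir, "pmf_meta.json"), auto_unbox = TRUE, digits = NA)
    manifest <- .record_stage(manifest, "pmf", pmf_files, outdir,
                              NA, proc.time()[3L] - t0)
  } else {
    say("stage pmf: up to date, skipping")
    manifest$stages$pmf <- old$stages$pmf
  }

  ## --- committor stage ---------------------------------------------------
  if (isTRUE(config$committor$enabled)) {
    com_files <- "committor.json"
    com_seed <- derive_seed(config$seed, 303L)
    if (stage_needed("committor", com_files)) {
      dirty <- TRUE
      start_cell <- config$committor$start_cell
      if (identical(start_cell, "middle")) {
        start_cell <- (nrow(final$images) + 1L) %/% 2L
      }
      say("stage committor: %d trajectories from cell %d",
          config$committor$n_traj, start_cell)
      t0 <- proc.time()[3L]
      com <- committor_lite(system, cvmap, final, start_cell,
                            n_traj = config$committor$n_traj,
                            n_steps = config$committor$n_steps,
                            sample_pool = samples, seed = com_seed,
                            cutoff = config$voronoi$cutoff,
                            step_size = config$committor$step_size)
      jsonlite::write_json(
        com[c("start_cell", "histogram", "fractions", "upper_fraction",
              "upper_ci", "median_shift", "n_traj", "n_steps", "seed")],
        file.path(outdir, "committor.json"), auto_unbox = TRUE, digits = NA)
      manifest <- .record_stage(manifest, "committor", com_files, outdir,
                                com_seed, proc.time()[3L] - t0)
    } else {
      say("stage committor: up to date, skipping")
      manifest$stages$committor <- old$stages$committor
    }
  }

  jsonlite::write_json(manifest, .manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
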