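# Run configuration: a YAML/JSON file validated into a fully-resolved
# RunConfig before any compute.  Defaults are applied recursively and the
# provenance of every defaulted field is recorded so a resolved config can
# be re-emitted and revalidated identically.

.config_defaults <- function() list(
  seed = 1L,
  outdir = "mfepath_run",
  system = list(name = "mueller_brown", params = list()),
  cv = list(type = "identity"),
  string = list(n_images = 25L, endpoints = "minima", spring = 2500,
                friction = 1, z_step = 4e-5, step_size = 2e-5,
                x_steps_per_z_update = 20L, total_updates = 3000L,
                snapshot_stride = 100L, convergence_tol = 0,
                force_mode = "batch_mean"),
  umbrella = list(spring = 200, n_steps = 3000L, equilibration = 500L,
                  step_size = 1e-4, subsample = TRUE),
  mbar = list(tol = 1e-8, max_iter = 10000L, solver = "hybrid"),
  voronoi = list(cutoff = NULL, min_samples = 10L, sigma_power = 1),
  committor = list(enabled = FALSE, start_cell = "middle", n_traj = 100L,
                   n_steps = 2000L, step_size = 1e-4)
)

.leaf_paths <- function(x, prefix) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    unlist(lapply(names(x), function(nm) {
      .leaf_paths(x[[nm]], paste0(prefix, ".", nm))
    }))
  } else {
    prefix
  }
}

.merge_defaults <- function(user, defaults, prefix = "") {
  applied <- character(0)
  for (nm in names(defaults)) {
    path <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
      applied <- c(applied, .leaf_paths(defaults[[nm]], path))
    } else if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
               !is.null(names(defaults[[nm]]))) {
      sub <- .merge_defaults(user[[nm]], defaults[[nm]], path)
      user[[nm]] <- sub$value
      applied <- c(applied, sub$applied)
    }
  }
  list(value = user, applied = applied)
}

.check_positive <- function(cfg, fields) {
  for (f in fields) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1L]]
    v <- cfg
    for (p in parts) v <- v[[p]]
    if (is.null(v) || !is.numeric(v) || any(v <= 0)) {
      stop(sprintf("config field '%s' must be positive", f), call. = FALSE)
    }
  }
}

#' Validate and resolve a run configuration
#'
#' Parses a YAML or JSON file (or accepts an already-parsed list), applies
#' defaults recursively, validates types and ranges before any compute, and
#' returns the fully-resolved configuration.  The `voronoi.cutoff` field
#' has no default: the outlier radius is a property of the CV space and
#' must be stated.
#'
#' @param path config file path, or a named list.
#' @return a `RunConfig`: the resolved configuration with attributes
#'   `defaults_applied` (field paths that were filled in) and `config_hash`.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                                 call. = FALSE)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  merged <- .merge_defaults(raw, .config_defaults())
  cfg <- merged$value

  if (!cfg$system$name %in% c("mueller_brown", "double_well_nd",
                              "harmonic_nd", "quartic_1d")) {
    stop(sprintf("config field 'system.name': unknown system '%s'",
                 cfg$system$name), call. = FALSE)
  }
  if (!identical(cfg$cv$type, "identity")) {
    stop("config field 'cv.type': only 'identity' is supported for model systems",
         call. = FALSE)
  }
  .check_positive(cfg, c("string.n_images", "string.spring", "string.friction",
                         "string.z_step", "string.step_size",
                         "string.x_steps_per_z_update", "string.total_updates",
                         "umbrella.spring", "umbrella.n_steps",
                         "umbrella.step_size", "mbar.tol",
                         "committor.n_traj", "committor.step_size"))
  if (cfg$string$n_images < 3L) {
    stop("config field 'string.n_images' must be >= 3", call. = FALSE)
  }
  if (is.null(cfg$voronoi$cutoff) || !is.numeric(cfg$voronoi$cutoff) ||
      cfg$voronoi$cutoff <= 0) {
    stop("config field 'voronoi.cutoff' must be a positive number", call. = FALSE)
  }
  if (cfg$umbrella$equilibration >= cfg$umbrella$n_steps) {
    stop("config field 'umbrella.equilibration' must be below umbrella.n_steps",
         call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("config field 'seed' must be a single integer", call. = FALSE)
  }
  if (!(identical(cfg$string$endpoints, "minima") ||
        (is.list(cfg$string$endpoints) && length(cfg$string$endpoints) == 2L) ||
        (is.matrix(cfg$string$endpoints) && nrow(cfg$string$endpoints) == 2L))) {
    stop("config field 'string.endpoints' must be \"minima\" or two CV vectors",
         call. = FALSE)
  }
  structure(cfg, class = "RunConfig",
            defaults_applied = merged$applied,
            config_hash = .config_hash(cfg))
}

.config_hash <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Emit a resolved configuration
#'
#' Writes the resolved config as YAML; re-validating the emitted file yields
#' an identical configuration (and hash).
#'
#' @param config a `RunConfig`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_resolved_config <- function(config, file) {
  stopifnot(inherits(config, "RunConfig"))
  x <- unclass(config)
  attributes(x) <- attributes(x)["names"]
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat(sprintf("RunConfig: system '%s', %d string images, seed %d\n",
              x$system$name, x$string$n_images, as.integer(x$seed)))
  da <- attr(x, "defaults_applied")
  cat(sprintf("  %d defaulted field(s); hash %s\n", length(da),
              substr(attr(x, "config_hash"), 1L, 8L)))
  invisible(x)
}
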