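# Plain-text artifact formats.  Every tabular artifact is a TSV with a
# one-line header naming columns; metadata travels in a JSON sidecar next to
# the table.  The formats are deliberately diff-able so pipeline runs can be
# compared file-by-file.

.sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a string path to disk
#'
#' TSV of images (one row per image, columns `cv1..cvM`) plus a JSON sidecar
#' with endpoint flags and arc parameters.
#'
#' @param path a `StringPath`.
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
write_string_path <- function(path, file) {
  stopifnot(inherits(path, "StringPath"))
  df <- as.data.frame(path$images)
  names(df) <- paste0("cv", seq_len(ncol(path$images)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "StringPath", n_images = nrow(path$images),
         n_cv = ncol(path$images), endpoint_fixed = path$endpoint_fixed,
         arc_parameter = path$arc_parameter),
    .sidecar(file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a string path written by [write_string_path()]
#' @param file TSV path.
#' @return a `StringPath`.
#' @export
read_string_path <- function(file) {
  meta <- jsonlite::read_json(.sidecar(file), simplifyVector = TRUE)
  img <- as.matrix(read.table(file, header = TRUE, sep = "\t"))
  string_path(unname(img), meta$endpoint_fixed)
}

#' Write a pooled sample set to disk
#'
#' Columnar TSV holding the window index, CV values, positions (if present)
#' and reduced potentials (`u1..uK` columns), plus a JSON sidecar with
#' counts, inefficiencies and window metadata.
#'
#' @param samples a `SampleSet`.
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
write_sample_set <- function(samples, file) {
  stopifnot(inherits(samples, "SampleSet"))
  K <- length(samples$counts)
  df <- data.frame(window = samples$window_index)
  cv <- as.data.frame(samples$cv_values)
  names(cv) <- paste0("cv", seq_len(ncol(cv)))
  df <- cbind(df, cv)
  if (!is.null(samples$positions)) {
    px <- as.data.frame(samples$positions)
    names(px) <- paste0("x", seq_len(ncol(px)))
    df <- cbind(df, px)
  }
  if (!is.null(samples$u_unbiased)) df$u0 <- samples$u_unbiased
  up <- as.data.frame(t(samples$reduced_potentials))
  names(up) <- paste0("u", seq_len(K))
  df <- cbind(df, up)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "SampleSet", counts = samples$counts,
         inefficiencies = samples$inefficiencies,
         has_positions = !is.null(samples$positions),
         has_u_unbiased = !is.null(samples$u_unbiased),
         n_cv = ncol(samples$cv_values), windows = samples$windows),
    .sidecar(file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a sample set written by [write_sample_set()]
#' @param file TSV path.
#' @return a `SampleSet`.
#' @export
read_sample_set <- function(file) {
  meta <- jsonlite::read_json(.sidecar(file), simplifyVector = TRUE)
  df <- read.table(file, header = TRUE, sep = "\t")
  K <- length(meta$counts)
  M <- meta$n_cv
  cv <- as.matrix(df[paste0("cv", seq_len(M))])
  pos <- if (isTRUE(meta$has_positions)) {
    as.matrix(df[grep("^x[0-9]+$", names(df), value = TRUE)])
  }
  u0 <- if (isTRUE(meta$has_u_unbiased)) df$u0
  up <- t(as.matrix(df[paste0("u", seq_len(K))]))
  win <- meta$windows
  if (!is.null(win$centers)) win$centers <- as.matrix(win$centers)
  sample_set(unname(cv), unname(up), meta$counts, df$window,
             positions = if (!is.null(pos)) unname(pos),
             u_unbiased = u0, inefficiencies = meta$inefficiencies,
             windows = win)
}

#' Write a cell PMF table
#'
#' TSV with one row per cell: probability, relative volume, PMF (kT) and,
#' when available, the uncorrected PMF and uncertainty.
#'
#' @param cellpmf a `CellPMF`.
#' @param file output TSV path.
#' @param extra optional named list of extra per-cell columns.
#' @return `file`, invisibly.
#' @export
write_cell_pmf <- function(cellpmf, file, extra = NULL) {
  stopifnot(inherits(cellpmf, "CellPMF"))
  df <- data.frame(cell = seq_along(cellpmf$pmf),
                   probability = cellpmf$probabilities,
                   volume = cellpmf$volumes,
                   pmf_kT = cellpmf$pmf)
  if (!is.null(cellpmf$uncertainties)) df$uncertainty <- cellpmf$uncertainties
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a density grid as plain-text voxels
#'
#' An OpenDX-style layout: a commented header carrying origin, spacing and
#' shape, then one density value per line per cell block, voxels in array
#' order (first axis fastest).
#'
#' @param grid a `DensityGrid`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_density_grid <- function(grid, file) {
  stopifnot(inherits(grid, "DensityGrid"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# object 1 class gridpositions counts %s",
            paste(grid$shape, collapse = " ")),
    sprintf("# origin %s", paste(grid$origin, collapse = " ")),
    sprintf("# delta %s", paste(grid$spacing, collapse = " ")),
    sprintf("# cells %d out_of_grid %d", nrow(grid$density), grid$out_of_grid)),
    con)
  for (k in seq_len(nrow(grid$density))) {
    writeLines(sprintf("# cell %d weight %.12g", k, grid$cell_weight[k]), con)
    writeLines(format(grid$density[k, ], digits = 10), con)
  }
  invisible(file)
}

#' Read a structure ensemble from PDB files
#'
#' Reads one or more (multi-model) PDB files, keeping the Cα atoms by
#' default.  All models must share the atom count and ordering; a mismatch
#' is reported with the first offending residue.  Residue numbering, chain
#' and insertion codes are preserved in the atom labels.
#'
#' @param paths character vector of PDB file paths.
#' @param selection bio3d atom selection keyword (default `"calpha"`).
#' @return a `StructureEnsemble` with labels `chain_resno[_insert]`.
#' @export
read_structure_ensemble <- function(paths, selection = "calpha") {
  stopifnot(length(paths) >= 1L)
  frames <- list()
  labels <- NULL
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE)
    sel <- bio3d::atom.select(pdb, selection, verbose = FALSE)
    at <- pdb$atom[sel$atom, , drop = FALSE]
    lab <- paste0(at$chain, "_", at$resno,
                  ifelse(is.na(at$insert) | at$insert == "", "",
                         paste0("_", at$insert)))
    if (is.null(labels)) {
      labels <- lab
    } else if (length(lab) != length(labels) || any(lab != labels)) {
      bad <- if (length(lab) != length(labels)) {
        m <- min(length(lab), length(labels))
        i <- which(lab[seq_len(m)] != labels[seq_len(m)])[1L]
        if (is.na(i)) m + 1L else i
      } else which(lab != labels)[1L]
      stop(sprintf("atom mismatch in '%s' at position %d (residue %s)",
                   p, bad,
                   if (bad <= length(lab)) lab[bad] else labels[bad]),
           call. = FALSE)
    }
    X <- pdb$xyz[, sel$xyz, drop = FALSE]
    for (i in seq_len(nrow(X))) {
      frames[[length(frames) + 1L]] <- .unflatten_frame(X[i, ])
    }
  }
  coords <- array(NA_real_, c(length(frames), length(labels), 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  structure_ensemble(coords, labels, source = paste(paths, collapse = ";"))
}

#' Write a structure ensemble as a multi-model PDB
#'
#' Cα-trace PDB with one MODEL block per frame, coordinates at the standard
#' 3-decimal precision (hence round-trips to 1e-3 length units).
#'
#' @param ensemble a `StructureEnsemble`.
#' @param file output PDB path.
#' @param chain chain identifier.
#' @return `file`, invisibly.
#' @export
write_structure_ensemble <- function(ensemble, file, chain = "A") {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  n <- dim(ensemble$coordinates)[1L]
  A <- dim(ensemble$coordinates)[2L]
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    fr <- .ens_frame(ensemble, i)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(A), chain, seq_len(A), fr[, 1L], fr[, 2L], fr[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
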