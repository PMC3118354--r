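# Conformational-ensemble container and I/O: multi-model PDB, XYZ trajectory,
# plain coordinate matrices, equivalence maps and cluster tables.

#' Conformational ensemble
#'
#' An ordered set of conformations of one molecule. Coordinates are stored as
#' a `frames x 3N` matrix in bio3d order (x1, y1, z1, x2, ...), in Angstrom.
#'
#' @param xyz numeric matrix `frames x 3N`, or a `frames x N x 3` array.
#' @param times per-frame time stamps (ps), strictly increasing within each
#'   source; synthesized at 1 ps spacing when `NULL`.
#' @param source_labels per-frame character identifier of the origin
#'   trajectory.
#' @param atom_ids ordered atom identifiers (e.g. "12 CA"); synthesized when
#'   `NULL`.
#' @return object of class `conf_ensemble` with fields `xyz`, `n_frames`,
#'   `n_atoms`, `times`, `source_labels`, `atom_ids`.
#' @export
conf_ensemble <- function(xyz, times = NULL, source_labels = NULL, atom_ids = NULL) {
  if (is.array(xyz) && length(dim(xyz)) == 3) {
    stopifnot(dim(xyz)[3] == 3)
    xyz <- t(apply(xyz, 1, function(fr) as.numeric(t(fr))))
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stopf("coordinate columns must be a multiple of 3")
  if (nrow(xyz) < 1) stopf("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stopf("coordinates must be finite")
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  times <- times %||% (seq_len(n_frames) - 1)
  source_labels <- source_labels %||% rep("traj", n_frames)
  atom_ids <- atom_ids %||% paste(seq_len(n_atoms), "CA")
  stopifnot(length(times) == n_frames, length(source_labels) == n_frames,
            length(atom_ids) == n_atoms)
  for (src in unique(source_labels)) {
    tt <- times[source_labels == src]
    if (any(diff(tt) <= 0))
      stopf("times must be strictly increasing within source '%s'", src)
  }
  structure(list(xyz = unname(xyz), n_frames = n_frames, n_atoms = as.integer(n_atoms),
                 times = as.numeric(times), source_labels = as.character(source_labels),
                 atom_ids = as.character(atom_ids)),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble: %d frames x %d atoms (%d sources)\n",
              x$n_frames, x$n_atoms, length(unique(x$source_labels))))
  cat(sprintf("  time span %.6g - %.6g ps\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one frame as an `N x 3` coordinate matrix
#' @param ensemble a [conf_ensemble()].
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Subset an ensemble by frame or atom indices
#' @param ensemble a [conf_ensemble()].
#' @param idx frame indices to keep (in the given order).
#' @return a [conf_ensemble()].
#' @export
subset_frames <- function(ensemble, idx) {
  conf_ensemble(ensemble$xyz[idx, , drop = FALSE], times = ensemble$times[idx],
                source_labels = ensemble$source_labels[idx],
                atom_ids = ensemble$atom_ids)
}

#' @rdname subset_frames
#' @param atoms atom indices to keep.
#' @export
subset_atoms <- function(ensemble, atoms) {
  cols <- as.vector(rbind(3 * atoms - 2, 3 * atoms - 1, 3 * atoms))
  conf_ensemble(ensemble$xyz[, cols, drop = FALSE], times = ensemble$times,
                source_labels = ensemble$source_labels,
                atom_ids = ensemble$atom_ids[atoms])
}

#' Read a conformational ensemble from file
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` records become
#' frames; parsed through bio3d), XYZ trajectory (repeated
#' count/comment/atom-line blocks), and plain whitespace-delimited matrices
#' (one frame per row, `3N` columns). PDB coordinates are Angstrom by
#' convention; for `xyz` and `matrix` input the unit can be declared and is
#' converted to the package-wide Angstrom on read.
#'
#' @param path file path.
#' @param format one of `"pdb_models"`, `"xyz"`, `"matrix"`.
#' @param selection atom-name filter (e.g. `"CA"`); `pdb_models` and `xyz`
#'   only. `NULL` keeps all atoms.
#' @param unit `"angstrom"` or `"nm"` for `xyz`/`matrix` input.
#' @param dt synthesized time spacing (ps) when the file carries no times.
#' @param source label recorded for every frame; defaults to the file name.
#' @return a [conf_ensemble()].
#' @export
read_ensemble <- function(path, format = c("pdb_models", "xyz", "matrix"),
                          selection = NULL, unit = c("angstrom", "nm"),
                          dt = 1, source = NULL) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stopf("file not found: %s", path)
  source <- source %||% basename(path)
  ens <- switch(format,
    pdb_models = read_pdb_models(path, selection),
    xyz = read_xyz_traj(path, selection),
    matrix = {
      m <- tryCatch(as.matrix(utils::read.table(path)),
                    error = function(e) stopf("cannot parse matrix file %s: %s",
                                              path, conditionMessage(e)))
      if (!is.numeric(m)) stopf("matrix file %s contains non-numeric entries", path)
      if (ncol(m) %% 3 != 0)
        stopf("matrix file %s has %d columns, not a multiple of 3", path, ncol(m))
      conf_ensemble(m)
    })
  if (unit == "nm" && format != "pdb_models") ens$xyz <- ens$xyz * 10
  ens$times <- (seq_len(ens$n_frames) - 1) * dt
  ens$source_labels <- rep(source, ens$n_frames)
  ens
}

# Multi-model PDB via bio3d, with an explicit per-MODEL consistency check
# (the method assumes fixed dimensionality; ragged models are rejected).
read_pdb_models <- function(path, selection = NULL) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    atom_counts <- vapply(seq_along(model_starts), function(i) {
      blk <- lines[bounds[i]:(bounds[i + 1] - 1L)]
      blk <- blk[grepl("^(ATOM  |HETATM)", blk)]
      if (!is.null(selection))
        blk <- blk[trimws(substr(blk, 13, 16)) %in% selection]
      length(blk)
    }, integer(1))
    if (length(unique(atom_counts)) > 1)
      stopf("inconsistent atom counts across MODEL records in %s: %s",
            path, paste(atom_counts, collapse = ", "))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stopf("cannot parse PDB %s: %s", path,
                                            conditionMessage(e)))
  if (!is.null(selection)) {
    sel <- which(pdb$atom$elety %in% selection)
    if (length(sel) == 0) stopf("selection '%s' matches no atoms in %s",
                                paste(selection, collapse = ","), path)
  } else sel <- seq_len(nrow(pdb$atom))
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  xyz <- rbind(pdb$xyz)[, cols, drop = FALSE]
  ids <- paste(pdb$atom$resno[sel], pdb$atom$elety[sel])
  conf_ensemble(xyz, atom_ids = ids)
}

# Plain XYZ trajectory: blocks of <natoms>, <comment>, natoms atom lines.
read_xyz_traj <- function(path, selection = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); names_ref <- NULL; pos <- 1L; fno <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1)
      stopf("XYZ parse error at line %d: expected atom count", pos)
    if (pos + 1L + nat > length(lines))
      stopf("XYZ truncated frame starting at line %d", pos)
    fno <- fno + 1L
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stopf("XYZ parse error at line %d: need 'name x y z'", pos + 1L + bad[1])
    nm <- vapply(parts, `[[`, "", 1)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(co)))
      stopf("XYZ parse error in frame %d: non-numeric coordinate", fno)
    keep <- if (is.null(selection)) seq_len(nat) else which(nm %in% selection)
    if (length(keep) == 0) stopf("selection matches no atoms in frame %d", fno)
    if (is.null(names_ref)) names_ref <- nm[keep]
    else if (length(keep) != length(names_ref))
      stopf("frame %d has %d selected atoms, expected %d", fno,
            length(keep), length(names_ref))
    frames[[fno]] <- as.numeric(t(co[keep, , drop = FALSE]))
    pos <- pos + 2L + nat
  }
  conf_ensemble(do.call(rbind, frames),
                atom_ids = paste(seq_along(names_ref), names_ref))
}

#' Write a conformational ensemble
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output path.
#' @param format `"matrix"` (whitespace matrix, one frame per row) or
#'   `"pdb_models"` (multi-model PDB via bio3d).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("matrix", "pdb_models")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(format(ensemble$xyz, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    resno <- suppressWarnings(as.integer(sub(" .*", "", ensemble$atom_ids)))
    if (any(is.na(resno))) resno <- seq_len(ensemble$n_atoms)
    bio3d::write.pdb(xyz = ensemble$xyz, file = path, resno = resno,
                     elety = rep("CA", ensemble$n_atoms),
                     resid = rep("ALA", ensemble$n_atoms))
  }
  invisible(path)
}

#' Read / write an atom-equivalence map
#'
#' Two-column TSV: domain name, comma-separated 1-based atom indices. All
#' domains must list the same number of indices (structurally equivalent
#' positions).
#'
#' @param path file path.
#' @return named list of integer vectors, class `equivalence_map`.
#' @export
read_equivalence_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("domain", "indices"),
                          stringsAsFactors = FALSE, comment.char = "#")
  m <- lapply(strsplit(df$indices, ","), function(s) as.integer(trimws(s)))
  names(m) <- df$domain
  equivalence_map(m)
}

#' @rdname read_equivalence_map
#' @param map named list of equal-length integer index vectors.
#' @export
equivalence_map <- function(map) {
  lens <- vapply(map, length, integer(1))
  if (length(unique(lens)) != 1) stopf("all domains must map the same atom count")
  for (nm in names(map)) {
    idx <- map[[nm]]
    if (anyDuplicated(idx) || any(idx < 1))
      stopf("indices for domain '%s' must be unique positive integers", nm)
  }
  structure(map, class = "equivalence_map")
}

#' @rdname read_equivalence_map
#' @export
write_equivalence_map <- function(map, path) {
  df <- data.frame(domain = names(map),
                   indices = vapply(map, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge ensembles over structurally equivalent atoms
#'
#' Concatenates frames of several (e.g. wild-type and mutant) ensembles,
#' restricted to the equivalent atom positions given by the map, so combined
#' data sets can be clustered together. Source labels and per-source time
#' ordering are preserved.
#'
#' @param ensembles named list of [conf_ensemble()] objects; names must match
#'   map domains.
#' @param map an [equivalence_map()]; `NULL` uses all atoms (requires equal
#'   atom counts).
#' @return a merged [conf_ensemble()].
#' @export
merge_ensembles <- function(ensembles, map = NULL) {
  stopifnot(length(ensembles) >= 1)
  nms <- names(ensembles) %||% paste0("ens", seq_along(ensembles))
  parts <- lapply(seq_along(ensembles), function(i) {
    ens <- ensembles[[i]]
    if (!is.null(map)) {
      idx <- map[[nms[i]]]
      if (is.null(idx)) stopf("equivalence map has no entry for domain '%s'", nms[i])
      if (max(idx) > ens$n_atoms)
        stopf("map index %d exceeds atom count %d for '%s'", max(idx),
              ens$n_atoms, nms[i])
      ens <- subset_atoms(ens, idx)
    }
    if (all(ens$source_labels == "traj") || all(ens$source_labels == "synth"))
      ens$source_labels <- rep(nms[i], ens$n_frames)
    ens
  })
  n_atoms <- unique(vapply(parts, function(e) e$n_atoms, integer(1)))
  if (length(n_atoms) != 1)
    stopf("mapped atom counts differ across ensembles: %s",
          paste(vapply(parts, function(e) e$n_atoms, integer(1)), collapse = ", "))
  conf_ensemble(do.call(rbind, lapply(parts, `[[`, "xyz")),
                times = unlist(lapply(parts, `[[`, "times")),
                source_labels = unlist(lapply(parts, `[[`, "source_labels")),
                atom_ids = parts[[1]]$atom_ids)
}

#' Write / read a per-conformation cluster table
#'
#' One row per conformation: source label, frame index, time, neuron index
#' and cluster id, ordered by source then time.
#'
#' @param solution a `cluster_solution` (see [cut_and_assign()]).
#' @param path output path.
#' @param meta optional named character vector written as `#` header lines.
#' @return `path` invisibly; `read_cluster_table()` returns a data.frame.
#' @export
write_cluster_table <- function(solution, path, meta = character()) {
  df <- data.frame(source = solution$source_labels,
                   frame = seq_along(solution$conformation_labels) - 1L,
                   time = solution$times,
                   neuron = solution$bmu,
                   cluster = solution$conformation_labels)
  if (nrow(df)) df <- df[order(df$source, df$time), ]
  write_tsv_meta(df, path, meta)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) read_tsv_meta(path)
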