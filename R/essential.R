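# Essential Dynamics: superposition, covariance/PCA essential space, ED
# filtering, RMSF, covariance overlap and dRMSD.

#' Rigid-body superposition of an ensemble
#'
#' Least-squares fits every frame (rotation + translation, Kabsch, via
#' bio3d's `fit.xyz`) onto a reference. The default is an iterative
#' fit-to-mean: frames are first fitted to frame 1, then re-fitted to the
#' running mean structure (`iter` rounds). The fit can never increase a
#' frame's RMSD to the reference, since the identity motion is admissible.
#'
#' @param ensemble a [conf_ensemble()].
#' @param mode `"iterative_mean"` (default) or `"first_frame"`.
#' @param iter number of fit-to-mean rounds for `"iterative_mean"`.
#' @return superposed [conf_ensemble()].
#' @export
superpose <- function(ensemble, mode = c("iterative_mean", "first_frame"),
                      iter = 2) {
  mode <- match.arg(mode)
  xyz <- ensemble$xyz
  fitted <- fit_to_reference(xyz[1, ], xyz)
  if (mode == "iterative_mean") {
    for (i in seq_len(iter)) fitted <- fit_to_reference(colMeans(fitted), fitted)
  }
  out <- ensemble
  out$xyz <- fitted
  out
}

fit_to_reference <- function(ref, xyz) {
  inds <- seq_len(ncol(xyz))
  fitted <- bio3d::fit.xyz(fixed = as.numeric(ref), mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  fitted <- rbind(fitted)
  if (any(!is.finite(fitted))) {
    warnf("degenerate frame(s) in superposition; centering without rotation")
    bad <- which(apply(fitted, 1, function(r) any(!is.finite(r))))
    refc <- colMeans(matrix(ref, ncol = 3, byrow = TRUE))
    for (i in bad) {
      fr <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      fr <- sweep(fr, 2, colMeans(fr) - refc)
      fitted[i, ] <- as.numeric(t(fr))
    }
  }
  fitted
}

#' Coordinate covariance matrix of an ensemble
#'
#' Mean-centered second moments of the `3N` atomic coordinates over frames.
#' The divisor is the frame count (population form) by default.
#'
#' @param ensemble a [conf_ensemble()] (usually superposed first).
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return object of class `cov_matrix`: list with `matrix` (`3N x 3N`) and
#'   `atom_count`.
#' @export
covariance <- function(ensemble, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (ensemble$n_frames < 2) stopf("covariance needs at least 2 frames")
  xc <- sweep(ensemble$xyz, 2, colMeans(ensemble$xyz))
  d <- if (divisor == "n") ensemble$n_frames else ensemble$n_frames - 1
  structure(list(matrix = crossprod(xc) / d, atom_count = ensemble$n_atoms),
            class = "cov_matrix")
}

#' Build the essential space of an ensemble
#'
#' Eigendecomposition of the coordinate covariance matrix; the leading `k`
#' eigendirections span the essential space of large-amplitude collective
#' motion. Eigenvalues are clamped at zero against numerical noise.
#'
#' @param ensemble a superposed [conf_ensemble()].
#' @param k retained dimension count, `1 <= k <= 3N`.
#' @param divisor covariance divisor, see [covariance()].
#' @return object of class `essential_space`: `mean_coords` (`N x 3`),
#'   `eigenvectors` (`3N x 3N`, columns), `eigenvalues` (descending), `k`,
#'   `atom_count`, `variance_explained`.
#' @export
essential_space <- function(ensemble, k = 30, divisor = "n") {
  d3 <- 3 * ensemble$n_atoms
  if (k < 1 || k > d3) stopf("k must lie in [1, %d]", d3)
  cv <- covariance(ensemble, divisor)
  eig <- eigen(cv$matrix, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  ve <- if (sum(vals) > 0) sum(vals[1:k]) / sum(vals) else 1
  structure(list(mean_coords = matrix(colMeans(ensemble$xyz), ncol = 3, byrow = TRUE),
                 eigenvectors = eig$vectors, eigenvalues = vals, k = as.integer(k),
                 atom_count = ensemble$n_atoms, variance_explained = ve),
            class = "essential_space")
}

#' @export
print.essential_space <- function(x, ...) {
  cat(sprintf("Essential space: %d atoms, k = %d (%.1f%% of variance)\n",
              x$atom_count, x$k, 100 * x$variance_explained))
  invisible(x)
}

#' Project an ensemble onto its essential space (ED filtering)
#'
#' Each frame is replaced by `mean + projection onto the first k
#' eigenvectors`, reconstructed in the full `3N` Cartesian space, so the
#' descriptor length stays `3N` (165 elements for 55 atoms) while
#' high-frequency noise outside the essential space is removed. The
#' operation is idempotent.
#'
#' @param ensemble a [conf_ensemble()] with the same atom count as `space`.
#' @param space an [essential_space()].
#' @return filtered [conf_ensemble()].
#' @export
ed_filter <- function(ensemble, space) {
  if (ensemble$n_atoms != space$atom_count)
    stopf("ensemble has %d atoms, essential space %d", ensemble$n_atoms,
          space$atom_count)
  mu <- as.numeric(t(space$mean_coords))
  V <- space$eigenvectors[, seq_len(space$k), drop = FALSE]
  xc <- sweep(ensemble$xyz, 2, mu)
  recon <- tcrossprod(xc %*% V, V)
  out <- ensemble
  out$xyz <- sweep(recon, 2, mu, `+`)
  out
}

#' Per-atom root mean square fluctuation
#'
#' RMSF of atom i is the square root of the time-averaged squared
#' displacement from its time-averaged position. Computed on the coordinates
#' as given; apply [ed_filter()] first for the noise-reduced profile.
#'
#' @param ensemble a superposed [conf_ensemble()] with >= 2 frames.
#' @return numeric vector of length `n_atoms` (Angstrom).
#' @export
rmsf <- function(ensemble) {
  if (ensemble$n_frames < 2) stopf("rmsf needs at least 2 frames")
  xc <- sweep(ensemble$xyz, 2, colMeans(ensemble$xyz))
  msd <- colMeans(xc^2)
  sqrt(msd[c(TRUE, FALSE, FALSE)] + msd[c(FALSE, TRUE, FALSE)] +
         msd[c(FALSE, FALSE, TRUE)])
}

# Symmetric PSD matrix square root; negative eigenvalues clamped at 0.
psd_sqrt <- function(m) {
  eig <- eigen(m, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  eig$vectors %*% (sqrt(vals) * t(eig$vectors))
}

#' Covariance overlap between two fluctuation spaces
#'
#' `s(A, B) = 1 - sqrt((tr A + tr B - 2 tr((A^1/2 B A^1/2)^1/2)) /
#' (tr A + tr B))`. A value of 1 means the spanned subspaces (with their
#' amplitudes) are identical; 0 means complete orthogonality. Symmetric in
#' its arguments and clamped to `[0, 1]` against rounding.
#'
#' @param A,B `cov_matrix` objects or plain symmetric PSD matrices of equal
#'   dimension.
#' @return numeric scalar in `[0, 1]`.
#' @export
covariance_overlap <- function(A, B) {
  if (inherits(A, "cov_matrix")) A <- A$matrix
  if (inherits(B, "cov_matrix")) B <- B$matrix
  stopifnot(all(dim(A) == dim(B)))
  trA <- sum(diag(A)); trB <- sum(diag(B))
  if (trA + trB <= 0) stopf("overlap undefined: both matrices have zero trace")
  # tr((A^1/2 B A^1/2)^1/2) equals the nuclear norm of B^1/2 A^1/2, which is
  # numerically far better conditioned than the nested square root
  cross <- sum(svd(psd_sqrt(B) %*% psd_sqrt(A), nu = 0, nv = 0)$d)
  arg <- (trA + trB - 2 * cross) / (trA + trB)
  # relative residuals at rounding level would be amplified by the sqrt
  if (arg < 1e-12) arg <- 0
  s <- 1 - sqrt(arg)
  min(max(s, 0), 1)
}

#' Distance RMSD between two conformations
#'
#' RMSD between the intra-conformation distances of all unordered pairs of
#' the selected atoms in conformation `a` and the same distances in `b`.
#' Invariant under rigid motion of either conformation.
#'
#' @param conf_a,conf_b `N x 3` coordinate matrices (or single-frame
#'   ensembles).
#' @param atom_indices atoms over which pairwise distances are taken
#'   (default: all).
#' @return numeric scalar (Angstrom).
#' @export
drmsd <- function(conf_a, conf_b, atom_indices = NULL) {
  as_mat <- function(x) {
    if (inherits(x, "conf_ensemble")) {
      stopifnot(x$n_frames == 1)
      x <- frame_coords(x, 1)
    }
    as.matrix(x)
  }
  a <- as_mat(conf_a); b <- as_mat(conf_b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  idx <- atom_indices %||% seq_len(nrow(a))
  if (length(idx) < 2) stopf("drmsd needs at least 2 atoms")
  da <- stats::dist(a[idx, , drop = FALSE])
  db <- stats::dist(b[idx, , drop = FALSE])
  sqrt(mean((da - db)^2))
}

#' Serialize / deserialize an essential space
#'
#' Structured plain-text format: header lines, mean coordinates, eigenvalues
#' and eigenvector columns.
#'
#' @param space an [essential_space()].
#' @param path file path.
#' @return `path` invisibly; the reader returns an `essential_space`.
#' @export
write_essential_space <- function(space, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# essential_space atoms=%d k=%d", space$atom_count, space$k),
               "# mean"), con)
  utils::write.table(format(space$mean_coords, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("# eigenvalues", con)
  writeLines(format(space$eigenvalues, digits = 12), con)
  writeLines("# eigenvectors (columns, row-per-line)", con)
  utils::write.table(format(space$eigenvectors, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_essential_space
#' @export
read_essential_space <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("# essential_space ", "", lines[1]), " ")[[1]]
  n <- as.integer(sub("atoms=", "", hdr[1]))
  k <- as.integer(sub("k=", "", hdr[2]))
  mean_block <- lines[3:(2 + n)]
  mean_coords <- do.call(rbind, lapply(strsplit(trimws(mean_block), "[[:space:]]+"),
                                       as.numeric))
  ev_start <- 3 + n + 1
  eigenvalues <- as.numeric(lines[ev_start:(ev_start + 3 * n - 1)])
  vec_start <- ev_start + 3 * n + 1
  vec_block <- lines[vec_start:(vec_start + 3 * n - 1)]
  eigenvectors <- do.call(rbind, lapply(strsplit(trimws(vec_block), "[[:space:]]+"),
                                        as.numeric))
  ve <- if (sum(eigenvalues) > 0) sum(eigenvalues[1:k]) / sum(eigenvalues) else 1
  structure(list(mean_coords = mean_coords, eigenvectors = eigenvectors,
                 eigenvalues = eigenvalues, k = k, atom_count = n,
                 variance_explained = ve),
            class = "essential_space")
}
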