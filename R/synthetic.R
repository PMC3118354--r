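# Synthetic conformational ensembles with planted basins, collective modes
# and Markov-style temporal correlation. These stand in for MD trajectories
# when validating the two-level clustering workflow end to end.

#' Specification of a synthetic conformational ensemble
#'
#' Describes a Calpha-like bead chain whose conformations fluctuate along a
#' small set of smooth collective modes, visit a few discrete conformational
#' basins (offsets along those modes) following a hidden Markov chain, and
#' carry isotropic Gaussian coordinate noise on top.
#'
#' Defaults emulate the statistical structure of a 40 ns domain simulation
#' summarised at 1 frame/ps: 55 atoms, 4000 frames, three basins separated by
#' 10 Angstrom in mode space, within-basin mode amplitudes of 1.0/0.7/0.5
#' Angstrom and 0.3 Angstrom per-coordinate noise.
#'
#' @param n_atoms number of beads (Calpha positions).
#' @param n_frames number of frames.
#' @param dt time spacing between frames (ps).
#' @param mode_amplitudes within-basin fluctuation standard deviation along
#'   each collective mode (Angstrom); its length sets the number of modes.
#' @param mode_smooth standard deviation (in beads) of the Gaussian smoothing
#'   applied along the chain when building mode displacement fields.
#' @param basin_centers numeric matrix, one row per basin, of offsets along
#'   the unit modes (Angstrom). Must have `length(mode_amplitudes)` columns.
#' @param basin_weights occupancy weights, summing to 1.
#' @param stay_prob per-frame probability of remaining in the current basin.
#' @param noise_sigma isotropic Gaussian noise per coordinate (Angstrom).
#' @param seed integer seed for the trajectory (states, fluctuations, noise).
#' @param structure_seed integer seed for the shared reference chain and mode
#'   directions; defaults to `seed`. Variants of one system share this value.
#' @return object of class `synth_spec`.
#' @seealso [simulate_ensemble()], [make_variant_set()]
#' @export
synth_spec <- function(n_atoms = 55, n_frames = 4000, dt = 1,
                       mode_amplitudes = c(1.0, 0.7, 0.5), mode_smooth = 3,
                       basin_centers = rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                       basin_weights = c(1, 1, 1) / 3,
                       stay_prob = 0.99, noise_sigma = 0.3,
                       seed = 1, structure_seed = seed) {
  basin_centers <- rbind(basin_centers)
  if (ncol(basin_centers) != length(mode_amplitudes))
    stopf("basin_centers must have one column per mode (%d)", length(mode_amplitudes))
  if (nrow(basin_centers) != length(basin_weights))
    stopf("need one weight per basin")
  if (abs(sum(basin_weights) - 1) > 1e-8)
    stopf("basin_weights must sum to 1")
  if (any(mode_amplitudes <= 0)) stopf("mode amplitudes must be positive")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (stay_prob <= 0 || stay_prob >= 1) stopf("stay_prob must lie in (0,1)")
  if (n_atoms < 4) stopf("need at least 4 atoms")
  structure(list(
    n_atoms = as.integer(n_atoms), n_frames = as.integer(n_frames), dt = dt,
    mode_amplitudes = mode_amplitudes, mode_smooth = mode_smooth,
    basin_centers = basin_centers, basin_weights = basin_weights,
    stay_prob = stay_prob, noise_sigma = noise_sigma,
    seed = as.integer(seed), structure_seed = as.integer(structure_seed)
  ), class = "synth_spec")
}

#' Build a Calpha-like self-avoiding reference chain
#'
#' A persistent random walk with exact 3.8 Angstrom bond lengths; candidate
#' beads closer than 3.4 Angstrom to any non-adjacent bead are rejected.
#'
#' @param n_atoms number of beads (>= 4).
#' @param seed integer seed.
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
make_reference <- function(n_atoms, seed = 1) {
  if (n_atoms < 4) stopf("need at least 4 atoms")
  with_seed(seed, {
    coords <- matrix(0, n_atoms, 3)
    dir <- c(1, 0, 0)
    for (i in 2:n_atoms) {
      placed <- FALSE
      for (try in 1:200) {
        persist <- if (try <= 100) 0.7 else 0   # loosen persistence if stuck
        cand_dir <- persist * dir + (1 - persist + 0.3) * stats::rnorm(3)
        cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
        cand <- coords[i - 1, ] + 3.8 * cand_dir
        if (i <= 3) { ok <- TRUE } else {
          prev <- coords[1:(i - 2), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
          ok <- all(d2 >= 3.4^2)
        }
        if (ok) { coords[i, ] <- cand; dir <- cand_dir; placed <- TRUE; break }
      }
      if (!placed) stopf("failed to grow self-avoiding chain at bead %d", i)
    }
    coords
  })
}

# Orthonormal basis of the 6 rigid-body displacement fields (3 translations,
# 3 infinitesimal rotations about the centroid) of a reference structure.
rigid_basis <- function(ref) {
  n <- nrow(ref)
  centred <- sweep(ref, 2, colMeans(ref))
  basis <- matrix(0, 3 * n, 6)
  for (ax in 1:3) basis[seq(ax, 3 * n, by = 3), ax] <- 1
  axes <- diag(3)
  for (ax in 1:3) {
    disp <- t(apply(centred, 1, function(r)
      c(axes[ax, 2] * r[3] - axes[ax, 3] * r[2],
        axes[ax, 3] * r[1] - axes[ax, 1] * r[3],
        axes[ax, 1] * r[2] - axes[ax, 2] * r[1])))
    basis[, 3 + ax] <- as.numeric(t(disp))
  }
  qr.Q(qr(basis))
}

# Smooth, orthonormal collective-mode matrix (3N x n_modes). Each mode is a
# per-atom displacement field smoothed along the chain index so contiguous
# stretches ("loops") move coherently, then orthonormalized against the
# rigid-body motions of the reference (so superposition does not absorb
# planted variance) and against the previous modes.
make_modes <- function(n_atoms, n_modes, smooth_sd, seed, reference = NULL) {
  rigid <- if (!is.null(reference)) rigid_basis(reference) else NULL
  with_seed(seed, {
    kernel_half <- max(1L, ceiling(3 * smooth_sd))
    kern <- stats::dnorm(seq(-kernel_half, kernel_half), sd = smooth_sd)
    kern <- kern / sum(kern)
    modes <- matrix(0, 3 * n_atoms, n_modes)
    for (m in seq_len(n_modes)) {
      field <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
      for (ax in 1:3) {
        padded <- c(rep(field[1, ax], kernel_half), field[, ax],
                    rep(field[n_atoms, ax], kernel_half))
        field[, ax] <- stats::filter(padded, kern, sides = 2)[
          (kernel_half + 1):(kernel_half + n_atoms)]
      }
      v <- as.numeric(t(field))   # atom-major (x1,y1,z1,x2,...)
      if (!is.null(rigid)) v <- v - rigid %*% crossprod(rigid, v)
      if (m > 1) {
        prev <- modes[, 1:(m - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      modes[, m] <- v / sqrt(sum(v^2))
    }
    modes
  })
}

#' Simulate a synthetic conformational ensemble
#'
#' Frames are `reference + sum_m (center[state, m] + A_m * eta) * mode_m +
#' noise`, where the hidden basin state follows a Markov chain that stays with
#' probability `stay_prob` and otherwise redraws the state from the occupancy
#' weights (which are therefore the stationary law of the chain).
#'
#' @param spec a [synth_spec()].
#' @return list with `ensemble` (a [conf_ensemble()]), `labels` (ground-truth
#'   basin per frame), `modes`, `reference` and `basin_centers`.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n_modes <- length(spec$mode_amplitudes)
  ref <- make_reference(spec$n_atoms, derive_seed(spec$structure_seed, "reference"))
  modes <- make_modes(spec$n_atoms, n_modes, spec$mode_smooth,
                      derive_seed(spec$structure_seed, "modes"), reference = ref)
  n <- spec$n_frames
  with_seed(spec$seed, {
    n_basins <- nrow(spec$basin_centers)
    states <- integer(n)
    states[1] <- sample.int(n_basins, 1, prob = spec$basin_weights)
    if (n > 1) {
      stay <- stats::runif(n - 1) < spec$stay_prob
      redraw <- sample.int(n_basins, n - 1, replace = TRUE, prob = spec$basin_weights)
      for (t in 2:n) states[t] <- if (stay[t - 1]) states[t - 1] else redraw[t - 1]
    }
    eta <- matrix(stats::rnorm(n * n_modes), n, n_modes)
    scores <- spec$basin_centers[states, , drop = FALSE] +
      sweep(eta, 2, spec$mode_amplitudes, `*`)
    xyz <- matrix(as.numeric(t(ref)), n, 3 * spec$n_atoms, byrow = TRUE) +
      scores %*% t(modes)
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sigma),
                          nrow(xyz), ncol(xyz))
    ens <- conf_ensemble(xyz, times = (seq_len(n) - 1) * spec$dt,
                         source_labels = rep("synth", n))
    list(ensemble = ens, labels = states, modes = modes, reference = ref,
         basin_centers = spec$basin_centers)
  })
}

#' Generate named ensemble variants sharing reference and modes
#'
#' Emulates a wild type plus mutants: variants share the reference chain and
#' mode directions but may differ in mode amplitudes (flexibility changes) or
#' basin layout. A variant with no modifications and the base seed reproduces
#' the base ensemble exactly.
#'
#' @param base a [synth_spec()].
#' @param variants named list; each element a list with optional entries
#'   `amplitude_scale` (scalar or per-mode multiplier), `basin_centers`,
#'   `basin_weights`, `stay_prob`, `noise_sigma`, `seed`.
#' @return named list of `simulate_ensemble()` results.
#' @export
make_variant_set <- function(base, variants) {
  stopifnot(inherits(base, "synth_spec"))
  if (is.null(names(variants)) || any(names(variants) == ""))
    stopf("variants must be a named list")
  out <- lapply(names(variants), function(nm) {
    mod <- variants[[nm]]
    sp <- base
    if (!is.null(mod$amplitude_scale))
      sp$mode_amplitudes <- sp$mode_amplitudes * mod$amplitude_scale
    for (f in c("basin_centers", "basin_weights", "stay_prob", "noise_sigma"))
      if (!is.null(mod[[f]])) sp[[f]] <- mod[[f]]
    sp$seed <- as.integer(mod$seed %||% base$seed)
    sim <- simulate_ensemble(sp)
    sim$ensemble$source_labels <- rep(nm, sim$ensemble$n_frames)
    sim
  })
  names(out) <- names(variants)
  out
}
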