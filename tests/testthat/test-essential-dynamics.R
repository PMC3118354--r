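rotate_z_90 <- function(coords) coords %*% rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))

test_that("superposition removes rigid motion and is idempotent", {
  set.seed(1)
  base <- matrix(rnorm(15, sd = 3), 5, 3)
  rot <- rotate_z_90(base) + 2
  ens <- conf_ensemble(rbind(as.numeric(t(base)), as.numeric(t(rot))))
  fit <- superpose(ens, mode = "first_frame")
  expect_lt(sqrt(mean((fit$xyz[1, ] - fit$xyz[2, ])^2)), 1e-8)
  again <- superpose(fit, mode = "first_frame")
  expect_equal(again$xyz, fit$xyz, tolerance = 1e-8)
})

test_that("least-squares fit beats any sampled rigid rotation", {
  ens <- random_ensemble(2, 6, seed = 2, sd = 2)
  fit <- superpose(ens, mode = "first_frame")
  ref <- frame_coords(fit, 1)
  fitted_rmsd <- sqrt(mean((frame_coords(fit, 2) - ref)^2))
  # oracle: grid of rotations about the three axes applied to the centered frame
  mobile <- frame_coords(ens, 2)
  mobile <- sweep(mobile, 2, colMeans(mobile))
  target <- sweep(ref, 2, colMeans(ref))
  angles <- seq(0, 2 * pi, length.out = 25)[-25]
  best <- Inf
  rot_mat <- function(a, b, g) {
    Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rx <- rbind(c(1, 0, 0), c(0, cos(g), -sin(g)), c(0, sin(g), cos(g)))
    Rz %*% Ry %*% Rx
  }
  for (a in angles) for (b in angles[1:12]) for (g in angles) {
    r <- sqrt(mean((mobile %*% rot_mat(a, b, g) - target)^2))
    if (r < best) best <- r
  }
  expect_lte(fitted_rmsd, best + 1e-10)
  # and the fit never increases any frame's RMSD
  ens20 <- random_ensemble(20, 6, seed = 3)
  fit20 <- superpose(ens20, mode = "first_frame")
  for (i in 1:20) {
    before <- sqrt(mean((ens20$xyz[i, ] - ens20$xyz[1, ])^2))
    after <- sqrt(mean((fit20$xyz[i, ] - fit20$xyz[1, ])^2))
    expect_lte(after, before + 1e-10)
  }
})

test_that("covariance matches the naive double-loop oracle", {
  ens <- random_ensemble(15, 3, seed = 4)
  cv <- covariance(ens)
  expect_equal(cv$matrix, naive_covariance(ens$xyz), tolerance = 1e-10)
  expect_equal(cv$matrix, t(cv$matrix), tolerance = 1e-12)
  # hand case: 1 atom at (0,0,0) and (2,0,0), divisor n
  two <- conf_ensemble(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(covariance(two)$matrix[1, 1], 1.0)
  expect_equal(sum(abs(covariance(two)$matrix)) , 1.0)
  # degenerate inputs
  const <- conf_ensemble(matrix(1, 5, 6))
  expect_equal(max(abs(covariance(const)$matrix)), 0)
  expect_error(covariance(subset_frames(ens, 1)), "at least 2 frames")
})

test_that("essential space captures planted mode variances", {
  line <- conf_ensemble(outer(seq(-1, 1, length.out = 11), c(1, 0, 0, 2, 0, 0)))
  es <- essential_space(line, k = 1)
  expect_gt(es$eigenvalues[1] / sum(es$eigenvalues), 0.9999)
  expect_equal(essential_space(line, k = 6)$variance_explained, 1.0)
  expect_error(essential_space(line, k = 7), "k must lie")
  # planted 3-mode ensemble with variance ratio 9:4:1
  spec <- synth_spec(n_atoms = 20, n_frames = 2000,
                     mode_amplitudes = c(3, 2, 1),
                     basin_centers = matrix(0, 1, 3), basin_weights = 1,
                     noise_sigma = 0, seed = 6)
  sim <- simulate_ensemble(spec)
  es3 <- essential_space(superpose(sim$ensemble), k = 3)
  ratio <- es3$eigenvalues[1:3] / es3$eigenvalues[1]
  expect_equal(ratio, c(1, 4 / 9, 1 / 9), tolerance = 0.1)
})

test_that("ED filtering is a projection that preserves descriptor length", {
  ens <- random_ensemble(30, 55, seed = 7)
  sup <- superpose(ens)
  es <- essential_space(sup, k = 30)
  filt <- ed_filter(sup, es)
  expect_equal(ncol(filt$xyz), 165)
  expect_equal(ed_filter(filt, es)$xyz, filt$xyz, tolerance = 1e-8)
  # full-rank filter is the identity
  es_full <- essential_space(sup, k = 165)
  expect_equal(ed_filter(sup, es_full)$xyz, sup$xyz, tolerance = 1e-6)
  # rank-1 ensemble is unchanged by its own k = 1 filter
  line <- conf_ensemble(outer(seq(-1, 1, length.out = 9), c(1, 0, 0, 2, 0, 0)))
  expect_equal(ed_filter(line, essential_space(line, k = 1))$xyz, line$xyz,
               tolerance = 1e-8)
  expect_error(ed_filter(random_ensemble(5, 4), es), "atoms")
})

test_that("RMSF matches hand computation and the per-atom oracle", {
  const <- conf_ensemble(matrix(2, 4, 9))
  expect_equal(rmsf(const), rep(0, 3))
  flip <- conf_ensemble(rbind(c(1, 0, 0, 5, 5, 5), c(-1, 0, 0, 5, 5, 5)))
  expect_equal(rmsf(flip), c(1, 0))
  ens <- random_ensemble(25, 4, seed = 8)
  expect_equal(rmsf(ens), naive_rmsf(ens$xyz), tolerance = 1e-10)
  expect_error(rmsf(subset_frames(ens, 1)), "at least 2 frames")
})

test_that("RMSF never increases under ED filtering", {
  ens <- superpose(random_ensemble(40, 10, seed = 9))
  filt <- ed_filter(ens, essential_space(ens, k = 5))
  expect_true(all(rmsf(filt) <= rmsf(ens) + 1e-8))
})

test_that("covariance overlap has the analytic limits and symmetry", {
  A <- random_psd(12, seed = 10)
  expect_equal(covariance_overlap(A, A), 1, tolerance = 1e-8)
  # disjoint diagonal supports are orthogonal
  B1 <- diag(c(rep(1, 6), rep(0, 6)))
  B2 <- diag(c(rep(0, 6), rep(1, 6)))
  expect_equal(covariance_overlap(B1, B2), 0, tolerance = 1e-12)
  # symmetry on random PSD pairs
  for (s in 1:5) {
    P <- random_psd(8, seed = s); Q <- random_psd(8, seed = s + 50)
    expect_lt(abs(covariance_overlap(P, Q) - covariance_overlap(Q, P)), 1e-8)
    expect_gte(covariance_overlap(P, Q), 0)
    expect_lte(covariance_overlap(P, Q), 1)
  }
  expect_error(covariance_overlap(diag(0, 3), diag(0, 3)), "zero trace")
})

test_that("overlap of commuting matrices matches the eigenbasis closed form", {
  A <- random_psd(6, seed = 11)
  lam <- eigen(A, symmetric = TRUE)$values
  # closed form for s(A, cA): shared eigenbasis collapses the trace terms
  closed <- function(c) {
    1 - sqrt((sum(lam) + c * sum(lam) - 2 * sum(sqrt(c) * lam)) /
               ((1 + c) * sum(lam)))
  }
  expect_equal(covariance_overlap(A, 2 * A), closed(2), tolerance = 1e-8)
  expect_equal(covariance_overlap(A, 5 * A), closed(5), tolerance = 1e-8)
})

test_that("trajectory halves overlap the full covariance on long synthetics", {
  sim <- simulate_ensemble(synth_spec(n_frames = 4000, seed = 12))
  ens <- superpose(sim$ensemble)
  full <- covariance(ens)
  h1 <- covariance(subset_frames(ens, 1:2000))
  h2 <- covariance(subset_frames(ens, 2001:4000))
  expect_gte(covariance_overlap(h1, full), 0.7)
  expect_gte(covariance_overlap(h2, full), 0.7)
})

test_that("dRMSD matches hand-enumerated pairs and is rigid-invariant", {
  a <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(drmsd(a, a), 0)
  rot <- rotate_z_90(a) + 7
  expect_equal(drmsd(a, rot), 0, tolerance = 1e-12)
  b <- cbind(c(0, 2, 4), 0, 0)
  expect_equal(drmsd(a, b), sqrt((1 + 1 + 4) / 3), tolerance = 1e-12)
  expect_error(drmsd(a, b, atom_indices = 1), "at least 2 atoms")
})

test_that("essential spaces serialize and restore", {
  ens <- superpose(random_ensemble(12, 4, seed = 13))
  es <- essential_space(ens, k = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_essential_space(es, path)
  back <- read_essential_space(path)
  expect_equal(back$k, es$k)
  expect_equal(back$mean_coords, es$mean_coords, tolerance = 1e-9)
  expect_equal(back$eigenvalues, es$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(diag(crossprod(back$eigenvectors, es$eigenvectors))),
               rep(1, 12), tolerance = 1e-6)
})
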