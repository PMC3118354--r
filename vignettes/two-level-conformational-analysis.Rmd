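---
title: "Two-level conformational analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level conformational analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformap)
```

## The model

`conformap` treats a conformational ensemble as a cloud of points in the
`3N`-dimensional space of superposed Cα coordinates and asks two questions:
which recurring conformations does the ensemble visit, and how do several
related ensembles distribute over them. The answer is produced in two
stages.

**Stage 1 — Essential Dynamics.** After iterative least-squares
superposition (two fit-to-mean rounds, frame 1 as the initial reference),
the coordinate covariance matrix is diagonalised and each frame is replaced
by its projection onto the leading `k` eigenvectors, reconstructed in full
Cartesian space. The reconstruction — rather than the raw principal
component scores — is deliberate: descriptors keep their `3N` length (165
elements for a 55-residue domain at the default `k = 30`), units stay in
Ångström, and the filtering is exactly idempotent. The essential space
assumption is the usual one: functional motion is concentrated in the few
largest-variance collective directions, and what lies outside them is
high-frequency noise. Filtering can only shrink per-atom fluctuation, so
RMSF profiles computed after filtering have a better signal-to-noise ratio;
the package computes RMSF from whatever coordinates it is given, so both
the raw and the filtered convention are available (filtered is recommended
and used in the examples).

**Stage 2 — SOM plus linkage.** A self-organising map condenses the
filtered descriptors into `R_tot` prototype vectors on a 2-D lattice. The
prototypes, interpreted as protoclusters, are then merged by complete (or
average) linkage, and Mojena's rule picks the cluster count: the largest
`k` whose merge height exceeds `mean + z * sd` of all merge heights
(strict inequality, so a tree with all-equal heights yields a single
cluster). Each conformation inherits the cluster of its best-matching
neuron. The two-level construction is what gives the method its noise
tolerance: linkage operates on a few hundred prototypes instead of tens of
thousands of frames, and the SOM's topology-preserving averaging smooths
frame-level noise before any tree is built.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `k` (essential dimensions) | 30 | – | explains >80–90% of variance for domain-sized systems; 20–30 directions are 12–18% of a 165-dim space |
| `map_size` | 100 | neurons | the characterised range is 100–400; the grid side ratio follows `sqrt(λ1/λ2)` of the data |
| `radius` | 3 | lattice units | initial neighbourhood radius, decays linearly to 1 |
| `training_length` | 5000 | iterations (batch) / epochs (sequential) | characterised range 1000–5000 |
| `neighbour` | `gaussian` | – | `bubble` and `ep` are supported for the design protocol |
| `algorithm` | `batch` | – | batch is deterministic given the seed and much faster in R (BLAS-bound) |
| `alpha0`, `alpha_type` | 0.05, `inverse` | – | sequential mode only |
| `z` (Mojena) | 2.75 complete / 2.50 average | – | the values that give the most informative separation in this family of rules |
| Cressie–Read `λ` | 2/3 | – | the recommended member of the power-divergence family; `λ = 1` reproduces Pearson's χ² |
| GROMOS cutoff grid | 0.1–4.0 step 0.05 | Å | the 0.01–0.40 nm grid expressed in the package's Å convention |

The defaults for `map_size`, `radius`, `training_length` and `neighbour`
are the values the experimental-design protocol itself identifies as
optimal across single, paired and combined data sets; they are expected to
transfer to systems of comparable conformational complexity, with
`map_size` the first thing to re-tune when training-data variance grows.

## The design protocol

`run_design()` executes the built-in 36-run Taguchi plan (3 replicas per
run, one trained SOM per run × replica × data-set case) and scores each map
with the clustering-efficiency index: average within-cluster
prototype-to-centroid distance, normalised by the total neuron count so
maps of different sizes are comparable, divided by the average
centroid-to-overall-centroid separation. Lower is better, and the index is
invariant to a uniform rescaling of the prototypes. Scoring needs cluster
labels before any optimum exists, so each design map is clustered with the
method's final choice (complete linkage, `z = 2.75`); when Mojena returns a
single cluster — where the index is undefined — the response falls back to
a two-cluster cut.

Term selection is mixed forward/backward stepwise with partial F-tests at
`p = 0.05` in both directions. Categorical factors enter and leave as whole
dummy blocks, and the data-set case label joins the candidate pool whenever
at least two cases are present. One calibration note: the per-term entry
rate under a null response is `α` by construction, so with a pool of `p`
independent candidates the chance that a pure-noise response selects
nothing is `(1 − α)^p`, not `1 − α`. The test suite therefore checks
calibration per term (a single-candidate null simulation) and checks
*power* — recovery of a planted effect — against the full nine-candidate
pool.

`optimal_parameters()` minimises the fitted model over the tested grid of
the significant parameters, holding the rest at package defaults, and
`validate_optimum()` retrains at the optimum to compare actual with
predicted response.

## Sampling-rate validation

A level `n` summarises the trajectory by one uniformly drawn frame per
equal-width time interval (stratified, so no episode is over-weighted). A
map trained on the subsample is queried with the subsample and with the
full trajectory; the two hit distributions are compared by the Cressie–Read
test on the cells the full data populates, with `n_cells − 1` degrees of
freedom. A level is accepted only when all replicas pass, and the smallest
accepted level is the recommended sampling rate. Subsample mass on a cell
the full data never hits cannot occur when both queries use the same map
and the full data defines the support; if it is ever encountered (e.g. hit
vectors supplied from elsewhere), the test rejects with a warning rather
than treating the cell as evidence of fit.

## The synthetic generator

`synth_spec()`/`simulate_ensemble()` build a Cα-like self-avoiding bead
chain (3.8 Å bonds, 3.4 Å excluded volume) and displace it along a few
smooth collective modes: random per-atom fields Gaussian-smoothed along the
chain index, orthonormalised against each other *and against the six
rigid-body motions* of the reference, so superposition cannot absorb
planted variance. Conformational basins are offsets along these modes; a
hidden Markov state stays put with probability `stay_prob` (default 0.99,
giving ~100-frame dwell times at 1 ps spacing) and otherwise redraws from
the occupancy weights, which are therefore exactly the stationary law.
Isotropic Gaussian noise (default 0.3 Å per coordinate) sits on top.

Defaults — 55 atoms, 4000 frames, three basins separated by 10 Å in mode
space against ~1 Å within-basin amplitudes — are chosen so the planted
structure is unambiguous at the scale of a summarised 40 ns trajectory:
they emulate the statistical shape of such data (dimensionality, temporal
correlation, basin occupancy), not its physics. Passing tests demonstrate
that the pipeline recovers planted geometric/kinetic structure; they say
nothing about force fields, solvent effects, anharmonic basin shapes or
slow degrees of freedom a real trajectory may contain. Variant families
(`make_variant_set()`) share the reference and modes while scaling
amplitudes, emulating mutants whose flexibility differs in localised
regions.

## Numerical choices

- **Covariance divisor** is the frame count (population form), configurable
  to `n − 1`; with thousands of frames the difference is negligible, but the
  population form matches the time-average definition of the RMSF.
- **Covariance overlap** needs `tr((A^{1/2} B A^{1/2})^{1/2})`; this is
  computed as the nuclear norm of `B^{1/2} A^{1/2}`, which avoids cubing the
  condition number in a nested square root. Eigenvalues are clamped at zero
  before square roots, relative residuals below `1e-12` are treated as
  exact, and the result is clamped to `[0, 1]`.
- **SOM initialisation** draws prototypes uniformly within the per-dimension
  data range; all randomness (initialisation, presentation order,
  subsampling) derives from one integer seed, and identical inputs give
  bitwise-identical trained maps.
- **BMU ties** break to the lowest neuron index; ties in
  closest-frame-to-centroid break to the lowest frame index.
- **Radius schedule** decays linearly from the configured radius to 1 over
  the training schedule; a radius of 0 is honoured as "no neighbourhood",
  which reduces a batch step to per-cell means (the k-means limit) — useful
  as an oracle in testing.
- **Hexagonal wrapped shapes**: cylinder/toroid distances wrap the planar
  coordinates by the grid period; for hexagonal lattices with an odd row
  count the offset pattern is not perfectly seamless at the wrap — an
  approximation shared with common SOM implementations.
- **Empty neurons** keep their prototypes and participate in linkage (the
  tree is built on prototypes, not hit sets); they contribute no frames and
  an empty neuron-level representative list is a valid result, not an
  error.
- **Cluster ids** are renumbered by first appearance in frame order so
  output tables are stable across runs.
- **Degenerate inputs**: single-frame ensembles are rejected where a
  variance is needed; rank-deficient data fall back to a square SOM grid
  with a warning; frames with missing atoms are rejected rather than
  imputed, because the method assumes fixed dimensionality.
- **Grid planning** uses the classical side-ratio rule
  (`rows = round(sqrt(map_size * sqrt(λ1/λ2)))`), with both sides at least
  2 so a prime map size resolves to the nearest balanced grid rather than a
  strip.

## Problem sizes in the test suite

The suite validates the full-scale study conditions where they matter — the
end-to-end recovery test trains 100-neuron maps for 5000 batch iterations
on 4000-frame, 55-atom ensembles over five seeds — and uses smaller
configurations (tens of neurons, tens-to-hundreds of iterations) for
oracle-equivalence and property checks, where the property being tested is
size-independent. The design protocol is exercised in a reduced form (two
plan rows, one replica, one case) plus full-plan bookkeeping and
regression-stage simulations on synthetic responses over the complete
36 × 3 design.

## Known limitations

- Binary trajectory formats (XTC/TRR/DCD) are out of scope; convert to
  multi-model PDB, XYZ or plain matrices first.
- No mass weighting and no dihedral-space PCA; the essential space is
  Cartesian and Cα-based.
- Structural alignment across domains is consumed as an equivalence map,
  not computed.
- Sequential training is a faithful per-input loop and is practical at the
  recommended sampling rates (hundreds of conformations); batch mode is the
  default and scales to full trajectories.
- Geometrical clustering assumes structurally similar conformations share a
  free-energy basin; kinetic clustering, which does not, is a different
  method family and deliberately out of scope.
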