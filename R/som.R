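# Self-Organising Map engine: grid planning, initialization, batch and
# sequential training, hit counting and the clustering-efficiency index.

SOM_LATTICES <- c("hexagonal", "rectangular")
SOM_SHAPES <- c("sheet", "cylinder", "toroid")
SOM_ALGORITHMS <- c("batch", "sequential")
SOM_NEIGHBOURS <- c("gaussian", "bubble", "ep")
SOM_ALPHA_TYPES <- c("inverse", "linear", "power")

#' SOM training configuration
#'
#' Collects the tunable SOM hyperparameters. The defaults are the values the
#' experimental-design protocol identifies as optimal for conformational
#' ensembles (map size 100, radius 3, training length 5000, Gaussian
#' neighbourhood, batch learning). Map sizes outside `[100, 400]` are
#' accepted with a warning (the tested range); any size >= 4 works.
#'
#' @param map_size requested total neuron count.
#' @param lattice `"hexagonal"` or `"rectangular"`.
#' @param shape `"sheet"`, `"cylinder"` (columns wrap) or `"toroid"` (both
#'   axes wrap).
#' @param algorithm `"batch"` or `"sequential"`.
#' @param neighbour neighbourhood kernel: `"gaussian"`, `"bubble"` or `"ep"`
#'   (Epanechnikov).
#' @param alpha_type learning-rate schedule for sequential training:
#'   `"inverse"`, `"linear"` or `"power"`.
#' @param radius initial neighbourhood radius (lattice units); decays
#'   linearly to 1 over training. Radius 0 disables the neighbourhood
#'   (per-cell k-means behaviour in batch mode).
#' @param training_length batch iterations, or full data passes (epochs) for
#'   sequential training.
#' @param alpha0 starting learning rate in `(0, 1)` (sequential only).
#' @param seed integer seed governing initialization and presentation order.
#' @param warn_size emit the map-size range warning (default `TRUE`).
#' @return object of class `som_config`.
#' @export
som_config <- function(map_size = 100, lattice = "hexagonal", shape = "sheet",
                       algorithm = "batch", neighbour = "gaussian",
                       alpha_type = "inverse", radius = 3,
                       training_length = 5000, alpha0 = 0.05, seed = 1,
                       warn_size = TRUE) {
  lattice <- match.arg(lattice, SOM_LATTICES)
  shape <- match.arg(shape, SOM_SHAPES)
  algorithm <- match.arg(algorithm, SOM_ALGORITHMS)
  neighbour <- match.arg(neighbour, SOM_NEIGHBOURS)
  alpha_type <- match.arg(alpha_type, SOM_ALPHA_TYPES)
  if (map_size < 4) stopf("map_size must be at least 4")
  if (warn_size && (map_size < 100 || map_size > 400))
    warnf("map_size %d is outside the characterised range [100, 400]", map_size)
  if (radius < 0) stopf("radius must be >= 0")
  if (training_length < 1) stopf("training_length must be >= 1")
  if (alpha0 <= 0 || alpha0 >= 1) stopf("alpha0 must lie in (0, 1)")
  structure(list(map_size = as.integer(map_size), lattice = lattice,
                 shape = shape, algorithm = algorithm, neighbour = neighbour,
                 alpha_type = alpha_type, radius = radius,
                 training_length = as.integer(training_length),
                 alpha0 = alpha0, seed = as.integer(seed)),
            class = "som_config")
}

#' Choose grid dimensions for a map size
#'
#' The classical side-ratio rule: the grid side ratio approximates
#' `sqrt(lambda1 / lambda2)` of the data covariance, with
#' `rows = round(sqrt(map_size * ratio))` and `cols = round(map_size / rows)`,
#' both at least 2 (so a prime `map_size` resolves to the nearest balanced
#' pair rather than a degenerate strip).
#'
#' @param map_size requested neuron count (>= 4).
#' @param data numeric matrix (frames x d) used to estimate the eigenvalue
#'   ratio.
#' @return integer vector `c(rows, cols)` with `rows >= cols`.
#' @export
plan_grid <- function(map_size, data) {
  data <- as_descriptor_matrix(data)
  if (map_size < 4) stopf("map_size must be at least 4")
  if (nrow(data) < 2) stopf("need at least 2 frames to plan a grid")
  xc <- sweep(data, 2, colMeans(data))
  sv <- svd(xc, nu = 0, nv = 0)$d
  l1 <- sv[1]^2
  l2 <- if (length(sv) > 1) sv[2]^2 else 0
  if (l2 <= l1 * 1e-12) {
    warnf("rank-deficient data; falling back to a square grid")
    target <- 1
  } else target <- sqrt(l1 / l2)
  rows <- max(2L, as.integer(round(sqrt(map_size * target))))
  cols <- max(2L, as.integer(round(map_size / rows)))
  if (cols > rows) { tmp <- rows; rows <- cols; cols <- tmp }
  c(rows, cols)
}

# Planar neuron positions, row-major indexing. Odd rows of a hexagonal
# lattice are offset by 0.5 and rows are sqrt(3)/2 apart.
lattice_positions <- function(rows, cols, lattice) {
  r <- rep(seq_len(rows), each = cols) - 1L
  cc <- rep(seq_len(cols), times = rows) - 1L
  if (lattice == "hexagonal") {
    cbind(x = cc + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  } else cbind(x = as.numeric(cc), y = as.numeric(r))
}

#' Initialize a SOM
#'
#' Plans the grid from the data, places neurons on the lattice and draws each
#' prototype component uniformly within the data range (seeded).
#'
#' @param config a [som_config()].
#' @param data descriptor matrix (frames x d) or a [conf_ensemble()].
#' @param seed overrides `config$seed` when given.
#' @return object of class `som_map` with fields `prototypes`, `grid_rows`,
#'   `grid_cols`, `positions`, `config`, `trained`.
#' @export
som_init <- function(config, data, seed = config$seed) {
  data <- as_descriptor_matrix(data)
  if (nrow(data) < 1) stopf("data must be non-empty")
  dims <- plan_grid(config$map_size, data)
  rows <- dims[1]; cols <- dims[2]
  n <- rows * cols
  lo <- apply(data, 2, min); hi <- apply(data, 2, max)
  prot <- with_seed(seed, {
    matrix(stats::runif(n * ncol(data)), n, ncol(data)) *
      matrix(hi - lo, n, ncol(data), byrow = TRUE) +
      matrix(lo, n, ncol(data), byrow = TRUE)
  })
  structure(list(prototypes = prot, grid_rows = rows, grid_cols = cols,
                 positions = lattice_positions(rows, cols, config$lattice),
                 config = config, trained = FALSE),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("SOM: %d x %d %s %s grid, d = %d, %strained\n", x$grid_rows,
              x$grid_cols, x$config$lattice, x$config$shape,
              ncol(x$prototypes), if (x$trained) "" else "not "))
  invisible(x)
}

as_descriptor_matrix <- function(data) {
  if (inherits(data, "conf_ensemble")) data$xyz else as.matrix(data)
}

#' Lattice distance between two neurons
#'
#' Euclidean distance between planar lattice positions; `cylinder` maps wrap
#' the column axis (minimum of direct and wrapped displacement), `toroid`
#' maps wrap both axes, `sheet` maps wrap none.
#'
#' @param som a `som_map`.
#' @param i,j neuron indices (1-based, row-major).
#' @return numeric distance in lattice units.
#' @export
lattice_distance <- function(som, i, j) {
  lattice_distance_matrix(som)[i, j]
}

# Full n x n lattice distance matrix (cached on the map object by train).
lattice_distance_matrix <- function(som) {
  if (!is.null(som$latdist)) return(som$latdist)
  pos <- som$positions
  px <- som$grid_cols * 1.0
  py <- som$grid_rows * (if (som$config$lattice == "hexagonal") sqrt(3) / 2 else 1.0)
  dx <- abs(outer(pos[, 1], pos[, 1], `-`))
  dy <- abs(outer(pos[, 2], pos[, 2], `-`))
  if (som$config$shape %in% c("cylinder", "toroid")) dx <- pmin(dx, px - dx)
  if (som$config$shape == "toroid") dy <- pmin(dy, py - dy)
  sqrt(dx^2 + dy^2)
}

#' Neighbourhood kernel weight
#'
#' @param kind `"gaussian"`, `"bubble"` or `"ep"`.
#' @param lattice_dist non-negative lattice distance(s).
#' @param radius_t current neighbourhood radius (> 0).
#' @return weight(s) in `[0, 1]`.
#' @export
neighbourhood_weight <- function(kind, lattice_dist, radius_t) {
  kind <- match.arg(kind, SOM_NEIGHBOURS)
  if (any(lattice_dist < 0)) stopf("lattice distances must be >= 0")
  if (radius_t <= 0) stopf("radius_t must be > 0")
  switch(kind,
         gaussian = exp(-lattice_dist^2 / (2 * radius_t^2)),
         bubble = (lattice_dist <= radius_t) * 1.0,
         ep = pmax(0, 1 - lattice_dist^2 / radius_t^2))
}

#' Learning-rate schedule
#'
#' `linear`: `alpha0 (1 - t/T)`; `power`: `alpha0 (0.005/alpha0)^(t/T)`;
#' `inverse`: `alpha0 C / (C + t)` with `C = T/100`.
#'
#' @param kind schedule name.
#' @param alpha0 starting rate (> 0).
#' @param t 0-based step, `0 <= t < T`.
#' @param T total number of steps.
#' @return learning rate in `(0, alpha0]`.
#' @export
alpha_schedule <- function(kind, alpha0, t, T) {
  kind <- match.arg(kind, SOM_ALPHA_TYPES)
  if (alpha0 <= 0) stopf("alpha0 must be > 0")
  stopifnot(all(t >= 0), all(t < T))
  switch(kind,
         linear = alpha0 * (1 - t / T),
         power = alpha0 * (0.005 / alpha0)^(t / T),
         inverse = alpha0 * (T / 100) / (T / 100 + t))
}

#' Best matching unit(s)
#'
#' Index of the prototype nearest (Euclidean) to the input; ties broken by
#' the lowest neuron index. Given a matrix, returns one index per row.
#'
#' @param som a `som_map`.
#' @param x numeric vector of length d, or a (frames x d) matrix / ensemble.
#' @return integer index or vector of indices.
#' @export
bmu <- function(som, x) {
  x <- if (is.matrix(x) || inherits(x, "conf_ensemble"))
    as_descriptor_matrix(x) else matrix(x, nrow = 1)
  if (any(!is.finite(x))) stopf("input vectors must be finite")
  if (ncol(x) != ncol(som$prototypes))
    stopf("input dimension %d does not match map dimension %d", ncol(x),
          ncol(som$prototypes))
  idx <- bmu_core(som$prototypes, x)
  if (nrow(x) == 1) idx[1] else idx
}

bmu_core <- function(prototypes, x) {
  m2 <- rowSums(prototypes^2)
  # squared distance = |x|^2 - 2 x.m + |m|^2; |x|^2 constant per row
  score <- x %*% t(prototypes) - matrix(m2 / 2, nrow(x), nrow(prototypes),
                                        byrow = TRUE)
  max.col(score, ties.method = "first")
}

#' Train a SOM
#'
#' Batch mode performs `training_length` rounds of neighbourhood-weighted
#' mean updates; sequential mode performs `training_length` full passes over
#' the data in a freshly seeded random order per epoch, pulling the winner
#' and its lattice neighbours towards each input by
#' `alpha(t) * h(lattice distance, radius(t))`. In both modes the
#' neighbourhood radius decays linearly from `config$radius` to 1 over the
#' schedule (a radius of 0 stays 0, reducing batch mode to per-cell means).
#'
#' @param som a `som_map` from [som_init()].
#' @param data descriptor matrix (frames x d) or [conf_ensemble()] matching
#'   the map dimension.
#' @param config overrides `som$config` when given.
#' @return the trained `som_map` (with the lattice distance matrix cached).
#' @export
som_train <- function(som, data, config = som$config) {
  data <- as_descriptor_matrix(data)
  if (nrow(data) < 1) stopf("training data must be non-empty")
  if (ncol(data) != ncol(som$prototypes))
    stopf("data dimension %d does not match map dimension %d", ncol(data),
          ncol(som$prototypes))
  som$config <- config
  som$latdist <- lattice_distance_matrix(som)
  som <- if (config$algorithm == "batch") train_batch(som, data)
         else train_sequential(som, data)
  som$trained <- TRUE
  som
}

radius_at <- function(r0, t, T) {
  if (r0 <= 0) return(0)
  if (T <= 1) return(max(r0, 1))
  if (r0 <= 1) return(r0)
  r0 - (r0 - 1) * (t / (T - 1))
}

train_batch <- function(som, data) {
  M <- som$prototypes
  n_neurons <- nrow(M)
  L <- som$config$training_length
  S <- matrix(0, n_neurons, ncol(M))
  for (it in seq_len(L)) {
    win <- bmu_core(M, data)
    S[] <- 0
    part <- rowsum(data, win)
    S[as.integer(rownames(part)), ] <- part
    counts <- tabulate(win, nbins = n_neurons)
    r_t <- radius_at(som$config$radius, it - 1, L)
    if (r_t <= 0) {
      upd <- counts > 0
      M[upd, ] <- S[upd, , drop = FALSE] / counts[upd]
    } else {
      K <- neighbourhood_weight(som$config$neighbour, som$latdist, r_t)
      num <- K %*% S
      den <- as.numeric(K %*% counts)
      upd <- den > 0
      M[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
    if (any(!is.finite(M)))
      stopf("non-finite prototype update at batch iteration %d", it)
  }
  som$prototypes <- M
  som
}

train_sequential <- function(som, data) {
  M <- som$prototypes
  n <- nrow(data)
  cfg <- som$config
  epochs <- cfg$training_length
  Ttot <- epochs * n
  with_seed(derive_seed(cfg$seed, "sequential-order"), {
    t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        x <- data[i, ]
        w <- bmu_core(M, matrix(x, nrow = 1))[1]
        r_t <- max(radius_at(cfg$radius, t, Ttot), 1e-8)
        a_t <- alpha_schedule(cfg$alpha_type, cfg$alpha0, t, Ttot)
        hw <- a_t * neighbourhood_weight(cfg$neighbour, som$latdist[w, ], r_t)
        act <- which(hw > 1e-12)
        M[act, ] <- M[act, , drop = FALSE] +
          hw[act] * (matrix(x, length(act), ncol(M), byrow = TRUE) -
                       M[act, , drop = FALSE])
        if (any(!is.finite(M[act, ])))
          stopf("non-finite prototype update at step %d", t)
        t <- t + 1
      }
    }
  })
  som$prototypes <- M
  som
}

#' Hit vector of a trained map
#'
#' Per-neuron counts of data vectors won (BMU) by the neuron; counts always
#' sum to the number of presented vectors.
#'
#' @param som a trained `som_map`.
#' @param data descriptor matrix or ensemble.
#' @return object of class `hit_vector`: list with `counts` and `total`.
#' @export
som_hits <- function(som, data) {
  data <- as_descriptor_matrix(data)
  win <- bmu_core(som$prototypes, data)
  counts <- tabulate(win, nbins = nrow(som$prototypes))
  structure(list(counts = counts, total = nrow(data)), class = "hit_vector")
}

#' Mean quantization error of a map on data
#' @param som a `som_map`.
#' @param data descriptor matrix or ensemble.
#' @return mean Euclidean distance from each vector to its BMU prototype.
#' @export
som_quantization_error <- function(som, data) {
  data <- as_descriptor_matrix(data)
  win <- bmu_core(som$prototypes, data)
  mean(sqrt(rowSums((data - som$prototypes[win, , drop = FALSE])^2)))
}

#' Clustering-efficiency index of a labelled map
#'
#' Ratio of average cluster tightness to centroid separation:
#' `P = [(1/R_tot) sum_j sum_{i in C_j} d(w_ij, mu_j)] /
#' [(1/J) sum_j d(mu_j, mu)]` with `R_tot` the total neuron count, `mu_j`
#' the cluster centroids of the prototype vectors, `mu` the overall
#' prototype centroid and `d` the Euclidean distance. The tightness term is
#' normalized by the map size so maps of different sizes are comparable.
#' Lower is better; the index is invariant to a uniform rescaling of the
#' prototypes.
#'
#' @param som a trained `som_map`.
#' @param neuron_labels integer cluster id per neuron (>= 2 distinct).
#' @return non-negative scalar.
#' @export
performance_index <- function(som, neuron_labels) {
  M <- som$prototypes
  stopifnot(length(neuron_labels) == nrow(M))
  labs <- sort(unique(neuron_labels))
  if (length(labs) < 2) stopf("performance index needs at least 2 clusters")
  grp <- match(neuron_labels, labs)
  centroids <- rowsum(M, grp) / tabulate(grp, length(labs))
  mu <- colMeans(M)
  tight <- sum(sqrt(rowSums((M - centroids[grp, , drop = FALSE])^2))) / nrow(M)
  sep <- mean(sqrt(rowSums(sweep(centroids, 2, mu)^2)))
  if (sep <= 0) stopf("performance index undefined: all cluster centroids coincide")
  tight / sep
}

#' Serialize / deserialize a SOM
#'
#' JSON document holding the configuration, grid dimensions, prototypes and
#' (optionally) hit counts.
#'
#' @param som a `som_map`.
#' @param path file path.
#' @param hits optional `hit_vector` to embed.
#' @return `path` invisibly; the reader returns a `som_map`.
#' @export
write_som <- function(som, path, hits = NULL) {
  doc <- list(config = unclass(som$config), grid_rows = som$grid_rows,
              grid_cols = som$grid_cols, trained = som$trained,
              prototypes = som$prototypes)
  if (!is.null(hits)) doc$hits <- hits$counts
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(som_config, c(doc$config, list(warn_size = FALSE)))
  som <- structure(list(prototypes = doc$prototypes,
                        grid_rows = doc$grid_rows, grid_cols = doc$grid_cols,
                        positions = lattice_positions(doc$grid_rows, doc$grid_cols,
                                                      cfg$lattice),
                        config = cfg, trained = isTRUE(doc$trained)),
                   class = "som_map")
  som
}
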