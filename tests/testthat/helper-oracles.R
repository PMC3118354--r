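# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately use naive loops, not the package's vectorized paths.

test_config <- function(...) som_config(..., warn_size = FALSE)

# Exactly isotropic toy data (covariance proportional to identity).
iso_data <- function() {
  rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
        c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
}

random_ensemble <- function(n_frames, n_atoms, seed = 1, sd = 1) {
  set.seed(seed)
  conf_ensemble(matrix(rnorm(n_frames * 3 * n_atoms, sd = sd), n_frames))
}

random_psd <- function(d, seed, rank = d) {
  set.seed(seed)
  m <- matrix(rnorm(d * rank), d, rank)
  tcrossprod(m)
}

# Naive covariance: double loop over coordinate pairs, divisor n.
naive_covariance <- function(xyz) {
  n <- nrow(xyz); d <- ncol(xyz)
  mu <- colMeans(xyz)
  out <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    out[i, j] <- sum((xyz[, i] - mu[i]) * (xyz[, j] - mu[j])) / n
  out
}

naive_rmsf <- function(xyz) {
  n_atoms <- ncol(xyz) / 3
  out <- numeric(n_atoms)
  for (a in seq_len(n_atoms)) {
    cols <- (3 * a - 2):(3 * a)
    mu <- colMeans(xyz[, cols, drop = FALSE])
    disp2 <- apply(xyz[, cols, drop = FALSE], 1, function(r) sum((r - mu)^2))
    out[a] <- sqrt(mean(disp2))
  }
  out
}

# O(n^3) agglomerative clustering oracle returning merge heights in order.
naive_linkage_heights <- function(x, method) {
  D <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    if (method == "complete") max(vals) else mean(vals)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Direct greedy re-implementation of GROMOS nearest-neighbour clustering.
naive_gromos <- function(x, cutoff) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  labels <- integer(n); remaining <- seq_len(n); cl <- 0L
  while (length(remaining)) {
    cl <- cl + 1L
    counts <- sapply(remaining, function(i)
      sum(D[i, remaining] <= cutoff) - 1L)
    centre <- remaining[which.max(counts)]
    members <- remaining[D[centre, remaining] <= cutoff]
    members <- union(centre, members)
    labels[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  labels
}

# Textbook per-point silhouette (singletons scored 0).
naive_silhouette <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  sapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl])))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  })
}

naive_davies_bouldin <- function(x, labels) {
  ids <- sort(unique(labels))
  cents <- t(sapply(ids, function(cl) colMeans(x[labels == cl, , drop = FALSE])))
  sig <- sapply(seq_along(ids), function(i) {
    m <- x[labels == ids[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cents[i, ])^2)))
  })
  mean(sapply(seq_along(ids), function(i) {
    max(sapply(seq_along(ids)[-i], function(j)
      (sig[i] + sig[j]) / sqrt(sum((cents[i, ] - cents[j, ])^2))))
  }))
}

pearson_statistic <- function(h, H) {
  keep <- H > 0
  e <- H[keep] * sum(h) / sum(H)
  sum((h[keep] - e)^2 / e)
}

# Two well-separated Gaussian blobs in d dimensions.
blob_data <- function(n_per = 30, d = 5, sep = 20, sigma = 1, seed = 1) {
  set.seed(seed)
  centres <- rbind(rep(0, d), c(sep, rep(0, d - 1)))
  x <- rbind(matrix(rnorm(n_per * d, sd = sigma), n_per) ,
             matrix(rnorm(n_per * d, sd = sigma), n_per) +
               matrix(centres[2, ], n_per, d, byrow = TRUE))
  list(x = x, labels = rep(1:2, each = n_per), centres = centres)
}

write_test_pdb <- function(path, n_models = 3, n_res = 5, drop_last_ca = FALSE) {
  lines <- character(0)
  set.seed(4)
  base <- matrix(rnorm(n_res * 3, sd = 5), n_res, 3)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    coords <- base + 0.1 * m
    n_keep <- if (drop_last_ca && m == 2) n_res - 1 else n_res
    for (r in seq_len(n_keep)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        r, r, coords[r, 1], coords[r, 2], coords[r, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
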