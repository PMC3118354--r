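# Baselines for method comparison: GROMOS nearest-neighbour clustering and
# the Silhouette / Davies-Bouldin cluster validity indices.

#' GROMOS nearest-neighbour clustering
#'
#' Greedy medoid algorithm: the point with the largest neighbourhood within
#' the distance cutoff defines the first cluster (itself plus its
#' neighbours); these points are removed and the step is iterated until all
#' points are assigned. Labels are numbered in formation order, so cluster
#' sizes are non-increasing. Ties on neighbourhood size go to the lowest
#' point index.
#'
#' @param data descriptor matrix (rows = conformations), [conf_ensemble()],
#'   or a `dist` object.
#' @param cutoff neighbourhood distance cutoff (> 0), in the descriptor's
#'   length unit (Angstrom for coordinate descriptors; a 0.01-0.40 nm grid
#'   corresponds to 0.1-4.0 here).
#' @return integer label vector.
#' @export
gromos_cluster <- function(data, cutoff) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  D <- if (inherits(data, "dist")) as.matrix(data)
       else as.matrix(stats::dist(as_descriptor_matrix(data)))
  n <- nrow(D)
  nb <- D <= cutoff
  diag(nb) <- FALSE
  labels <- integer(n)
  active <- rep(TRUE, n)
  cl <- 0L
  while (any(active)) {
    cl <- cl + 1L
    act_idx <- which(active)
    counts <- colSums(nb[act_idx, act_idx, drop = FALSE])
    centre <- act_idx[which.max(counts)]
    members <- unique(c(centre, act_idx[nb[centre, act_idx]]))
    labels[members] <- cl
    active[members] <- FALSE
  }
  labels
}

#' Silhouette index
#'
#' Standard silhouette on Euclidean distances: for point i with
#' within-cluster mean distance `a` and smallest other-cluster mean distance
#' `b`, `s = (b - a) / max(a, b)`. Points in singleton clusters score 0, as
#' do points where `a = b = 0`. Cluster and overall values are means of the
#' point values.
#'
#' @param data descriptor matrix, ensemble, or `dist`.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @param level `"overall"` (scalar), `"cluster"` (named vector) or
#'   `"point"`.
#' @return numeric value(s) in `[-1, 1]`.
#' @export
silhouette_index <- function(data, labels, level = c("overall", "cluster", "point")) {
  level <- match.arg(level)
  D <- if (inherits(data, "dist")) as.matrix(data)
       else as.matrix(stats::dist(as_descriptor_matrix(data)))
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stopf("silhouette undefined for a single cluster")
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cl_ids <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1)
    b <- min(vapply(cl_ids[cl_ids != labels[i]], function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  switch(level,
         point = s,
         cluster = vapply(split(s, labels), mean, numeric(1)),
         overall = mean(s))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' `(sigma_i + sigma_j) / d(c_i, c_j)`, where `sigma` is the mean distance
#' of a cluster's points to its centroid and `d` the centroid separation.
#' Lower values indicate more compact, better separated clusters; coincident
#' centroids yield `Inf` with a warning.
#'
#' @param data descriptor matrix or ensemble.
#' @param labels cluster labels (>= 2 clusters).
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(data, labels) {
  X <- as_descriptor_matrix(data)
  labels <- as.integer(factor(labels))
  ids <- sort(unique(labels))
  if (length(ids) < 2) stopf("Davies-Bouldin undefined for a single cluster")
  centroids <- t(vapply(ids, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  sig <- vapply(ids, function(cl) {
    m <- X[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums((m - matrix(centroids[cl, ], nrow(m), ncol(X),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(centroids))
  if (any(dc[upper.tri(dc)] == 0))
    warnf("coincident cluster centroids; Davies-Bouldin is infinite")
  r <- vapply(seq_along(ids), function(i) {
    max(vapply(seq_along(ids)[-i], function(j)
      (sig[i] + sig[j]) / dc[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Scan GROMOS cutoffs for the best solution per cluster count
#'
#' Runs [gromos_cluster()] over a cutoff grid and keeps, for each requested
#' number of clusters, the best solution (by the chosen quality index) among
#' the cutoffs that produce exactly that count.
#'
#' @param data descriptor matrix or ensemble.
#' @param k_range cluster counts of interest (default 2 to 15).
#' @param cutoffs cutoff grid; the default is the 0.1-4.0 Angstrom grid in
#'   steps of 0.05 (79 values).
#' @param index `"silhouette"` (maximized) or `"db"` (minimized).
#' @return data.frame per k: availability, chosen cutoff, silhouette and
#'   Davies-Bouldin values; class `quality_report`.
#' @export
gromos_scan <- function(data, k_range = 2:15, cutoffs = seq(0.1, 4.0, by = 0.05),
                        index = c("silhouette", "db")) {
  index <- match.arg(index)
  X <- as_descriptor_matrix(data)
  D <- stats::dist(X)
  sols <- lapply(cutoffs, function(co) gromos_cluster(D, co))
  ks <- vapply(sols, function(l) length(unique(l)), integer(1))
  rows <- lapply(k_range, function(k) {
    hit <- which(ks == k)
    if (!length(hit))
      return(data.frame(k = k, available = FALSE, cutoff = NA_real_,
                        silhouette = NA_real_, db = NA_real_))
    svals <- vapply(hit, function(i) silhouette_index(D, sols[[i]]), numeric(1))
    dvals <- vapply(hit, function(i)
      suppressWarnings(davies_bouldin(X, sols[[i]])), numeric(1))
    best <- if (index == "silhouette") hit[which.max(svals)] else hit[which.min(dvals)]
    pos <- match(best, hit)
    data.frame(k = k, available = TRUE, cutoff = cutoffs[best],
               silhouette = svals[pos], db = dvals[pos])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quality_report", class(out))
  out
}

#' Compare clustering methods by validity indices
#'
#' Evaluates the two-level approach (`som_complete`, `som_average`: linkage
#' on SOM prototypes, conformations labelled through their BMUs) against
#' plain complete/average linkage on the conformation descriptors and
#' GROMOS, for each cluster count in `k_range`, scoring every labelling
#' with the Silhouette and Davies-Bouldin indices on the conformations.
#'
#' @param data descriptor matrix or ensemble.
#' @param methods subset of `c("som_complete", "som_average", "complete",
#'   "average", "gromos")`.
#' @param k_range cluster counts.
#' @param som a trained `som_map` for the SOM variants; trained on `data`
#'   with `config` when `NULL`.
#' @param config [som_config()] used when training is needed.
#' @param cutoffs GROMOS cutoff grid.
#' @return data.frame (method, k, silhouette, db, params); class
#'   `quality_report`.
#' @export
compare_methods <- function(data, methods = c("som_complete", "som_average",
                                              "complete", "average", "gromos"),
                            k_range = 2:15, som = NULL,
                            config = som_config(warn_size = FALSE),
                            cutoffs = seq(0.1, 4.0, by = 0.05)) {
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as_descriptor_matrix(data)
  D <- stats::dist(X)
  need_som <- any(grepl("^som_", methods))
  if (need_som && is.null(som)) som <- som_train(som_init(config, X), X)
  rows <- list()
  score <- function(labels) {
    if (length(unique(labels)) < 2) return(c(NA_real_, NA_real_))
    c(silhouette_index(D, labels), suppressWarnings(davies_bouldin(X, labels)))
  }
  for (m in methods) {
    if (m == "gromos") {
      rep_g <- gromos_scan(X, k_range, cutoffs)
      for (i in seq_len(nrow(rep_g)))
        rows[[length(rows) + 1]] <- data.frame(
          method = "gromos", k = rep_g$k[i], silhouette = rep_g$silhouette[i],
          db = rep_g$db[i],
          params = ifelse(rep_g$available[i],
                          sprintf("cutoff=%.3g", rep_g$cutoff[i]), "unavailable"))
      next
    }
    if (m %in% c("complete", "average")) {
      hc <- stats::hclust(D, method = m)
      for (k in k_range) {
        sc <- score(stats::cutree(hc, k = k))
        rows[[length(rows) + 1]] <- data.frame(method = m, k = k,
                                               silhouette = sc[1], db = sc[2],
                                               params = "")
      }
      next
    }
    link <- sub("^som_", "", m)
    tree <- linkage_prototypes(som, link)
    for (k in k_range) {
      sol <- cut_and_assign(som, tree, k, X)
      sc <- score(sol$conformation_labels)
      rows[[length(rows) + 1]] <- data.frame(method = m, k = k,
                                             silhouette = sc[1], db = sc[2],
                                             params = "")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quality_report", class(out))
  out
}
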