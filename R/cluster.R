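# Second level of the two-level approach: hierarchical clustering of SOM
# prototype vectors, Mojena's stopping rule, assignment of conformations to
# clusters through their BMUs, and representative extraction.

#' Hierarchical clustering of SOM prototype vectors
#'
#' Agglomerative clustering (Euclidean distance) of the prototype vectors,
#' treating each neuron as a "protocluster". Empty neurons still take part:
#' the tree is built on prototypes, not on hit sets.
#'
#' @param som a trained `som_map`.
#' @param method `"complete"` or `"average"` linkage.
#' @return object of class `linkage_tree` wrapping the `hclust` result, with
#'   `method` and `leaves`.
#' @export
linkage_prototypes <- function(som, method = c("complete", "average")) {
  method <- match.arg(method)
  if (nrow(som$prototypes) < 2) stopf("need at least 2 neurons")
  hc <- stats::hclust(stats::dist(som$prototypes), method = method)
  structure(list(hclust = hc, method = method, leaves = nrow(som$prototypes)),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("Linkage tree: %d leaves, %s linkage, merge heights %.3g - %.3g\n",
              x$leaves, x$method, min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Number of clusters by Mojena's stopping rule
#'
#' Let `h(k)` be the height of the merge that reduces `k` clusters to
#' `k - 1`, and let the mean and standard deviation be taken over all merge
#' heights of the tree. The rule returns the largest `k` with
#' `h(k) > mean + z * sd` (strict), or 1 when no `k` qualifies. The returned
#' `k` is non-increasing in `z`.
#'
#' @param tree a [linkage_prototypes()] result (or an `hclust`).
#' @param z threshold constant (> 0); 2.75 is the recommended value for
#'   complete linkage, 2.50 for average linkage.
#' @return integer number of clusters.
#' @export
mojena_k <- function(tree, z) {
  hc <- if (inherits(tree, "linkage_tree")) tree$hclust else tree
  if (z <= 0) stopf("z must be > 0")
  h <- hc$height
  L <- length(h) + 1L
  thresh <- mean(h) + z * stats::sd(h)
  if (is.na(thresh)) return(1L)   # single merge: sd undefined
  ks <- 2:L
  qual <- h[L - ks + 1L] > thresh
  if (!any(qual)) 1L else max(ks[qual])
}

#' Cut the tree and assign conformations
#'
#' Cuts the prototype tree into `k` neuron groups; every conformation then
#' inherits the group of its best-matching neuron. Cluster ids are
#' renumbered by first appearance in frame order; neuron-only clusters (no
#' hits) are numbered after those. Per-cluster centroids are means of the
#' member prototype vectors, and the centroid frame is the conformation
#' closest to that centroid (ties to the lowest frame index).
#'
#' @param som a trained `som_map`.
#' @param tree a [linkage_prototypes()] result.
#' @param k number of clusters, `1 <= k <= leaves`.
#' @param data the conformations: descriptor matrix or [conf_ensemble()].
#' @param z_used optional record of the Mojena constant that produced `k`.
#' @return object of class `cluster_solution` with `neuron_labels`,
#'   `conformation_labels`, `bmu`, `k`, `z_used`, `centroid_frames`,
#'   `cluster_neurons`, `source_labels`, `times`, plus the prototype and
#'   descriptor matrices needed for representative extraction.
#' @export
cut_and_assign <- function(som, tree, k, data, z_used = NA_real_) {
  if (k < 1 || k > tree$leaves) stopf("k must lie in [1, %d]", tree$leaves)
  X <- as_descriptor_matrix(data)
  memb <- if (k == tree$leaves) seq_len(tree$leaves)
          else stats::cutree(tree$hclust, k = k)
  win <- bmu_core(som$prototypes, X)
  raw <- memb[win]
  # renumber by first appearance in frame order, unseen groups afterwards
  seen <- unique(raw)
  rest <- setdiff(sort(unique(memb)), seen)
  remap <- stats::setNames(seq_along(c(seen, rest)), c(seen, rest))
  conf_labels <- as.integer(remap[as.character(raw)])
  neuron_labels <- as.integer(remap[as.character(memb)])
  cluster_ids <- sort(unique(neuron_labels))
  centroids <- t(vapply(cluster_ids, function(cl) {
    colMeans(som$prototypes[neuron_labels == cl, , drop = FALSE])
  }, numeric(ncol(X))))
  centroid_frames <- vapply(cluster_ids, function(cl) {
    members <- which(conf_labels == cl)
    if (!length(members)) return(NA_integer_)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(centroids[cl, ], length(members), ncol(X),
                            byrow = TRUE))^2)
    members[which.min(d2)]
  }, integer(1))
  if (inherits(data, "conf_ensemble")) {
    src <- data$source_labels; times <- data$times
  } else {
    src <- rep("data", nrow(X)); times <- seq_len(nrow(X)) - 1
  }
  structure(list(neuron_labels = neuron_labels, conformation_labels = conf_labels,
                 bmu = win, k = as.integer(k), z_used = z_used,
                 centroid_frames = stats::setNames(centroid_frames, cluster_ids),
                 cluster_neurons = split(seq_along(neuron_labels), neuron_labels),
                 centroids = centroids, prototypes = som$prototypes,
                 descriptors = X, source_labels = src, times = times),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d over %d frames / %d neurons",
              x$k, length(x$conformation_labels), length(x$neuron_labels)))
  if (!is.na(x$z_used)) cat(sprintf(" (Mojena z = %.2f)", x$z_used))
  cat("\n")
  print(table(cluster = x$conformation_labels))
  invisible(x)
}

#' Run the full two-level clustering of a trained map
#'
#' Convenience wrapper: linkage of the prototypes, Mojena's rule, cut and
#' assignment.
#'
#' @param som a trained `som_map`.
#' @param data conformations presented to the map.
#' @param method linkage criterion.
#' @param z Mojena constant; default 2.75 for complete linkage and 2.50 for
#'   average.
#' @param k forced cluster count, overriding Mojena when given.
#' @return a `cluster_solution`.
#' @export
two_level_cluster <- function(som, data, method = c("complete", "average"),
                              z = NULL, k = NULL) {
  method <- match.arg(method)
  z <- z %||% (if (method == "complete") 2.75 else 2.50)
  tree <- linkage_prototypes(som, method)
  if (is.null(k)) k <- mojena_k(tree, z)
  cut_and_assign(som, tree, k, data, z_used = z)
}

#' Representative conformations of a solution
#'
#' Three granularities: `neuron` — all frames won by one neuron; `cluster` —
#' for each member neuron with hits, the single frame closest to its
#' prototype; `centroid` — the one frame closest to the cluster centroid.
#'
#' @param solution a `cluster_solution`.
#' @param level `"neuron"`, `"cluster"` or `"centroid"`.
#' @param id neuron index (`neuron` level) or cluster id.
#' @return integer vector of frame indices (possibly empty at neuron level).
#' @export
representatives <- function(solution, level = c("neuron", "cluster", "centroid"),
                            id) {
  level <- match.arg(level)
  if (level == "neuron") {
    if (id < 1 || id > length(solution$neuron_labels)) stopf("invalid neuron id")
    return(which(solution$bmu == id))
  }
  if (!id %in% solution$conformation_labels && level == "centroid")
    stopf("cluster %s has no member frames", id)
  if (level == "centroid") {
    return(unname(solution$centroid_frames[as.character(id)]))
  }
  # cluster level: one closest hit frame per member neuron
  neurons <- which(solution$neuron_labels == id)
  out <- integer(0)
  for (nr in neurons) {
    hits <- which(solution$bmu == nr)
    if (!length(hits)) next
    d2 <- rowSums((solution$descriptors[hits, , drop = FALSE] -
                     matrix(solution$prototypes[nr, ], length(hits),
                            ncol(solution$descriptors), byrow = TRUE))^2)
    out <- c(out, hits[which.min(d2)])
  }
  out
}

#' Per-source cluster composition table
#'
#' For each source trajectory, the percentage of its conformations falling
#' in each cluster; rows sum to 100. The transposed (per-cluster) view is
#' attached as attribute `"per_cluster"`.
#'
#' @param solution a `cluster_solution`.
#' @param source_labels overrides the labels stored in the solution.
#' @return matrix (sources x clusters) of percentages.
#' @export
composition_table <- function(solution, source_labels = solution$source_labels) {
  stopifnot(length(source_labels) == length(solution$conformation_labels))
  tab <- table(source = source_labels, cluster = solution$conformation_labels)
  pct <- sweep(unclass(tab), 1, rowSums(tab), `/`) * 100
  cpct <- sweep(unclass(tab), 2, colSums(tab), `/`) * 100
  attr(pct, "per_cluster") <- cpct
  pct
}

#' Plot-data export of a clustered map
#'
#' One record per neuron: planar lattice position, cluster id, hit count,
#' hit size normalised to the most-populated neuron, and prototype norm —
#' sufficient to redraw the hexagon map with population-sized markers.
#'
#' @param som a trained `som_map`.
#' @param solution a `cluster_solution` for this map.
#' @param hits a `hit_vector` from [som_hits()].
#' @param path optional path; when given the document is written as JSON.
#' @return data.frame of per-neuron records.
#' @export
map_export <- function(som, solution, hits, path = NULL) {
  n <- nrow(som$prototypes)
  stopifnot(length(solution$neuron_labels) == n, length(hits$counts) == n)
  df <- data.frame(neuron = seq_len(n),
                   x = som$positions[, 1], y = som$positions[, 2],
                   cluster = solution$neuron_labels,
                   hits = hits$counts,
                   hit_size = if (max(hits$counts) > 0)
                     hits$counts / max(hits$counts) else 0,
                   prototype_norm = sqrt(rowSums(som$prototypes^2)))
  if (!is.null(path))
    jsonlite::write_json(list(grid_rows = som$grid_rows,
                              grid_cols = som$grid_cols,
                              lattice = som$config$lattice,
                              neurons = df),
                         path, auto_unbox = TRUE, digits = NA)
  df
}
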