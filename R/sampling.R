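# Sampling-rate validation: stratified trajectory subsampling and the
# Cressie-Read goodness-of-fit test on SOM hit distributions.

#' Stratified subsample of a trajectory
#'
#' Splits the trajectory time span into `n` equal-width intervals and draws
#' one frame uniformly at random from each, preserving chronological order.
#' Sampling one frame per interval (rather than n frames at random) avoids a
#' correlation bias towards densely sampled episodes.
#'
#' @param ensemble a [conf_ensemble()].
#' @param n number of intervals / frames to draw, `1 <= n <= frames`.
#' @param seed integer seed.
#' @return subsampled [conf_ensemble()] with attribute `"frame_idx"` giving
#'   the original frame indices.
#' @export
stratified_sample <- function(ensemble, n, seed = 1) {
  if (n < 1 || n > ensemble$n_frames)
    stopf("n must lie in [1, %d]", ensemble$n_frames)
  tt <- ensemble$times
  span <- range(tt)
  # interval i covers [lo + (i-1) w, lo + i w); the last is closed above
  w <- (span[2] - span[1]) / n
  bin <- if (w > 0) pmin(floor((tt - span[1]) / w) + 1L, n) else rep(1L, length(tt))
  idx <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      members <- which(bin == i)
      if (!length(members))
        stopf("interval %d of %d contains no frames (n too large?)", i, n)
      if (length(members) == 1) members else sample(members, 1)
    }, integer(1))
  })
  idx <- sort(idx)
  out <- subset_frames(ensemble, idx)
  attr(out, "frame_idx") <- idx
  out
}

#' Cressie-Read goodness-of-fit test between two hit vectors
#'
#' Compares a subsample's hit distribution `h` against the full-data hit
#' distribution `H` on the same map. Cells with `H > 0` are retained;
#' expected counts are `e_c = H_c (h_tot / H_tot)` and the power-divergence
#' statistic `(2 / (lambda (lambda + 1))) sum_c h_c ((h_c / e_c)^lambda - 1)`
#' is referred to a chi-square with `retained cells - 1` degrees of freedom.
#' `lambda = 2/3` is the recommended member of the family; `lambda = 1`
#' recovers the Pearson chi-square. Any `h` mass on cells with `H = 0`
#' (unreachable when `H` comes from the full data on the same map) triggers
#' automatic rejection with a warning.
#'
#' @param h `hit_vector` (or numeric counts) of the subsample.
#' @param H `hit_vector` (or numeric counts) of the full data, same map.
#' @param alpha significance level.
#' @param lambda power-divergence exponent.
#' @return object of class `sampling_test`: list with `statistic`, `df`,
#'   `p_value`, `rejected`, `alpha`, `lambda`.
#' @export
cressie_read_test <- function(h, H, alpha = 0.05, lambda = 2 / 3) {
  hv <- if (inherits(h, "hit_vector")) h$counts else as.numeric(h)
  Hv <- if (inherits(H, "hit_vector")) H$counts else as.numeric(H)
  stopifnot(length(hv) == length(Hv))
  if (sum(Hv) < sum(hv)) stopf("H must be the larger (full-data) hit vector")
  keep <- Hv > 0
  if (!any(keep)) stopf("no non-null cells in H")
  if (any(hv[!keep] > 0)) {
    warnf("subsample hits fall on cells unsupported by the full data; rejecting")
    out <- list(statistic = Inf, df = sum(keep) - 1L, p_value = 0,
                rejected = TRUE, alpha = alpha, lambda = lambda)
    return(structure(out, class = "sampling_test"))
  }
  hc <- hv[keep]
  ec <- Hv[keep] * (sum(hv) / sum(Hv))
  ratio <- ifelse(hc > 0, (hc / ec)^lambda, 0)
  stat <- 2 / (lambda * (lambda + 1)) * sum(hc * (ratio - 1))
  stat <- max(stat, 0)
  df <- sum(keep) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 rejected = p < alpha, alpha = alpha, lambda = lambda),
            class = "sampling_test")
}

#' @export
print.sampling_test <- function(x, ...) {
  cat(sprintf("Cressie-Read test (lambda = %.3g): statistic %.3f, df %d, p = %.4f (%s)\n",
              x$lambda, x$statistic, x$df, x$p_value,
              if (x$rejected) "rejected" else "not rejected"))
  invisible(x)
}

#' Scan sampling rates for the minimum faithful summarization level
#'
#' For each summarization level `n` and replica `i`: draw a stratified
#' sample `Q_i`, train a map on it with the given configuration, query the
#' map with both `Q_i` and the full trajectory `Q`, and test the two hit
#' distributions. A level is accepted when none of its `k` replicas is
#' rejected; the minimal accepted level summarizes the trajectory without
#' significant loss of information.
#'
#' @param ensemble the full [conf_ensemble()] (already ED-filtered
#'   descriptors are recommended).
#' @param levels integer vector of sample sizes, scanned in descending
#'   order.
#' @param k_replicas replicas per level.
#' @param config [som_config()] used for every trained map.
#' @param alpha significance level of the tests.
#' @param seed master seed; each (level, replica) derives its own sub-seed.
#' @return object of class `sampling_scan`: list with `results` (data.frame
#'   level/replica/statistic/p_value/rejected), `accepted_levels` and
#'   `min_accepted`.
#' @export
sampling_rate_scan <- function(ensemble, levels, k_replicas = 3,
                               config = som_config(), alpha = 0.05, seed = 1) {
  levels <- sort(unique(as.integer(levels)), decreasing = TRUE)
  X <- as_descriptor_matrix(ensemble)
  rows <- list()
  for (n in levels) {
    for (i in seq_len(k_replicas)) {
      s_samp <- derive_seed(seed, sprintf("sample-%d-%d", n, i))
      s_train <- derive_seed(seed, sprintf("train-%d-%d", n, i))
      sub <- stratified_sample(ensemble, n, seed = s_samp)
      cfg <- config; cfg$seed <- s_train
      som <- som_train(som_init(cfg, sub$xyz, seed = s_train), sub$xyz)
      h <- som_hits(som, sub$xyz)
      H <- som_hits(som, X)
      tst <- cressie_read_test(h, H, alpha = alpha)
      rows[[length(rows) + 1]] <- data.frame(
        level = n, replica = i, statistic = tst$statistic, df = tst$df,
        p_value = tst$p_value, rejected = tst$rejected)
    }
  }
  results <- do.call(rbind, rows)
  acc <- vapply(levels, function(n)
    !any(results$rejected[results$level == n]), logical(1))
  accepted <- levels[acc]
  structure(list(results = results, accepted_levels = accepted,
                 min_accepted = if (length(accepted)) min(accepted) else NA_integer_,
                 alpha = alpha),
            class = "sampling_scan")
}

#' @export
print.sampling_scan <- function(x, ...) {
  cat(sprintf("Sampling-rate scan (alpha = %.2f)\n", x$alpha))
  print(x$results, row.names = FALSE)
  cat(sprintf("minimal accepted level: %s\n",
              ifelse(is.na(x$min_accepted), "none", x$min_accepted)))
  invisible(x)
}
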