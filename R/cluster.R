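#' K-means clustering with silhouette quality
#'
#' Clusters individuals in the (index, serotonin) plane — typically
#' z-scored — with k-means under multiple random restarts, and reports the
#' mean silhouette coefficient (Euclidean distance) plus cluster sizes and
#' fractions.
#'
#' @param points Numeric matrix or data frame, one row per individual
#'   (usually two z-scored columns: index and serotonin).
#' @param k Number of clusters (default 2).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts; best inertia wins.
#' @return An object of class `cluster_report`: `labels`, `sizes`,
#'   `fractions`, `silhouette`, `centers`, `tot_withinss`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
kmeans_silhouette <- function(points, k = 2, seed = 1L, nstart = 10) {
  m <- as.matrix(points)
  if (anyNA(m)) {
    abort("clustering input must be complete",
          class = "taiscore_parameter_error")
  }
  if (nrow(m) <= k) {
    abort("need more points than clusters",
          class = "taiscore_parameter_error")
  }
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart, iter.max = 100)
  sil <- cluster::silhouette(km$cluster, stats::dist(m))
  sizes <- as.integer(table(factor(km$cluster, levels = seq_len(k))))
  structure(
    list(
      labels = km$cluster,
      k = k,
      sizes = sizes,
      fractions = sizes / nrow(m),
      silhouette = mean(sil[, "sil_width"]),
      centers = km$centers,
      tot_withinss = km$tot.withinss,
      points = m
    ),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "k-means (k = %d): sizes %s (%s), silhouette %.2f\n",
    x$k, paste(x$sizes, collapse = "/"),
    paste(sprintf("%.1f%%", 100 * x$fractions), collapse = "/"),
    x$silhouette
  ))
  invisible(x)
}

#' Bootstrap Jaccard cluster stability
#'
#' For each of B bootstrap resamples of the points, re-runs k-means and
#' matches every original cluster to its maximum-Jaccard counterpart among
#' the new clusters, with the Jaccard index computed on the resampled
#' point multiset. Reports the per-cluster mean over resamples; values
#' above about 0.75 indicate a stable cluster.
#'
#' @param points Numeric matrix or data frame of the clustered points.
#' @param labels Original cluster labels (integers `1..k`).
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed RNG seed.
#' @param nstart Restarts per re-clustering.
#' @return A tibble: `cluster`, `mean_jaccard`, `n_resamples`.
#' @export
bootstrap_jaccard <- function(points, labels, B = 100, seed = 1L,
                              nstart = 10) {
  if (B < 1) {
    abort("B must be at least 1", class = "taiscore_parameter_error")
  }
  m <- as.matrix(points)
  labels <- as.integer(labels)
  k <- length(unique(labels))
  n <- nrow(m)
  set.seed(seed)
  jac <- matrix(NA_real_, nrow = B, ncol = k)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    orig <- labels[idx]
    km <- kmeans(m[idx, , drop = FALSE], centers = k, nstart = nstart,
                 iter.max = 100)
    new_lab <- km$cluster
    for (c_orig in seq_len(k)) {
      a_set <- orig == c_orig
      if (!any(a_set)) next
      best <- 0
      for (c_new in seq_len(k)) {
        b_set <- new_lab == c_new
        j <- sum(a_set & b_set) / sum(a_set | b_set)
        if (j > best) best <- j
      }
      jac[b, c_orig] <- best
    }
  }
  tibble::tibble(
    cluster = seq_len(k),
    mean_jaccard = colMeans(jac, na.rm = TRUE),
    n_resamples = colSums(!is.na(jac))
  )
}
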