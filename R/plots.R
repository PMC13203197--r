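#' Bland-Altman plot
#'
#' Differences against pairwise means with the mean-difference line and
#' the 95% limits of agreement.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Mean of methods", y = "Difference (A - B)",
      title = sprintf("Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f]",
                      object$mean_diff, object$loa[1], object$loa[2])
    ) +
    ggplot2::theme_minimal()
}

#' Cluster scatter plot
#'
#' Points coloured by cluster with centers marked.
#'
#' @param object A `cluster_report` from [kmeans_silhouette()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_report
#' @export
autoplot.cluster_report <- function(object, ...) {
  df <- tibble::as_tibble(object$points, .name_repair = "minimal")
  names(df) <- c("x", "y")[seq_len(ncol(df))]
  df$cluster <- factor(object$labels)
  centers <- tibble::as_tibble(object$centers, .name_repair = "minimal")
  names(centers) <- names(df)[seq_len(ncol(centers))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = centers, colour = "black", shape = 4,
                        size = 3, stroke = 1.5) +
    ggplot2::labs(
      x = "TAI (z)", y = "5-HT (z)",
      title = sprintf("k-means (k = %d), silhouette %.2f",
                      object$k, object$silhouette)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort's aggression-index distribution by group
#'
#' Histogram of index scores, filled by aggression group when present.
#'
#' @param cohort A cohort tibble with a `tai` column and optionally
#'   `group`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_tai_distribution <- function(cohort, bins = 30) {
  p <- ggplot2::ggplot(cohort, ggplot2::aes(x = .data$tai))
  if ("group" %in% names(cohort)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$group), bins = bins, colour = "white"
    )
  } else {
    p <- p + ggplot2::geom_histogram(bins = bins, colour = "white",
                                     fill = "steelblue")
  }
  p + ggplot2::labs(x = "Time-weighted Aggression Index", y = "Individuals") +
    ggplot2::theme_minimal()
}

#' Plot pairing-trial attack counts by context
#'
#' @param data A tibble with `context` and `attacks` columns.
#' @return A ggplot (boxplot with jittered points).
#' @export
plot_pairing_counts <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$context, y = .data$attacks)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, height = 0) +
    ggplot2::labs(x = "Pairing context", y = "Aggressive acts per trial") +
    ggplot2::theme_minimal()
}

#' Plot a confidence trace with extracted bouts
#'
#' Per-frame classifier confidence for one behavior with detected bouts
#' shaded.
#'
#' @param trace A [confidence_trace()].
#' @param behavior One behavior category.
#' @param config A [tai_config()].
#' @return A ggplot.
#' @export
plot_bouts <- function(trace, behavior = "fighting", config = tai_config()) {
  bouts <- extract_bouts(trace, behavior, config)
  df <- tibble::tibble(frame = trace$frame, p = trace[[behavior]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$p))
  if (nrow(bouts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame),
      ymin = 0, ymax = 1, fill = "indianred", alpha = 0.25,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = config$confidence_threshold,
                        linetype = "dotted") +
    ggplot2::labs(x = "Frame", y = sprintf("P(%s)", behavior)) +
    ggplot2::theme_minimal()
}
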