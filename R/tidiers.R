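#' Tidy a weight-derivation fit
#'
#' @param x A `tai_weight_fit` from [derive_weights()].
#' @param ... Unused.
#' @return A tibble with one row per index term: raw OLS coefficient and
#'   normalized weight.
#' @method tidy tai_weight_fit
#' @export
tidy.tai_weight_fit <- function(x, ...) {
  w <- x$weights
  tibble::tibble(
    term = c("anxious", "demonstration", "fighting", "latency"),
    coefficient = unname(x$coefficients),
    weight = c(w$w_anxious, w$w_demonstration, w$w_fighting, w$w_latency)
  )
}

#' @rdname tidy.tai_weight_fit
#' @return For `glance()`: a one-row tibble with `r_squared`, `sigma`,
#'   `n`.
#' @method glance tai_weight_fit
#' @export
glance.tai_weight_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared,
    sigma = s$sigma,
    n = x$n
  )
}

#' Tidy an intraclass-correlation fit
#'
#' @param x An `icc_fit` from [icc_consistency()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (single and average
#'   measure) and its confidence interval.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    type = c("ICC(C,1)", sprintf("ICC(C,%d)", x$k)),
    estimate = c(x$icc1, x$icck),
    conf_low = c(x$ci1[["lower"]], x$cik[["lower"]]),
    conf_high = c(x$ci1[["upper"]], x$cik[["upper"]])
  )
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A one-row tibble with the mean difference, its CI, the limits
#'   of agreement and the fraction of points inside them.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff,
    ci_low = x$ci_mean[["lower"]],
    ci_high = x$ci_mean[["upper"]],
    loa_low = x$loa[["lower"]],
    loa_high = x$loa[["upper"]],
    frac_within_loa = x$frac_within_loa,
    n = x$n
  )
}

#' Tidy a pairing-trial report
#'
#' @param x A `pairing_report` from [pairing_analysis()].
#' @param ... Unused.
#' @return The Dunn post-hoc table (one row per pairwise comparison).
#' @method tidy pairing_report
#' @export
tidy.pairing_report <- function(x, ...) x$dunn

#' @rdname tidy.pairing_report
#' @return For `glance()`: a one-row tibble with the Kruskal-Wallis H
#'   statistic, df and p value.
#' @method glance pairing_report
#' @export
glance.pairing_report <- function(x, ...) {
  tibble::tibble(
    statistic = x$kw$statistic,
    df = x$kw$df,
    p_value = x$kw$p_value
  )
}

#' Tidy a cluster report
#'
#' @param x A `cluster_report` from [kmeans_silhouette()].
#' @param ... Unused.
#' @return A tibble with one row per cluster (size and fraction).
#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = x$sizes,
    fraction = x$fractions
  )
}

#' @rdname tidy.cluster_report
#' @return For `glance()`: a one-row tibble with k, the silhouette
#'   coefficient and the total within-cluster sum of squares.
#' @method glance cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    silhouette = x$silhouette,
    tot_withinss = x$tot_withinss
  )
}

#' Tidy a keypoint-error evaluation
#'
#' @param x A `keypoint_error` object.
#' @param ... Unused.
#' @return The per-keypoint error tibble.
#' @method tidy keypoint_error
#' @export
tidy.keypoint_error <- function(x, ...) x$per_keypoint

#' @rdname tidy.keypoint_error
#' @method glance keypoint_error
#' @export
glance.keypoint_error <- function(x, ...) {
  tibble::tibble(mean_px = x$mean_px, sd_px = x$sd_px, n_pairs = x$n_pairs)
}
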