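#' Time-weighted Aggression Index weights
#'
#' The four non-negative weights of the index: one per behavioral duration
#' (anxious, demonstration, fighting) and one for the first-attack latency
#' reward term. The defaults are the published set, which sums to 1.00.
#'
#' @param w_anxious,w_demonstration,w_fighting,w_latency Non-negative
#'   weights.
#' @return A list of class `tai_weights`.
#' @examples
#' tai_weights()
#' @export
tai_weights <- function(w_anxious = 0.14, w_demonstration = 0.21,
                        w_fighting = 0.35, w_latency = 0.3) {
  w <- c(w_anxious, w_demonstration, w_fighting, w_latency)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("TAI weights must be finite and non-negative",
          class = "taiscore_parameter_error")
  }
  structure(
    list(w_anxious = w_anxious, w_demonstration = w_demonstration,
         w_fighting = w_fighting, w_latency = w_latency),
    class = "tai_weights"
  )
}

#' @export
print.tai_weights <- function(x, ...) {
  cat(sprintf(
    "<tai_weights> anxious %.3g, demonstration %.3g, fighting %.3g, latency %.3g\n",
    x$w_anxious, x$w_demonstration, x$w_fighting, x$w_latency
  ))
  invisible(x)
}

#' Compute the Time-weighted Aggression Index
#'
#' For each trial summary evaluates
#' \deqn{TAI = \frac{w_a D_{anx} + w_d D_{dem} + w_f D_{fight}}{T_{total}}
#'   + w_{lat}\,\frac{T_{total} - T_{first}}{T_{total}}}
#' so the index rewards both total time in aggression-related behaviors
#' and an early first attack. With the default weights and mutually
#' exclusive categories the attainable maximum is 0.65; if categories may
#' fully overlap it is 1.00.
#'
#' @param summary A trial-summary tibble with columns `d_anxious`,
#'   `d_demonstration`, `d_fighting`, `t_first`, `t_total` (one or more
#'   rows).
#' @param weights A [tai_weights()].
#' @param rescale_max If `TRUE`, divide by the configuration's attainable
#'   maximum (sum of duration weights plus the latency weight) so the
#'   score maps onto `[0, 1]` even under overlapping categories. Off by
#'   default: the published formula is used verbatim.
#' @return Numeric vector of TAI scores, one per row of `summary`.
#' @examples
#' s <- tibble::tibble(d_anxious = 300, d_demonstration = 200,
#'                     d_fighting = 100, t_first = 600, t_total = 1800)
#' compute_tai(s)
#' @export
compute_tai <- function(summary, weights = tai_weights(),
                        rescale_max = FALSE) {
  t_total <- summary$t_total
  if (any(t_total <= 0)) {
    abort("t_total must be positive", class = "taiscore_parameter_error")
  }
  tai <- (weights$w_anxious * summary$d_anxious +
            weights$w_demonstration * summary$d_demonstration +
            weights$w_fighting * summary$d_fighting) / t_total +
    weights$w_latency * (t_total - summary$t_first) / t_total
  if (rescale_max) {
    cap <- weights$w_anxious + weights$w_demonstration +
      weights$w_fighting + weights$w_latency
    tai <- tai / cap
  }
  tai
}

#' Aggression frequency
#'
#' Total number of aggressive acts (bouts across the scored categories)
#' divided by the trial duration.
#'
#' @param summary A trial-summary tibble with `n_acts` and `t_total`.
#' @return Acts per second, one value per row.
#' @examples
#' aggression_frequency(tibble::tibble(n_acts = 18, t_total = 1800))
#' @export
aggression_frequency <- function(summary) {
  if (any(summary$t_total <= 0)) {
    abort("t_total must be positive", class = "taiscore_parameter_error")
  }
  summary$n_acts / summary$t_total
}

#' Average repeated trials for one individual
#'
#' Field-wise arithmetic mean of the trial summaries of one individual
#' (durations, latency, act count, X1, X2). All repeats must share the
#' same trial duration. A repeat count different from the configured one
#' warns but does not fail.
#'
#' @param summaries Trial-summary tibble, one row per repeat.
#' @param config A [tai_config()] (for the expected repeat count).
#' @return A one-row tibble with the averaged fields and `n_repeats`.
#' @export
average_repeats <- function(summaries, config = tai_config()) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) == 0) {
    abort("no trial summaries to average",
          class = "taiscore_parameter_error")
  }
  if (length(unique(summaries$t_total)) != 1) {
    abort("repeats have differing trial durations",
          class = "taiscore_parameter_error")
  }
  if (nrow(summaries) != config$n_repeats) {
    warn(sprintf("averaging %d repeats where %d were configured",
                 nrow(summaries), config$n_repeats))
  }
  out <- dplyr::summarise(
    summaries,
    dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE))
  )
  out$n_repeats <- nrow(summaries)
  out
}

#' Derive index weights by multiple linear regression
#'
#' Re-derives the index weights from data: ordinary least squares of the
#' per-individual aggression frequency on the three behavioral durations
#' and the transformed latency `(Ttotal - Tfirst)` (so the latency
#' coefficient is positively signed, matching the index's reward term).
#' The intercept is fitted and discarded; the four slope coefficients are
#' normalized to sum to one in absolute value, which reproduces the
#' published set (0.14, 0.21, 0.35, 0.30). A negative duration
#' coefficient survives only as magnitude, so a warning records the sign
#' loss.
#'
#' @param cohort Tibble with one row per individual: `d_anxious`,
#'   `d_demonstration`, `d_fighting`, `t_first`, `t_total`, `frequency`.
#' @return An object of class `tai_weight_fit`: the fitted [tai_weights()]
#'   in `$weights`, raw coefficients in `$coefficients`, the underlying
#'   `lm` fit in `$fit`. Supports [tidy()] and [glance()].
#' @examples
#' set.seed(1)
#' co <- tibble::tibble(
#'   d_anxious = runif(50, 0, 400), d_demonstration = runif(50, 0, 400),
#'   d_fighting = runif(50, 0, 400), t_first = runif(50, 0, 1800),
#'   t_total = 1800
#' )
#' co$frequency <- with(co, 0.14 * d_anxious + 0.21 * d_demonstration +
#'   0.35 * d_fighting + 0.3 * (t_total - t_first)) / 1800
#' derive_weights(co)$weights
#' @export
derive_weights <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) < 10) {
    abort("weight derivation needs at least 10 individuals",
          class = "taiscore_parameter_error")
  }
  dat <- dplyr::transmute(
    cohort,
    frequency = .data$frequency,
    d_anxious = .data$d_anxious,
    d_demonstration = .data$d_demonstration,
    d_fighting = .data$d_fighting,
    latency_reward = .data$t_total - .data$t_first
  )
  preds <- c("d_anxious", "d_demonstration", "d_fighting", "latency_reward")
  for (p in preds) {
    if (sd(dat[[p]]) == 0) {
      abort(sprintf("rank-deficient design: predictor `%s` is constant", p),
            class = "taiscore_estimation_error")
    }
  }
  fit <- lm(frequency ~ d_anxious + d_demonstration + d_fighting +
              latency_reward, data = dat)
  b <- coef(fit)[preds]
  if (anyNA(b)) {
    bad <- preds[is.na(b)]
    abort(sprintf("rank-deficient design: predictor `%s` is collinear",
                  paste(bad, collapse = ", ")),
          class = "taiscore_estimation_error")
  }
  if (any(b[1:3] < 0)) {
    warn(sprintf(
      "negative coefficient on duration predictor(s) %s; sign lost in normalization",
      paste(preds[1:3][b[1:3] < 0], collapse = ", ")
    ))
  }
  w <- abs(b) / sum(abs(b))
  structure(
    list(
      weights = tai_weights(w[["d_anxious"]], w[["d_demonstration"]],
                            w[["d_fighting"]], w[["latency_reward"]]),
      coefficients = b,
      fit = fit,
      n = nrow(dat)
    ),
    class = "tai_weight_fit"
  )
}

#' @export
print.tai_weight_fit <- function(x, ...) {
  cat(sprintf("Weight derivation by OLS (n = %d)\n", x$n))
  print(x$weights)
  invisible(x)
}

#' Score a cohort of trials into per-individual aggression records
#'
#' Entry point composing the full pipeline: for each trial, extract bouts
#' from its confidence trace, aggregate durations and latency, compute the
#' pose-derived features, then average the repeats of each individual and
#' attach the Time-weighted Aggression Index and aggression frequency.
#'
#' @param trials A tibble with one row per trial: `id`, and list-columns
#'   `trace` ([confidence_trace()]s) and optionally `pose`
#'   ([pose_track()]s; if absent, X1/X2 are `NA`).
#' @param config A [tai_config()].
#' @param rescale_max Passed to [compute_tai()].
#' @return A cohort tibble, one row per individual: `id`, `tai`,
#'   `frequency`, `x1`, `x2`, `n_repeats` plus the averaged summary
#'   fields.
#' @export
score_cohort <- function(trials, config = tai_config(), rescale_max = FALSE) {
  trials <- tibble::as_tibble(trials)
  if (!all(c("id", "trace") %in% names(trials))) {
    abort("trials must have columns `id` and `trace`",
          class = "taiscore_parameter_error")
  }
  has_pose <- "pose" %in% names(trials)
  per_trial <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    trace <- trials$trace[[i]]
    bouts <- extract_bouts(trace, "all", config)
    x1 <- NA_real_
    x2 <- NA_real_
    if (has_pose && !is.null(trials$pose[[i]])) {
      filtered <- filter_low_likelihood(
        trials$pose[[i]],
        config$likelihood_threshold, config$max_interp_frames
      )
      x1 <- relative_movement_distance(filtered, config)
      x2 <- freezing_duration(filtered, config)
    }
    dplyr::mutate(summarize_trial(bouts, config, x1 = x1, x2 = x2),
                  id = trials$id[i], .before = 1)
  })
  per_ind <- per_trial |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ average_repeats(.x, config)) |>
    dplyr::ungroup()
  per_ind |>
    dplyr::mutate(
      tai = compute_tai(per_ind, config$tai_weights, rescale_max),
      frequency = aggression_frequency(per_ind)
    ) |>
    dplyr::select("id", "tai", "frequency", "x1", "x2", "n_repeats",
                  dplyr::everything())
}
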