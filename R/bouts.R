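#' Minimum bout length in frames
#'
#' Converts a minimum bout duration from milliseconds to a frame count,
#' rounding up (the minimum duration is a lower bound the bout must meet)
#' and never returning fewer than one frame.
#'
#' @param min_bout_ms Minimum bout duration in milliseconds (>= 0).
#' @param fps Frame rate in frames per second (> 0).
#' @return Integer frame count (>= 1).
#' @examples
#' min_bout_frames(180, 30) # 6
#' @export
min_bout_frames <- function(min_bout_ms, fps) {
  if (!is.numeric(fps) || length(fps) != 1 || is.na(fps) || fps <= 0) {
    abort("fps must be a single positive number",
          class = "taiscore_parameter_error")
  }
  if (!is.numeric(min_bout_ms) || length(min_bout_ms) != 1 ||
      is.na(min_bout_ms) || min_bout_ms < 0) {
    abort("min_bout_ms must be a single non-negative number",
          class = "taiscore_parameter_error")
  }
  max(1L, as.integer(ceiling(min_bout_ms / 1000 * fps)))
}

#' Extract behavioral bouts from a confidence trace
#'
#' Finds maximal runs of frames whose classifier confidence strictly
#' exceeds the threshold, optionally merges runs separated by short
#' sub-threshold gaps, and discards runs shorter than the minimum bout
#' duration. Each surviving run becomes one bout with its mean confidence.
#'
#' @param trace A [confidence_trace()] (or data frame with a column per
#'   behavior).
#' @param behavior One of `"anxious"`, `"demonstration"`, `"fighting"`, or
#'   `"all"` to extract every category at once.
#' @param config A [tai_config()] supplying `confidence_threshold`,
#'   `min_bout_ms`, `gap_merge_frames` and `fps`.
#' @return A tibble of bouts: `behavior`, `start_frame`, `end_frame`
#'   (0-based, inclusive), `duration_s`, `mean_confidence`.
#' @examples
#' tr <- confidence_trace(
#'   tibble::tibble(frame = 0:19, anxious = 0, demonstration = 0,
#'                  fighting = rep(c(0.1, 0.9), each = 10)),
#'   fps = 30
#' )
#' extract_bouts(tr, "fighting", tai_config())
#' @export
extract_bouts <- function(trace, behavior = "all", config = tai_config()) {
  behaviors <- if (identical(behavior, "all")) BEHAVIOR_LEVELS else behavior
  bad <- setdiff(behaviors, BEHAVIOR_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown behavior label: %s", paste(bad, collapse = ", ")),
          class = "taiscore_parameter_error")
  }
  if (nrow(trace) == 0) {
    abort("confidence trace is empty", class = "taiscore_parameter_error")
  }
  fps <- attr(trace, "fps") %||% config$fps
  frame0 <- if ("frame" %in% names(trace)) trace$frame[1] else 0L
  min_len <- min_bout_frames(config$min_bout_ms, fps)

  purrr::map_dfr(behaviors, function(beh) {
    p <- trace[[beh]]
    runs <- supra_threshold_runs(p, config$confidence_threshold,
                                 config$gap_merge_frames)
    runs <- runs[(runs$end - runs$start + 1) >= min_len, , drop = FALSE]
    if (nrow(runs) == 0) {
      return(tibble::tibble(
        behavior = character(0), start_frame = integer(0),
        end_frame = integer(0), duration_s = double(0),
        mean_confidence = double(0)
      ))
    }
    tibble::tibble(
      behavior = beh,
      start_frame = as.integer(frame0 + runs$start - 1L),
      end_frame = as.integer(frame0 + runs$end - 1L),
      duration_s = (runs$end - runs$start + 1) / fps,
      mean_confidence = vapply(
        seq_len(nrow(runs)),
        function(i) mean(p[runs$start[i]:runs$end[i]]),
        double(1)
      )
    )
  })
}

# Maximal runs of values strictly above `threshold` (1-based start/end),
# after merging gaps of length <= gap_merge.
supra_threshold_runs <- function(p, threshold, gap_merge = 0) {
  above <- !is.na(p) & p > threshold
  if (gap_merge > 0) {
    r <- rle(above)
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    fill <- !r$values & r$lengths <= gap_merge &
      seq_along(r$values) %in% interior
    r$values[fill] <- TRUE
    above <- inverse.rle(r)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Aggregate bouts into per-trial durations
#'
#' Sums bout durations within each behavior category (clipped to the trial
#' duration; categories come from independent classifier traces and may
#' overlap in time, so there is no cross-category renormalization) and
#' counts aggressive acts as the total bout count across the three
#' categories.
#'
#' @param bouts A bout tibble as returned by [extract_bouts()].
#' @param config A [tai_config()].
#' @param count_behaviors Categories counted as aggressive acts; defaults
#'   to all three scored categories.
#' @return A one-row tibble: `d_anxious`, `d_demonstration`, `d_fighting`
#'   (seconds), `n_acts`, `t_total`.
#' @export
aggregate_durations <- function(bouts, config = tai_config(),
                                count_behaviors = BEHAVIOR_LEVELS) {
  t_total <- config$trial_duration_s
  if (nrow(bouts) > 0 &&
      any(bouts$end_frame >= t_total * config$fps)) {
    abort("bout extends past the end of the trial",
          class = "taiscore_validation_error")
  }
  durations <- vapply(BEHAVIOR_LEVELS, function(beh) {
    min(t_total, sum(bouts$duration_s[bouts$behavior == beh]))
  }, double(1))
  tibble::tibble(
    d_anxious = durations[["anxious"]],
    d_demonstration = durations[["demonstration"]],
    d_fighting = durations[["fighting"]],
    n_acts = sum(bouts$behavior %in% count_behaviors),
    t_total = t_total
  )
}

#' First-attack latency
#'
#' Start time in seconds of the earliest fighting bout. Trials with no
#' fighting bout get latency equal to the trial duration, so the latency
#' reward term of the aggression index is exactly zero.
#'
#' @param bouts A bout tibble.
#' @param config A [tai_config()].
#' @return Latency `Tfirst` in seconds, in `[0, Ttotal]`.
#' @export
first_attack_latency <- function(bouts, config = tai_config()) {
  fights <- bouts[bouts$behavior == "fighting", , drop = FALSE]
  if (nrow(fights) == 0) return(config$trial_duration_s)
  min(fights$start_frame) / config$fps
}

#' Summarize one trial from its bouts and pose-derived features
#'
#' Combines [aggregate_durations()], [first_attack_latency()] and the
#' kinematic features into a one-row trial summary ready for index
#' scoring.
#'
#' @param bouts A bout tibble for the trial.
#' @param config A [tai_config()].
#' @param x1 Relative movement distance (dimensionless), or `NA`.
#' @param x2 Freezing duration (seconds), or `NA`.
#' @param count_behaviors Passed to [aggregate_durations()].
#' @return A one-row tibble: durations, `t_first`, `n_acts`, `t_total`,
#'   `x1`, `x2`.
#' @export
summarize_trial <- function(bouts, config = tai_config(),
                            x1 = NA_real_, x2 = NA_real_,
                            count_behaviors = BEHAVIOR_LEVELS) {
  agg <- aggregate_durations(bouts, config, count_behaviors)
  dplyr::mutate(
    agg,
    t_first = first_attack_latency(bouts, config),
    x1 = x1,
    x2 = x2,
    .after = "d_fighting"
  )
}
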