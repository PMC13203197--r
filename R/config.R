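#' Pipeline configuration
#'
#' Bundles every tunable threshold of the scoring pipeline in one validated
#' list. Defaults follow the published assay: 30 fps video, 30-minute
#' (1800 s) trials repeated five times, bout calling at confidence > 0.5
#' with a 180 ms minimum duration, keypoint filtering at likelihood 0.95,
#' and the printed index weights.
#'
#' @param fps Video frame rate, frames per second (> 0).
#' @param trial_duration_s Trial length `Ttotal` in seconds (> 0).
#' @param confidence_threshold Bout-calling threshold on classifier
#'   confidence; frames must exceed it strictly. In `[0, 1]`.
#' @param min_bout_ms Minimum bout duration in milliseconds (>= 0); bouts
#'   always span at least one frame.
#' @param likelihood_threshold Keypoint likelihood below which an
#'   observation is treated as missing. In `[0, 1]`.
#' @param tai_weights A [tai_weights()] object or numeric vector of four
#'   non-negative weights (anxious, demonstration, fighting, latency).
#' @param quartile_fraction Fraction of the cohort assigned to each extreme
#'   aggression group. In `(0, 0.5]`.
#' @param n_repeats Expected number of trial repeats per individual.
#' @param gap_merge_frames Runs of sub-threshold frames no longer than this
#'   are merged into the surrounding bout before length filtering
#'   (0 disables merging).
#' @param max_interp_frames Longest low-likelihood gap (frames) filled by
#'   linear interpolation when filtering pose tracks.
#' @param centroid_keypoints Keypoints averaged into the body centroid.
#' @param freeze_speed_threshold Centroid speed (carapace widths per
#'   second) below which a frame counts as still.
#' @param min_freeze_s Minimum duration (s) of a still run scored as
#'   freezing.
#' @param bootstrap_B Bootstrap resamples for cluster stability.
#' @param rng_seed Integer seed used by stochastic downstream steps.
#'
#' @return A list of class `tai_config`.
#' @examples
#' cfg <- tai_config()
#' cfg$fps
#' @export
tai_config <- function(fps = 30,
                       trial_duration_s = 1800,
                       confidence_threshold = 0.5,
                       min_bout_ms = 180,
                       likelihood_threshold = 0.95,
                       tai_weights = taiscore::tai_weights(),
                       quartile_fraction = 0.25,
                       n_repeats = 5,
                       gap_merge_frames = 0,
                       max_interp_frames = 5,
                       centroid_keypoints = c("LBODY", "RBOD", "HEAD"),
                       freeze_speed_threshold = 0.2,
                       min_freeze_s = 2,
                       bootstrap_B = 100,
                       rng_seed = 1L) {
  if (is.numeric(tai_weights)) {
    tai_weights <- tai_weights(
      tai_weights[[1]], tai_weights[[2]], tai_weights[[3]], tai_weights[[4]]
    )
  }
  cfg <- structure(
    list(
      fps = fps,
      trial_duration_s = trial_duration_s,
      confidence_threshold = confidence_threshold,
      min_bout_ms = min_bout_ms,
      likelihood_threshold = likelihood_threshold,
      tai_weights = tai_weights,
      quartile_fraction = quartile_fraction,
      n_repeats = n_repeats,
      gap_merge_frames = gap_merge_frames,
      max_interp_frames = max_interp_frames,
      centroid_keypoints = centroid_keypoints,
      freeze_speed_threshold = freeze_speed_threshold,
      min_freeze_s = min_freeze_s,
      bootstrap_B = bootstrap_B,
      rng_seed = as.integer(rng_seed)
    ),
    class = "tai_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_range <- function(key, lo, hi, lo_open = FALSE) {
    x <- cfg[[key]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (lo_open && x <= lo) || (!lo_open && x < lo) || x > hi) {
      abort(
        sprintf("config value `%s` must be in %s%g, %g]: got %s",
                key, if (lo_open) "(" else "[", lo, hi,
                paste(format(x), collapse = ", ")),
        class = "taiscore_config_error"
      )
    }
    invisible(x)
  }
  check_range("fps", 0, Inf, lo_open = TRUE)
  check_range("trial_duration_s", 0, Inf, lo_open = TRUE)
  check_range("confidence_threshold", 0, 1)
  check_range("min_bout_ms", 0, Inf)
  check_range("likelihood_threshold", 0, 1)
  check_range("quartile_fraction", 0, 0.5, lo_open = TRUE)
  check_range("n_repeats", 1, Inf)
  check_range("gap_merge_frames", 0, Inf)
  check_range("max_interp_frames", 0, Inf)
  check_range("freeze_speed_threshold", 0, Inf)
  check_range("min_freeze_s", 0, Inf)
  check_range("bootstrap_B", 1, Inf)
  if (!inherits(cfg$tai_weights, "tai_weights")) {
    abort("config value `tai_weights` must be a tai_weights object",
          class = "taiscore_config_error")
  }
  if (length(cfg$centroid_keypoints) < 1) {
    abort("config value `centroid_keypoints` must name at least one keypoint",
          class = "taiscore_config_error")
  }
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a flat key/value YAML file and merges it over the [tai_config()]
#' defaults. Unknown keys produce a warning, not an error, so configs
#' written for newer versions still load. `tai_weights` may be given as a
#' four-element list in the order anxious, demonstration, fighting, latency.
#'
#' @param path Path to a YAML config file.
#' @return A validated `tai_config` list.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("fps: 25", f)
#' load_config(f)$fps
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "taiscore_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    abort("config file must contain a key/value mapping",
          class = "taiscore_config_error")
  }
  known <- names(formals(tai_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown config keys: %s",
                 paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  if (!is.null(raw$tai_weights)) raw$tai_weights <- unlist(raw$tai_weights)
  if (!is.null(raw$centroid_keypoints)) {
    raw$centroid_keypoints <- unlist(raw$centroid_keypoints)
  }
  do.call(tai_config, raw)
}

#' @export
print.tai_config <- function(x, ...) {
  cat("<tai_config>\n")
  w <- x$tai_weights
  for (key in names(x)) {
    val <- x[[key]]
    if (inherits(val, "tai_weights")) {
      val <- sprintf("(%.2f, %.2f, %.2f, %.2f)",
                     w$w_anxious, w$w_demonstration, w$w_fighting, w$w_latency)
    }
    cat(sprintf("  %-24s %s\n", key, paste(format(val), collapse = " ")))
  }
  invisible(x)
}
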