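#' Filter low-likelihood keypoint observations
#'
#' Marks keypoint observations whose likelihood falls below the threshold
#' as missing, then fills short interior gaps (at most
#' `config$max_interp_frames` frames) by linear interpolation per
#' coordinate. Longer gaps and gaps touching either end of the track stay
#' missing — no extrapolation. Rows are never dropped, so the frame
#' sequence stays gap-free.
#'
#' @param track A [pose_track()].
#' @param likelihood_threshold Likelihood below which an observation is
#'   unreliable; in `[0, 1]`.
#' @param max_interp_frames Longest gap (frames) bridged by interpolation.
#' @return A filtered [pose_track()] of the same dimensions.
#' @export
filter_low_likelihood <- function(track, likelihood_threshold = 0.95,
                                  max_interp_frames = 5) {
  if (likelihood_threshold < 0 || likelihood_threshold > 1) {
    abort("likelihood_threshold must lie in [0, 1]",
          class = "taiscore_parameter_error")
  }
  out <- tibble::as_tibble(track)
  for (kp in pose_keypoints(track)) {
    lik <- out[[paste0(kp, "_likelihood")]]
    drop <- is.na(lik) | lik < likelihood_threshold
    for (coord in c("x", "y")) {
      col <- paste0(kp, "_", coord)
      v <- out[[col]]
      v[drop] <- NA_real_
      out[[col]] <- fill_short_gaps(v, max_interp_frames)
    }
  }
  pose_track(out, fps = pose_fps(track), keypoints = pose_keypoints(track))
}

# Linear interpolation of interior NA runs no longer than max_gap;
# leading/trailing runs are left untouched.
fill_short_gaps <- function(v, max_gap) {
  if (max_gap <= 0 || !anyNA(v) || all(is.na(v))) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] > max_gap) next
    lo <- starts[i] - 1L
    hi <- ends[i] + 1L
    if (lo < 1 || hi > n || is.na(v[lo]) || is.na(v[hi])) next
    idx <- starts[i]:ends[i]
    v[idx] <- v[lo] + (v[hi] - v[lo]) * (idx - lo) / (hi - lo)
  }
  v
}

#' Body centroid path
#'
#' Per-frame arithmetic mean of the available body keypoints (default
#' LBODY, RBOD, HEAD). A frame is valid only if at least two of the set
#' are available; invalid frames are flagged, never interpolated.
#'
#' @param track A filtered [pose_track()].
#' @param keypoints Keypoints averaged into the centroid.
#' @return A tibble of class `centroid_path`: `frame`, `x`, `y`, `valid`,
#'   with attribute `fps`.
#' @export
body_centroid <- function(track, keypoints = c("LBODY", "RBOD", "HEAD")) {
  if (length(keypoints) < 1) {
    abort("centroid keypoint set must not be empty",
          class = "taiscore_config_error")
  }
  xs <- as.matrix(tibble::as_tibble(track)[paste0(keypoints, "_x")])
  ys <- as.matrix(tibble::as_tibble(track)[paste0(keypoints, "_y")])
  avail <- !is.na(xs) & !is.na(ys)
  n_avail <- rowSums(avail)
  valid <- n_avail >= min(2L, length(keypoints))
  cx <- rowMeans(ifelse(avail, xs, NA), na.rm = TRUE)
  cy <- rowMeans(ifelse(avail, ys, NA), na.rm = TRUE)
  cx[!valid] <- NA_real_
  cy[!valid] <- NA_real_
  structure(
    tibble::tibble(frame = track$frame, x = cx, y = cy, valid = valid),
    fps = pose_fps(track),
    class = c("centroid_path", class(tibble::tibble()))
  )
}

# Median carapace width: Euclidean LBODY-RBOD distance over frames where
# both landmarks are available.
carapace_width <- function(track) {
  d <- sqrt((track$LBODY_x - track$RBOD_x)^2 +
              (track$LBODY_y - track$RBOD_y)^2)
  d <- d[!is.na(d)]
  if (length(d) == 0 || median(d) <= 0) {
    abort("carapace width undefined: no valid LBODY-RBOD pair or zero width",
          class = "taiscore_feature_error")
  }
  median(d)
}

#' Relative movement distance (X1)
#'
#' Total Euclidean path length of the body centroid over valid consecutive
#' frame pairs, normalized by the median carapace width (the LBODY-RBOD
#' distance) so the feature is dimensionless and invariant to camera
#' scale. Displacements spanning invalid frames are skipped.
#'
#' @param track A filtered [pose_track()].
#' @param config A [tai_config()] (supplies the centroid keypoint set).
#' @return Dimensionless path length (carapace widths).
#' @export
relative_movement_distance <- function(track, config = tai_config()) {
  cen <- body_centroid(track, config$centroid_keypoints)
  ok <- cen$valid
  pair_ok <- ok[-1] & ok[-length(ok)]
  if (!any(pair_ok)) {
    abort("no valid consecutive centroid pair",
          class = "taiscore_feature_error")
  }
  dx <- diff(cen$x)
  dy <- diff(cen$y)
  steps <- sqrt(dx^2 + dy^2)[pair_ok]
  sum(steps) / carapace_width(track)
}

# Centroid speed in carapace widths / s, central difference over valid
# neighbors (one-sided at the ends).
centroid_speed <- function(cen, cw) {
  n <- nrow(cen)
  fps <- attr(cen, "fps") %||% 30
  speed <- rep(NA_real_, n)
  if (n >= 2) {
    x <- cen$x
    y <- cen$y
    idx <- 2:(n - 1)
    if (n > 2) {
      speed[idx] <- sqrt((x[idx + 1] - x[idx - 1])^2 +
                           (y[idx + 1] - y[idx - 1])^2) * fps / 2
    }
    speed[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) * fps
    speed[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) * fps
  } else if (n == 1) {
    speed[1] <- 0
  }
  speed / cw
}

#' Freezing duration (X2)
#'
#' Total time spent in maximal runs of frames whose centroid speed stays
#' below `freeze_speed_threshold` (carapace widths per second) for at
#' least `min_freeze_s` seconds. Frames with undefined speed (invalid
#' centroid neighbors) never count as still.
#'
#' @param track A filtered [pose_track()].
#' @param config A [tai_config()].
#' @return Freezing duration in seconds.
#' @export
freezing_duration <- function(track, config = tai_config()) {
  cen <- body_centroid(track, config$centroid_keypoints)
  if (!any(cen$valid)) {
    abort("no valid centroid frame", class = "taiscore_feature_error")
  }
  fps <- pose_fps(track)
  speed <- centroid_speed(cen, carapace_width(track))
  still <- !is.na(speed) & speed < config$freeze_speed_threshold
  min_frames <- max(1L, as.integer(ceiling(config$min_freeze_s * fps)))
  r <- rle(still)
  keep <- r$values & r$lengths >= min_frames
  sum(r$lengths[keep]) / fps
}

#' Keypoint localization error
#'
#' Mean (and SD) Euclidean pixel distance between predicted and manually
#' annotated keypoint coordinates over all annotated, non-missing
#' (frame, keypoint) pairs, with a per-keypoint breakdown.
#'
#' @param predicted,annotated Two [pose_track()]s over the same frames and
#'   keypoints.
#' @return A list of class `keypoint_error`: `mean_px`, `sd_px`, `n_pairs`
#'   and a `per_keypoint` tibble.
#' @export
keypoint_error <- function(predicted, annotated) {
  if (!identical(as.integer(predicted$frame), as.integer(annotated$frame))) {
    abort("predicted and annotated tracks cover different frames",
          class = "taiscore_validation_error")
  }
  kp <- pose_keypoints(predicted)
  if (!identical(kp, pose_keypoints(annotated))) {
    abort("predicted and annotated tracks have different keypoints",
          class = "taiscore_validation_error")
  }
  per <- purrr::map_dfr(kp, function(k) {
    dx <- predicted[[paste0(k, "_x")]] - annotated[[paste0(k, "_x")]]
    dy <- predicted[[paste0(k, "_y")]] - annotated[[paste0(k, "_y")]]
    d <- sqrt(dx^2 + dy^2)
    d <- d[!is.na(d)]
    tibble::tibble(
      keypoint = k, n = length(d),
      mean_px = if (length(d)) mean(d) else NA_real_,
      sd_px = if (length(d) > 1) sd(d) else NA_real_
    )
  })
  all_d <- unlist(purrr::map(kp, function(k) {
    d <- sqrt((predicted[[paste0(k, "_x")]] - annotated[[paste0(k, "_x")]])^2 +
                (predicted[[paste0(k, "_y")]] - annotated[[paste0(k, "_y")]])^2)
    d[!is.na(d)]
  }))
  if (length(all_d) == 0) {
    abort("no overlapping annotated keypoint observations",
          class = "taiscore_validation_error")
  }
  structure(
    list(
      mean_px = mean(all_d),
      sd_px = if (length(all_d) > 1) sd(all_d) else NA_real_,
      n_pairs = length(all_d),
      per_keypoint = per
    ),
    class = "keypoint_error"
  )
}

#' @export
print.keypoint_error <- function(x, ...) {
  cat(sprintf("Keypoint localization error: %.2f +/- %.2f px (n = %d)\n",
              x$mean_px, x$sd_px, x$n_pairs))
  invisible(x)
}
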