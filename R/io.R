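#' Construct a pose track
#'
#' A pose track is a tibble with one row per frame: a 0-based `frame`
#' column followed by `<keypoint>_x`, `<keypoint>_y`,
#' `<keypoint>_likelihood` triplets for each of the 13 landmarks.
#' Coordinates are in pixels with the origin at the top-left and y
#' increasing downward; likelihoods lie in `[0, 1]`. Missing observations
#' are encoded as `NA` coordinates with likelihood 0 so the frame sequence
#' stays gap-free.
#'
#' @param data A data frame with columns `frame` and the per-keypoint
#'   triplets, in keypoint order.
#' @param fps Frame rate in frames per second.
#' @param keypoints Character vector of keypoint names (defaults to the
#'   13-landmark schema).
#' @return A tibble of class `pose_track` with attributes `fps` and
#'   `keypoints`.
#' @export
pose_track <- function(data, fps, keypoints = KEYPOINTS) {
  data <- tibble::as_tibble(data)
  expected <- c("frame", as.vector(t(outer(
    keypoints, c("x", "y", "likelihood"), paste, sep = "_"
  ))))
  missing_cols <- setdiff(expected, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("pose track is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "taiscore_schema_error")
  }
  data <- data[expected]
  if (nrow(data) > 0 &&
      !identical(as.integer(data$frame),
                 seq.int(data$frame[1], length.out = nrow(data)))) {
    abort("pose track frame indices must be consecutive integers",
          class = "taiscore_schema_error")
  }
  lik <- as.matrix(data[grep("_likelihood$", names(data))])
  if (any(!is.na(lik) & (lik < 0 | lik > 1))) {
    abort("keypoint likelihoods must lie in [0, 1]",
          class = "taiscore_schema_error")
  }
  structure(data,
            fps = fps, keypoints = keypoints,
            class = c("pose_track", class(data)))
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track: %d frames, %d keypoints, %g fps>\n",
              nrow(x), length(attr(x, "keypoints")), attr(x, "fps")))
  NextMethod()
}

pose_fps <- function(track) attr(track, "fps") %||% 30
pose_keypoints <- function(track) attr(track, "keypoints") %||% KEYPOINTS

#' Read a pose-estimation CSV export
#'
#' Parses the three-header-row CSV dialect written by markerless
#' pose-estimation software (rows named `scorer`, `bodyparts` and
#' `coords`, the last cycling `x`, `y`, `likelihood`), followed by one row
#' per frame whose first column is the frame index.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate to attach to the track (frames per second).
#' @param expected_keypoints Number of keypoints the file must contain;
#'   set to `NA` to accept any count.
#' @return A [pose_track()] tibble.
#' @examples
#' trk <- pose_track(
#'   cbind(frame = 0:1, as.data.frame(matrix(runif(2 * 39), 2))) |>
#'     stats::setNames(c("frame", paste(rep(taiscore:::KEYPOINTS, each = 3),
#'                       c("x", "y", "likelihood"), sep = "_"))),
#'   fps = 30
#' )
#' f <- tempfile(fileext = ".csv")
#' write_pose_csv(trk, f)
#' identical(dim(read_pose_csv(f)), dim(trk))
#' @export
read_pose_csv <- function(path, fps = 30, expected_keypoints = 13) {
  if (!file.exists(path)) {
    abort(sprintf("pose file not found: %s", path),
          class = "taiscore_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort("pose CSV must start with scorer/bodyparts/coords header rows",
          class = "taiscore_format_error")
  }
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  labels <- vapply(hdr, function(x) x[1], character(1))
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    abort(sprintf(
      "pose CSV header rows must be scorer/bodyparts/coords, got: %s",
      paste(labels, collapse = "/")
    ), class = "taiscore_format_error")
  }
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  keypoints <- unique(bodyparts)
  if (!is.na(expected_keypoints) &&
      length(keypoints) != expected_keypoints) {
    abort(sprintf("expected %d keypoints, file has %d",
                  expected_keypoints, length(keypoints)),
          class = "taiscore_schema_error")
  }
  if (length(coords) != length(bodyparts) ||
      !all(coords == rep(c("x", "y", "likelihood"),
                         length.out = length(coords)))) {
    abort("coords header row must cycle x,y,likelihood per keypoint",
          class = "taiscore_format_error")
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  ncol_expected <- 1 + length(bodyparts)
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol_expected)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) != ncol_expected) {
      abort(sprintf("row %d has %d cells, expected %d",
                    i + 3, length(row), ncol_expected),
            class = "taiscore_format_error")
    }
    vals <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(vals) & !(row %in% c("", "NA", "NaN")))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value %s at row %d, column %d",
                    dQuote(row[bad[1]]), i + 3, bad[1]),
            class = "taiscore_parse_error")
    }
    mat[i, ] <- vals
  }
  out <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(out) <- c("frame", paste(bodyparts, coords, sep = "_"))
  pose_track(out, fps = fps, keypoints = keypoints)
}

#' Write a pose track in the pose-estimation CSV dialect
#'
#' @param track A [pose_track()].
#' @param path Output file path.
#' @param scorer Label written in the `scorer` header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "taiscore") {
  kp <- pose_keypoints(track)
  header <- c(
    paste(c("scorer", rep(scorer, 3 * length(kp))), collapse = ","),
    paste(c("bodyparts", rep(kp, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(kp))),
          collapse = ",")
  )
  mat <- as.matrix(as.data.frame(track))
  body <- apply(mat, 1, function(r) {
    paste(ifelse(is.na(r), "NA", format(r, trim = TRUE, digits = 15,
                                        scientific = FALSE)),
          collapse = ",")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

bout_columns <- c("behavior", "start_frame", "end_frame",
                  "duration_s", "mean_confidence")

#' Write a bout table
#'
#' One row per detected bout with columns `behavior`, `start_frame`,
#' `end_frame`, `duration_s`, `mean_confidence`. Frame indices are 0-based
#' and inclusive at both ends, so `duration_s = (end - start + 1) / fps`.
#'
#' @param bouts A tibble of bouts (possibly zero rows) with the columns
#'   above.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bout_table <- function(bouts, path) {
  bouts <- tibble::as_tibble(bouts)
  if (nrow(bouts) == 0 && ncol(bouts) == 0) {
    bouts <- tibble::as_tibble(setNames(
      rep(list(logical(0)), length(bout_columns)), bout_columns
    ))
  }
  missing_cols <- setdiff(bout_columns, names(bouts))
  if (length(missing_cols) > 0) {
    abort(sprintf("bout table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "taiscore_schema_error")
  }
  readr::write_csv(bouts[bout_columns], path)
  invisible(path)
}

#' Read a bout table
#'
#' Inverse of [write_bout_table()]. Durations are re-derived from the
#' frame interval and checked against the stored `duration_s`.
#'
#' @param path Path to the bout CSV.
#' @param fps Frame rate used to validate durations.
#' @param tolerance Largest tolerated absolute difference (s) between the
#'   stored and recomputed duration.
#' @return A tibble of bouts in file order.
#' @export
read_bout_table <- function(path, fps = 30, tolerance = 1e-3) {
  if (!file.exists(path)) {
    abort(sprintf("bout file not found: %s", path),
          class = "taiscore_io_error")
  }
  bouts <- readr::read_csv(
    path,
    col_types = readr::cols(
      behavior = readr::col_character(),
      start_frame = readr::col_integer(),
      end_frame = readr::col_integer(),
      duration_s = readr::col_double(),
      mean_confidence = readr::col_double()
    )
  )
  missing_cols <- setdiff(bout_columns, names(bouts))
  if (length(missing_cols) > 0) {
    abort(sprintf("bout table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "taiscore_schema_error")
  }
  if (nrow(bouts) == 0) return(bouts)
  if (any(bouts$end_frame < bouts$start_frame)) {
    abort("bout end_frame precedes start_frame",
          class = "taiscore_validation_error")
  }
  expected <- (bouts$end_frame - bouts$start_frame + 1) / fps
  off <- abs(expected - bouts$duration_s)
  if (any(off > tolerance)) {
    i <- which.max(off)
    abort(sprintf(
      "bout %d duration %.4f s inconsistent with frames [%d, %d] at %g fps",
      i, bouts$duration_s[i], bouts$start_frame[i], bouts$end_frame[i], fps
    ), class = "taiscore_validation_error")
  }
  bouts
}

#' Write a confidence trace
#'
#' Per-frame classifier probabilities for the three behavior categories,
#' one column per category plus a 0-based `frame` column.
#'
#' @param trace A [confidence_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_confidence_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read a confidence trace
#'
#' @param path Path to the trace CSV.
#' @param fps Frame rate to attach.
#' @return A [confidence_trace()] tibble.
#' @export
read_confidence_csv <- function(path, fps = 30) {
  if (!file.exists(path)) {
    abort(sprintf("trace file not found: %s", path),
          class = "taiscore_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  confidence_trace(df, fps = fps)
}

#' Construct a confidence trace
#'
#' @param data Data frame with columns `frame`, `anxious`,
#'   `demonstration`, `fighting`; probabilities in `[0, 1]` (categories
#'   need not sum to one — an unclassified residual is allowed).
#' @param fps Frame rate in frames per second.
#' @return A tibble of class `confidence_trace` with attribute `fps`.
#' @export
confidence_trace <- function(data, fps) {
  data <- tibble::as_tibble(data)
  needed <- c("frame", BEHAVIOR_LEVELS)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("confidence trace is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "taiscore_schema_error")
  }
  probs <- as.matrix(data[BEHAVIOR_LEVELS])
  if (any(!is.na(probs) & (probs < 0 | probs > 1))) {
    abort("confidence probabilities must lie in [0, 1]",
          class = "taiscore_schema_error")
  }
  structure(data[needed], fps = fps,
            class = c("confidence_trace", class(data)))
}

#' Write a cohort table
#'
#' @param cohort Per-individual tibble (id, tai, frequency, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' Read a cohort table
#'
#' @param path Path to the cohort CSV.
#' @return A tibble, one row per individual.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path),
          class = "taiscore_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE)
}
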