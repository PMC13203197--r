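# Shared fixture builders and independent oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Confidence trace from explicit per-frame probability vectors.
make_trace <- function(fighting, anxious = NULL, demonstration = NULL,
                       fps = 30) {
  n <- length(fighting)
  confidence_trace(
    tibble::tibble(
      frame = seq_len(n) - 1L,
      anxious = anxious %||% rep(0, n),
      demonstration = demonstration %||% rep(0, n),
      fighting = fighting
    ),
    fps = fps
  )
}

# Pose track whose body centroid follows (x, y) exactly: LBODY/RBOD sit
# cw apart about the centroid, HEAD offset cancels out by construction.
make_centroid_track <- function(x, y, fps = 30, cw = 50, likelihood = 1) {
  n <- length(x)
  cols <- list(frame = seq_len(n) - 1L)
  offsets <- list(
    LBODY = c(-cw / 2, 0), RBOD = c(cw / 2, 0), HEAD = c(0, 0)
  )
  for (kp in taiscore:::KEYPOINTS) {
    o <- offsets[[kp]] %||% c(0, 0)
    cols[[paste0(kp, "_x")]] <- x + o[1]
    cols[[paste0(kp, "_y")]] <- y + o[2]
    cols[[paste0(kp, "_likelihood")]] <- rep(likelihood, n)
  }
  pose_track(tibble::as_tibble(cols), fps = fps)
}

# Brute-force bout oracle: scan every frame, collect maximal runs strictly
# above threshold, drop runs shorter than min_len. Independent of the
# rle-based implementation.
brute_force_bouts <- function(p, threshold, min_len) {
  runs <- list()
  start <- NA
  for (i in seq_along(p)) {
    if (p[i] > threshold) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(p))
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_len, runs)
  if (length(runs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r[1] - 1L, end = r[2] - 1L) # 0-based
  }))
}

# Exhaustive 2-partition oracle: minimal total within-cluster sum of
# squares over all non-trivial binary partitions.
brute_force_kmeans2 <- function(points) {
  m <- as.matrix(points)
  n <- nrow(m)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    assign <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    if (all(assign == assign[1])) next
    ss <- 0
    for (g in 0:1) {
      sub <- m[assign == g, , drop = FALSE]
      if (nrow(sub) == 0) next
      ctr <- colMeans(sub)
      ss <- ss + sum(sweep(sub, 2, ctr)^2)
    }
    if (ss < best - 1e-12) {
      best <- ss
      best_assign <- assign
    }
  }
  list(assign = best_assign, withinss = best)
}

# Tie-corrected Kruskal-Wallis H computed directly from the rank formula;
# independent of stats::kruskal.test.
hand_kw_h <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
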