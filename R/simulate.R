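#' Simulation parameters for synthetic cohorts
#'
#' Defines the study conditions emulated by the synthetic generator: a
#' cohort of individuals whose latent aggressiveness drives behavioral
#' durations and first-attack latency, hemolymph serotonin positively
#' linked to aggressiveness with a discordant high-serotonin/low-aggression
#' subcluster, and context-dependent attack counts in pairing trials.
#'
#' @param n Number of individuals (default 200, the assay's cohort size).
#' @param t_total Trial duration in seconds (default 1800).
#' @param fps Frame rate (default 30).
#' @param n_repeats Trial repeats per individual (default 5).
#' @param a_mean,a_sd Mean and SD of latent aggressiveness `a`
#'   (normal, clipped to `[0, 1]`); defaults give an approximately normal
#'   induced index.
#' @param duration_max Named maxima (s) of the mean category durations at
#'   `a = 1`; each individual's mean duration is `a * duration_max`.
#' @param duration_cv Coefficient of variation of individual duration
#'   means around the latent-trait line.
#' @param latency_slope Fraction of the trial by which mean first-attack
#'   latency shrinks from `t_total` as `a` goes 0 to 1.
#' @param trial_noise_cv Trial-to-trial coefficient of variation of
#'   realized durations and latency around the individual means.
#' @param bout_mean_s Mean single-bout length (s) of the renewal process.
#' @param conf_in,conf_out Classifier confidence levels inside and outside
#'   true bouts.
#' @param conf_noise Half-width of the uniform confidence jitter.
#' @param speed_base Baseline centroid speed, px/s, at `a = 0`.
#' @param speed_slope Added px/s of centroid speed per unit `a`.
#' @param fight_speed_factor Speed multiplier during fighting bouts.
#' @param freeze_frac_max Occupancy fraction of freezing spells at
#'   `a = 0` (shrinks linearly to 0 at `a = 1`).
#' @param freeze_mean_s Mean freezing-spell length (s).
#' @param carapace_px Carapace width in pixels (LBODY-RBOD distance).
#' @param arena_px Arena side length in pixels (positions reflected at the
#'   walls).
#' @param ht_intercept,ht_slope,ht_noise Intercept, slope and noise SD
#'   (ng/mL) of the serotonin-on-aggressiveness line.
#' @param discordant_fraction Fraction of individuals in the discordant
#'   subcluster (high serotonin, low aggressiveness; default 0.20).
#' @param discordant_offset Additional serotonin (ng/mL) given to the
#'   discordant subcluster above the high-aggression level.
#' @param pairing_means Named mean attack counts per pairing context
#'   (defaults: `H-H` 7.08, `L-L` 0.96, `H-L` 2.41, `M-M` 2.25).
#' @param pairing_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param zero_inflation Named structural zero probabilities per context
#'   (default 0.48 for `L-L`, 0 elsewhere).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n = 200,
                       t_total = 1800,
                       fps = 30,
                       n_repeats = 5,
                       a_mean = 0.5,
                       a_sd = 0.15,
                       duration_max = c(anxious = 240, demonstration = 300,
                                        fighting = 420),
                       duration_cv = 0.10,
                       latency_slope = 0.85,
                       trial_noise_cv = 0.10,
                       bout_mean_s = 4,
                       conf_in = 0.9,
                       conf_out = 0.1,
                       conf_noise = 0.05,
                       speed_base = 5,
                       speed_slope = 20,
                       fight_speed_factor = 3,
                       freeze_frac_max = 0.4,
                       freeze_mean_s = 6,
                       carapace_px = 50,
                       arena_px = 1000,
                       ht_intercept = 40,
                       ht_slope = 120,
                       ht_noise = 8,
                       discordant_fraction = 0.20,
                       discordant_offset = 55,
                       pairing_means = c("H-H" = 7.08, "L-L" = 0.96,
                                         "H-L" = 2.41, "M-M" = 2.25),
                       pairing_dispersion = 3,
                       zero_inflation = c("L-L" = 0.48),
                       seed = 1L) {
  if (missing(duration_max) && t_total != 1800) {
    # Keep default occupancy fractions when the trial is shortened.
    duration_max <- duration_max * t_total / 1800
  }
  p <- structure(as.list(environment()), class = "sim_params")
  if (p$n < 1) {
    abort("n must be at least 1", class = "taiscore_parameter_error")
  }
  if (p$discordant_fraction < 0 || p$discordant_fraction > 1) {
    abort("discordant_fraction must lie in [0, 1]",
          class = "taiscore_parameter_error")
  }
  if (any(p$pairing_means < 0) || p$ht_noise < 0 || p$duration_cv < 0 ||
      p$trial_noise_cv < 0) {
    abort("means and noise scales must be non-negative",
          class = "taiscore_parameter_error")
  }
  if (sum(p$duration_max) > p$t_total) {
    abort("expected category durations exceed the trial duration",
          class = "taiscore_parameter_error")
  }
  p$seed <- as.integer(seed)
  p
}

# Deterministic per-individual/per-use substream seed.
sub_seed <- function(seed, id, stream = 0L) {
  as.integer((as.double(seed) * 48271 + id * 131071 + stream * 7919) %%
               2147483629)
}

#' Generate individual behavioral profiles
#'
#' Draws latent aggressiveness `a` for each individual (normal, clipped to
#' `[0, 1]`) and derives its behavioral phenotype: mean category durations
#' increasing in `a`, mean first-attack latency decreasing in `a`,
#' locomotion speed increasing in `a` and freezing propensity decreasing
#' in `a`.
#'
#' @param params A [sim_params()].
#' @return A tibble with one row per individual: `id`, `a`,
#'   `mean_d_anxious`, `mean_d_demonstration`, `mean_d_fighting` (s),
#'   `mean_latency` (s), `speed_px_s`, `freeze_frac`.
#' @export
generate_profiles <- function(params = sim_params()) {
  if (params$n < 1) {
    abort("n must be at least 1", class = "taiscore_parameter_error")
  }
  set.seed(sub_seed(params$seed, 0L, 1L))
  n <- params$n
  a <- pmin(1, pmax(0, rnorm(n, params$a_mean, params$a_sd)))
  cv <- params$duration_cv
  jitter_mult <- function() exp(rnorm(n, -cv^2 / 2, cv))
  dmax <- params$duration_max
  tibble::tibble(
    id = seq_len(n),
    a = a,
    mean_d_anxious = a * dmax[["anxious"]] * jitter_mult(),
    mean_d_demonstration = a * dmax[["demonstration"]] * jitter_mult(),
    mean_d_fighting = a * dmax[["fighting"]] * jitter_mult(),
    mean_latency = pmin(params$t_total,
                        params$t_total * (1 - params$latency_slope * a)),
    speed_px_s = params$speed_base + params$speed_slope * a,
    freeze_frac = params$freeze_frac_max * (1 - a)
  )
}

#' Simulate one resident-intruder trial
#'
#' Generates a confidence trace and a pose track for one individual. Each
#' behavior category runs an independent two-state renewal process
#' (exponential dwell times) whose occupancy matches the profile's mean
#' duration; the first fighting off-dwell is drawn around the profile's
#' latency so aggressive individuals attack sooner. Classifier confidence
#' sits near `conf_in` inside true bouts and `conf_out` outside. The body
#' centroid performs a correlated random walk whose speed rises during
#' fighting and drops to zero in freezing spells; the 13 keypoints are
#' placed around the centroid at a fixed carapace width.
#'
#' @param profile One row of [generate_profiles()].
#' @param params A [sim_params()].
#' @param repeat_index Repeat number (its own RNG substream).
#' @return A list with elements `pose` ([pose_track()]) and `trace`
#'   ([confidence_trace()]).
#' @export
simulate_trial <- function(profile, params = sim_params(),
                           repeat_index = 1L) {
  set.seed(sub_seed(params$seed, profile$id, 100L + repeat_index))
  n_frames <- as.integer(round(params$t_total * params$fps))
  fps <- params$fps

  state <- matrix(FALSE, nrow = n_frames, ncol = 3,
                  dimnames = list(NULL, BEHAVIOR_LEVELS))
  mean_dur <- c(anxious = profile$mean_d_anxious,
                demonstration = profile$mean_d_demonstration,
                fighting = profile$mean_d_fighting)
  for (beh in BEHAVIOR_LEVELS) {
    occupancy <- min(0.95, mean_dur[[beh]] / params$t_total)
    if (occupancy <= 0) next
    on_mean <- params$bout_mean_s * fps
    off_mean <- on_mean * (1 - occupancy) / occupancy
    first_off <- if (beh == "fighting") {
      max(profile$mean_latency, 1 / fps) * fps
    } else {
      off_mean
    }
    state[, beh] <- renewal_indicator(n_frames, on_mean, off_mean, first_off)
  }

  jitter <- function(m) {
    runif(n_frames, m - params$conf_noise, m + params$conf_noise)
  }
  prob <- vapply(BEHAVIOR_LEVELS, function(beh) {
    p <- ifelse(state[, beh], jitter(params$conf_in),
                jitter(params$conf_out))
    pmin(1, pmax(0, p))
  }, double(n_frames))
  trace <- confidence_trace(
    tibble::tibble(frame = seq_len(n_frames) - 1L,
                   anxious = prob[, "anxious"],
                   demonstration = prob[, "demonstration"],
                   fighting = prob[, "fighting"]),
    fps = fps
  )

  pose <- simulate_pose(state, profile, params, n_frames)
  list(pose = pose, trace = trace)
}

# Alternating exponential off/on dwell times -> logical indicator.
renewal_indicator <- function(n_frames, on_mean, off_mean, first_off) {
  ind <- logical(n_frames)
  pos <- 1 + rexp(1, 1 / max(first_off, 1))
  on <- TRUE
  while (pos <= n_frames) {
    dwell <- rexp(1, 1 / (if (on) on_mean else off_mean))
    if (on) {
      lo <- as.integer(floor(pos))
      hi <- min(n_frames, as.integer(floor(pos + dwell)))
      if (hi >= lo) ind[lo:hi] <- TRUE
    }
    pos <- pos + dwell + 1
    on <- !on
  }
  ind
}

# Correlated random walk centroid + rigid keypoint layout.
simulate_pose <- function(state, profile, params, n_frames) {
  fps <- params$fps
  freezing <- if (profile$freeze_frac > 0) {
    renewal_indicator(
      n_frames,
      on_mean = params$freeze_mean_s * fps,
      off_mean = params$freeze_mean_s * fps *
        (1 - profile$freeze_frac) / profile$freeze_frac,
      first_off = params$freeze_mean_s * fps
    )
  } else {
    logical(n_frames)
  }
  freezing <- freezing & !state[, "fighting"]

  speed <- rep(profile$speed_px_s, n_frames)
  speed[state[, "fighting"]] <- speed[state[, "fighting"]] *
    params$fight_speed_factor
  speed[freezing] <- 0

  heading <- cumsum(rnorm(n_frames, 0, 0.15))
  step <- speed / fps
  x <- params$arena_px / 2 + cumsum(step * cos(heading))
  y <- params$arena_px / 2 + cumsum(step * sin(heading))
  reflect <- function(v) {
    v <- abs(v)
    m <- v %% (2 * params$arena_px)
    ifelse(m > params$arena_px, 2 * params$arena_px - m, m)
  }
  x <- reflect(x)
  y <- reflect(y)

  cw <- params$carapace_px
  ux <- cos(heading)
  uy <- sin(heading)
  # Perpendicular axis carries the left-right carapace spine pair.
  px <- -uy
  py <- ux
  offsets <- list(
    LBODY = c(-0.5, 0), RBOD = c(0.5, 0), HEAD = c(0, 0.6),
    LFOOTS = c(-0.4, -0.3), LFOOTE = c(-0.8, -0.5),
    RFOOTS = c(0.4, -0.3), RFOOTE = c(0.8, -0.5),
    LCLAWS = c(-0.3, 0.4), LCLAWJ = c(-0.5, 0.7), LCLAWE = c(-0.6, 1.0),
    RCLAWS = c(0.3, 0.4), RCLAWJ = c(0.5, 0.7), RCLAWE = c(0.6, 1.0)
  )
  cols <- list(frame = seq_len(n_frames) - 1L)
  for (kp in KEYPOINTS) {
    o <- offsets[[kp]]
    kx <- x + cw * (o[1] * px + o[2] * ux) + rnorm(n_frames, 0, 0.5)
    ky <- y + cw * (o[1] * py + o[2] * uy) + rnorm(n_frames, 0, 0.5)
    lik <- pmin(1, pmax(0, 1 - rexp(n_frames, 200)))
    # Occasional tracking dropouts.
    dropout <- runif(n_frames) < 0.002
    lik[dropout] <- runif(sum(dropout), 0, 0.5)
    cols[[paste0(kp, "_x")]] <- kx
    cols[[paste0(kp, "_y")]] <- ky
    cols[[paste0(kp, "_likelihood")]] <- lik
  }
  pose_track(tibble::as_tibble(cols), fps = fps)
}

#' Simulate per-individual trial summaries
#'
#' A lightweight alternative to frame-level simulation: draws realized
#' per-trial category durations and first-attack latency directly around
#' each profile's means (lognormal multiplicative noise for durations,
#' truncated normal for latency), already averaged over `n_repeats`.
#' Useful for cohort-scale statistical work where the frame-level detail
#' is irrelevant.
#'
#' @param profiles A [generate_profiles()] tibble.
#' @param params A [sim_params()].
#' @return A trial-summary tibble with one row per individual (`id`,
#'   durations, `t_first`, `n_acts`, `t_total`).
#' @export
simulate_summaries <- function(profiles, params = sim_params()) {
  set.seed(sub_seed(params$seed, 0L, 2L))
  n <- nrow(profiles)
  cv <- params$trial_noise_cv / sqrt(params$n_repeats)
  noise <- function() exp(rnorm(n, -cv^2 / 2, cv))
  t_total <- params$t_total
  lat <- pmin(t_total, pmax(0, rnorm(
    n, profiles$mean_latency, cv * t_total / 4
  )))
  d_anx <- pmin(t_total, profiles$mean_d_anxious * noise())
  d_dem <- pmin(t_total, profiles$mean_d_demonstration * noise())
  d_fig <- pmin(t_total, profiles$mean_d_fighting * noise())
  tibble::tibble(
    id = profiles$id,
    d_anxious = d_anx,
    d_demonstration = d_dem,
    d_fighting = d_fig,
    t_first = lat,
    n_acts = round((d_anx + d_dem + d_fig) / params$bout_mean_s),
    t_total = t_total,
    n_repeats = params$n_repeats
  )
}

#' Simulate hemolymph serotonin concentrations
#'
#' The majority of individuals follow a linear-plus-noise link between
#' latent aggressiveness and serotonin. A discordant fraction (drawn from
#' the lower half of the aggressiveness distribution) instead receives the
#' serotonin level predicted for a highly aggressive animal plus an
#' offset, reproducing the high-serotonin/low-aggression subcluster.
#'
#' @param profiles A [generate_profiles()] tibble.
#' @param params A [sim_params()].
#' @return A tibble: `id`, `ht_ng_ml`, `discordant` (logical).
#' @export
simulate_serotonin <- function(profiles, params = sim_params()) {
  if (nrow(profiles) == 0) {
    abort("profiles must be non-empty", class = "taiscore_parameter_error")
  }
  if (params$ht_noise < 0) {
    abort("ht_noise must be non-negative",
          class = "taiscore_parameter_error")
  }
  set.seed(sub_seed(params$seed, 0L, 3L))
  n <- nrow(profiles)
  ht <- params$ht_intercept + params$ht_slope * profiles$a +
    rnorm(n, 0, params$ht_noise)
  n_disc <- round(params$discordant_fraction * n)
  disc <- rep(FALSE, n)
  if (n_disc > 0) {
    low_half <- order(profiles$a)[seq_len(max(n_disc, ceiling(n / 2)))]
    chosen <- sample(low_half, n_disc)
    high_level <- params$ht_intercept +
      params$ht_slope * stats::quantile(profiles$a, 0.85, names = FALSE)
    ht[chosen] <- high_level + params$discordant_offset +
      rnorm(n_disc, 0, params$ht_noise)
    disc[chosen] <- TRUE
  }
  tibble::tibble(id = profiles$id, ht_ng_ml = pmax(0, ht),
                 discordant = disc)
}

#' Simulate pairing-trial attack counts
#'
#' Attack counts per trial for homogeneous and heterogeneous pairing
#' contexts, drawn from a negative binomial with context-specific means
#' (overdispersed, as the assay's SDs exceed its means) plus optional
#' structural zero inflation. When a context has structural zero
#' probability `pi < 1`, the negative-binomial mean is scaled by
#' `1 / (1 - pi)` so the configured mean is the marginal mean; at
#' `pi = 1` every count is zero.
#'
#' @param n_trials Named integer vector of trials per context; names must
#'   be among `H-H`, `M-M`, `L-L`, `H-L`. Defaults to the assay design
#'   (25/25/25/50).
#' @param params A [sim_params()].
#' @return A tibble: `context`, `trial`, `attacks`.
#' @export
simulate_pairing_trials <- function(n_trials = c("L-L" = 25, "H-H" = 25,
                                                 "M-M" = 25, "H-L" = 50),
                                    params = sim_params()) {
  contexts <- names(n_trials)
  bad <- setdiff(contexts, names(params$pairing_means))
  if (length(bad) > 0) {
    abort(sprintf("unknown pairing context: %s", paste(bad, collapse = ", ")),
          class = "taiscore_parameter_error")
  }
  set.seed(sub_seed(params$seed, 0L, 4L))
  purrr::map_dfr(contexts, function(ctx) {
    n <- n_trials[[ctx]]
    mu <- params$pairing_means[[ctx]]
    pi0 <- if (ctx %in% names(params$zero_inflation)) {
      params$zero_inflation[[ctx]]
    } else {
      0
    }
    counts <- if (pi0 >= 1) {
      rep(0L, n)
    } else {
      nb <- rnbinom(n, size = params$pairing_dispersion,
                    mu = mu / (1 - pi0))
      structural <- rbinom(n, 1, pi0) == 1
      nb[structural] <- 0L
      nb
    }
    tibble::tibble(context = ctx, trial = seq_len(n),
                   attacks = as.integer(counts))
  })
}

#' Simulate a full cohort and score it
#'
#' Convenience wrapper: generates profiles, simulates per-individual trial
#' summaries, scores the index and frequency, and attaches serotonin.
#'
#' @param params A [sim_params()].
#' @param weights A [tai_weights()].
#' @return A cohort tibble: `id`, `a`, `tai`, `frequency`, `ht_ng_ml`,
#'   `discordant`, plus the summary fields.
#' @export
simulate_cohort <- function(params = sim_params(),
                            weights = tai_weights()) {
  profiles <- generate_profiles(params)
  summaries <- simulate_summaries(profiles, params)
  ht <- simulate_serotonin(profiles, params)
  summaries |>
    dplyr::mutate(
      a = profiles$a,
      tai = compute_tai(summaries, weights),
      frequency = aggression_frequency(summaries)
    ) |>
    dplyr::left_join(ht, by = "id") |>
    dplyr::select("id", "a", "tai", "frequency", "ht_ng_ml", "discordant",
                  dplyr::everything())
}
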