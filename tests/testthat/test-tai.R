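test_that("the index evaluates its closed form exactly", {
  null_trial <- tibble::tibble(d_anxious = 0, d_demonstration = 0,
                               d_fighting = 0, t_first = 1800,
                               t_total = 1800)
  expect_equal(compute_tai(null_trial), 0)

  max_fight <- tibble::tibble(d_anxious = 0, d_demonstration = 0,
                              d_fighting = 1800, t_first = 0,
                              t_total = 1800)
  expect_equal(compute_tai(max_fight), 0.65)

  mixed <- tibble::tibble(d_anxious = 300, d_demonstration = 200,
                          d_fighting = 100, t_first = 600, t_total = 1800)
  expect_equal(compute_tai(mixed), (42 + 42 + 35) / 1800 + 0.3 * 1200 / 1800,
               tolerance = 1e-12)
  expect_equal(round(compute_tai(mixed), 5), 0.26611)

  bad <- dplyr::mutate(mixed, t_total = 0)
  expect_error(compute_tai(bad), class = "taiscore_parameter_error")
})

test_that("the index is monotone in durations and latency, and homogeneous", {
  set.seed(31)
  base <- tibble::tibble(d_anxious = 100, d_demonstration = 120,
                         d_fighting = 150, t_first = 700, t_total = 1800)
  t0 <- compute_tai(base)
  for (col in c("d_anxious", "d_demonstration", "d_fighting")) {
    up <- base
    up[[col]] <- up[[col]] + 50
    expect_gt(compute_tai(up), t0)
  }
  earlier <- dplyr::mutate(base, t_first = t_first - 100)
  expect_gt(compute_tai(earlier), t0)

  w <- tai_weights()
  w2 <- tai_weights(2 * w$w_anxious, 2 * w$w_demonstration,
                    2 * w$w_fighting, 2 * w$w_latency)
  expect_equal(compute_tai(base, w2), 2 * t0, tolerance = 1e-12)

  # linear in the duration vector at fixed latency
  a <- dplyr::mutate(base, t_first = 500)
  b <- dplyr::mutate(base, d_anxious = 30, d_demonstration = 40,
                     d_fighting = 50, t_first = 500)
  ab <- dplyr::mutate(base,
                      d_anxious = d_anxious + 30,
                      d_demonstration = d_demonstration + 40,
                      d_fighting = d_fighting + 50, t_first = 500)
  zero <- dplyr::mutate(base, d_anxious = 0, d_demonstration = 0,
                        d_fighting = 0, t_first = 500)
  expect_equal(compute_tai(ab) + compute_tai(zero),
               compute_tai(a) + compute_tai(b), tolerance = 1e-12)
})

test_that("default weights sum to one and rescaling divides by the maximum", {
  w <- tai_weights()
  expect_identical(w$w_anxious + w$w_demonstration + w$w_fighting +
                     w$w_latency, 1.00)
  s <- tibble::tibble(d_anxious = 1800, d_demonstration = 1800,
                      d_fighting = 1800, t_first = 0, t_total = 1800)
  expect_equal(compute_tai(s, rescale_max = TRUE), 1)
})

test_that("aggression frequency is acts per second", {
  expect_equal(aggression_frequency(
    tibble::tibble(n_acts = 0, t_total = 1800)), 0)
  expect_equal(aggression_frequency(
    tibble::tibble(n_acts = 18, t_total = 1800)), 0.01)
  expect_equal(aggression_frequency(
    tibble::tibble(n_acts = 1800, t_total = 1800)), 1)
  expect_error(aggression_frequency(
    tibble::tibble(n_acts = 1, t_total = 0)),
    class = "taiscore_parameter_error")
})

test_that("repeat averaging is a field-wise mean with validation", {
  cfg <- tai_config()
  one <- tibble::tibble(d_anxious = 10, d_demonstration = 20,
                        d_fighting = 30, t_first = 600, n_acts = 12,
                        t_total = 1800, x1 = 5, x2 = 40)
  five <- dplyr::bind_rows(rep(list(one), 5))
  avg <- average_repeats(five, cfg)
  expect_equal(avg$n_repeats, 5)
  expect_equal(avg$d_fighting, 30)
  expect_equal(avg$x1, 5)

  two <- dplyr::bind_rows(
    dplyr::mutate(one, t_first = 0),
    dplyr::mutate(one, t_first = 1800)
  )
  expect_warning(avg2 <- average_repeats(two, cfg), "2 repeats")
  expect_equal(avg2$t_first, 900)

  mixed <- dplyr::bind_rows(one, dplyr::mutate(one, t_total = 900))
  expect_error(average_repeats(mixed, cfg),
               class = "taiscore_parameter_error")
  expect_error(average_repeats(one[0, ], cfg),
               class = "taiscore_parameter_error")
})

make_weight_cohort <- function(n, seed, noise_frac = 0) {
  set.seed(seed)
  co <- tibble::tibble(
    d_anxious = runif(n, 0, 400),
    d_demonstration = runif(n, 0, 400),
    d_fighting = runif(n, 0, 400),
    t_first = runif(n, 0, 1800),
    t_total = 1800
  )
  resp <- with(co, 0.14 * d_anxious + 0.21 * d_demonstration +
                 0.35 * d_fighting + 0.3 * (t_total - t_first)) / 1800
  co$frequency <- resp + rnorm(n, 0, noise_frac * sd(resp))
  co
}

test_that("weight derivation recovers the generating ratios", {
  fit <- derive_weights(make_weight_cohort(200, seed = 101))
  w <- fit$weights
  expect_equal(
    c(w$w_anxious, w$w_demonstration, w$w_fighting, w$w_latency),
    c(0.14, 0.21, 0.35, 0.30), tolerance = 1e-6
  )
  expect_gt(suppressWarnings(glance(fit))$r_squared, 1 - 1e-9)
  expect_equal(sum(tidy(fit)$weight), 1, tolerance = 1e-12)

  # 5% response noise: each weight within 0.02 of truth
  for (s in 1:5) {
    wn <- derive_weights(make_weight_cohort(200, seed = 200 + s,
                                            noise_frac = 0.05))$weights
    expect_equal(
      c(wn$w_anxious, wn$w_demonstration, wn$w_fighting, wn$w_latency),
      c(0.14, 0.21, 0.35, 0.30), tolerance = 0.02
    )
  }
})

test_that("weight derivation flags degenerate designs and sign loss", {
  co <- make_weight_cohort(50, seed = 300)
  co$d_anxious <- 100
  expect_error(derive_weights(co), "d_anxious",
               class = "taiscore_estimation_error")

  neg <- make_weight_cohort(100, seed = 301)
  neg$frequency <- with(neg, -0.5 * d_anxious + 0.3 * d_fighting +
                          0.2 * (t_total - t_first)) / 1800
  expect_warning(fit <- derive_weights(neg), "negative coefficient")
  expect_gte(fit$weights$w_anxious, 0)

  expect_error(derive_weights(make_weight_cohort(5, seed = 302)),
               class = "taiscore_parameter_error")
})

test_that("cohort scoring composes the pipeline deterministically", {
  cfg <- tai_config(trial_duration_s = 30, n_repeats = 1)
  p <- rep(0.1, 900)
  p[101:200] <- 0.9
  trace <- make_trace(p)
  quiet <- make_trace(rep(0.1, 900))

  trials <- tibble::tibble(
    id = c(1L, 2L, 3L),
    trace = list(trace, trace, quiet)
  )
  co <- suppressWarnings(score_cohort(trials, cfg))
  expect_equal(nrow(co), 3)
  expect_equal(co$tai[1], co$tai[2]) # identical inputs, identical rows
  expect_equal(co$tai[3], 0)         # no supra-threshold frames
  expect_gt(co$tai[1], 0)
  expect_equal(co$frequency[1], 1 / 30)
})
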