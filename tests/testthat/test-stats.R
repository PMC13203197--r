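test_that("quartile stratification yields floor(q n) per extreme group", {
  set.seed(41)
  g200 <- stratify(rnorm(200), 0.25)
  expect_equal(as.integer(table(g200)), c(50, 100, 50))

  g4 <- stratify(c(4, 2, 3, 1), 0.25)
  expect_equal(as.integer(table(g4)), c(1, 2, 1))
  expect_equal(as.character(g4), c("HA", "MA", "MA", "LA"))

  # all-equal scores: ties broken by stable input order, sizes unchanged
  gt <- stratify(rep(1, 200), 0.25)
  expect_equal(as.integer(table(gt)), c(50, 100, 50))
  expect_equal(as.character(gt[1:50]), rep("HA", 50))

  expect_error(stratify(1:3), class = "taiscore_parameter_error")
})

test_that("stratification partitions with ordered group scores", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(20:300, 1))
    g <- stratify(x)
    expect_equal(length(g), length(x))
    expect_gte(min(x[g == "HA"]), max(x[g == "MA"]) - 1e-12)
    expect_gte(min(x[g == "MA"]), max(x[g == "LA"]) - 1e-12)
  }
})

test_that("the normality gate dispatches by test level and power", {
  parametric <- vapply(1:20, function(s) {
    set.seed(s)
    normality_gate(rnorm(500))$branch == "parametric"
  }, logical(1))
  expect_gte(mean(parametric), 0.9)

  nonparam <- vapply(1:20, function(s) {
    set.seed(s)
    normality_gate(rexp(500)^2)$branch == "nonparametric"
  }, logical(1))
  expect_equal(mean(nonparam), 1)

  set.seed(1)
  ks <- normality_gate(rnorm(100), method = "ks")
  expect_true(ks$branch %in% c("parametric", "nonparametric"))
  expect_error(normality_gate(rep(1, 10)),
               class = "taiscore_parameter_error")
  expect_error(normality_gate(c(1, 2)), class = "taiscore_parameter_error")
})

test_that("z-scores standardize to mean 0 and unit sample SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(43)
  for (i in 1:10) {
    z <- zscore(rnorm(50, 100, 20))
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_error(zscore(rep(2, 5)), class = "taiscore_parameter_error")
})

test_that("correlation handles both methods and the hand-checked case", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlate(x, -x, "pearson")$estimate, -1)
  expect_equal(
    correlate(c(1, 2, 3, 4), c(2, 1, 4, 3), "pearson")$estimate, 0.6
  )
  expect_equal(
    correlate(c(1, 2, 3, 4), c(2, 1, 4, 3), "spearman")$estimate, 0.6
  )
  expect_error(correlate(x, rep(1, 10)), class = "taiscore_parameter_error")
  expect_error(correlate(1:3, 1:4), class = "taiscore_parameter_error")
})

test_that("the reference regression model evaluates exactly", {
  expect_equal(reference_model_predict(0, 0), -0.002)
  expect_equal(reference_model_predict(10, 100), 0.128)
  expect_equal(reference_model_predict(1, 1), 0.020)
})

test_that("ICC matches the independent ANOVA oracle", {
  # identical columns: perfect consistency
  m <- cbind(1:6, 1:6)
  fit <- icc_consistency(m)
  expect_equal(fit$icc1, 1)
  expect_equal(fit$icck, 1)

  # frozen values from a two-way ANOVA oracle (stats::aov decomposition)
  m2 <- matrix(c(3, 5, 2, 8, 6, 4,
                 4, 6, 1, 9, 7, 5), ncol = 2)
  fit2 <- icc_consistency(m2)
  expect_equal(fit2$msr, 11.8, tolerance = 1e-10)
  expect_equal(fit2$mse, 1 / 3, tolerance = 1e-10)
  expect_equal(fit2$icc1, 0.9450549451, tolerance = 1e-9)
  expect_equal(fit2$icck, 0.9717514124, tolerance = 1e-9)

  # and against aov() computed here, on random data
  set.seed(44)
  m3 <- matrix(rnorm(40), ncol = 4)
  df <- data.frame(y = as.vector(m3),
                   subj = factor(rep(1:10, 4)),
                   meth = factor(rep(1:4, each = 10)))
  tab <- summary(stats::aov(y ~ subj + meth, data = df))[[1]]
  fit3 <- icc_consistency(m3)
  expect_equal(fit3$msr, tab["subj", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit3$mse, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(icc_consistency(matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10),
                                      ncol = 2)),
               class = "taiscore_parameter_error")
})

test_that("direct average-measure ICC equals the Spearman-Brown relation", {
  set.seed(45)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    n <- sample(6:30, 1)
    subj <- rnorm(n, 0, 2)
    m <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k) +
      outer(rep(1, n), rnorm(k)) # column offsets: consistency ignores them
    fit <- icc_consistency(m)
    expect_equal(fit$icck, spearman_brown(fit$icc1, k), tolerance = 1e-12)
  }
})

test_that("Spearman-Brown handles the published value and its domain", {
  expect_equal(round(spearman_brown(0.554, 2), 3), 0.713)
  expect_equal(spearman_brown(1, 7), 1)
  expect_equal(spearman_brown(0.5, 2), 2 / 3, tolerance = 1e-12)
  expect_error(spearman_brown(-0.9, 5), class = "taiscore_domain_error")
  expect_error(spearman_brown(1.2, 2), class = "taiscore_parameter_error")
})

test_that("Bland-Altman reports differences, limits and coverage", {
  a <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  ba5 <- bland_altman(a, a + 5)
  expect_equal(ba5$mean_diff, -5)
  expect_equal(diff(ba5$loa), 0, ignore_attr = TRUE)

  set.seed(46)
  d <- rnorm(10000)
  ba <- bland_altman(d, rep(0, 10000))
  expect_equal(ba$frac_within_loa, 0.95, tolerance = 0.01)
  expect_true(abs(ba$loa[1] + 1.96) < 0.05 && abs(ba$loa[2] - 1.96) < 0.05)

  expect_error(bland_altman(1:4, 1:5), class = "taiscore_parameter_error")
})

test_that("pairing analysis reproduces the rank-formula H and Dunn tables", {
  toy <- tibble::tibble(context = c("a", "a", "b", "b"),
                        attacks = c(1, 2, 3, 4))
  rep_toy <- pairing_analysis(toy)
  expect_equal(rep_toy$kw$statistic, 2.4) # hand rank formula
  expect_equal(rep_toy$kw$statistic,
               hand_kw_h(toy$attacks, toy$context))
  expect_equal(rep_toy$kw$df, 1)

  set.seed(47)
  four <- tibble::tibble(
    context = rep(c("H-H", "M-M", "L-L", "H-L"), each = 12),
    attacks = c(rnbinom(12, 3, mu = 7), rnbinom(12, 3, mu = 2.2),
                rnbinom(12, 3, mu = 1), rnbinom(12, 3, mu = 2.4))
  )
  rep4 <- pairing_analysis(four)
  expect_equal(rep4$kw$df, 3)
  expect_equal(rep4$kw$statistic, hand_kw_h(four$attacks, four$context),
               tolerance = 1e-12)
  expect_equal(nrow(rep4$dunn), 6)
  expect_true(all(rep4$dunn$p_adjusted >= rep4$dunn$p_value - 1e-15))
  expect_true(all(rep4$dunn$p_adjusted <= 1))
  expect_equal(glance(rep4)$df, 3)

  thin <- tibble::tibble(context = c("a", "a", "b"), attacks = c(1, 2, 3))
  expect_error(pairing_analysis(thin), "b",
               class = "taiscore_parameter_error")
})

test_that("the Kruskal-Wallis path holds its type-I error under the null", {
  set.seed(48)
  rejections <- vapply(1:1000, function(i) {
    x <- rnorm(40)
    g <- rep(letters[1:4], each = 10)
    kruskal.test(x, factor(g))$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), 2.5 * se)
})

test_that("group differences dispatch on the normality gate", {
  set.seed(49)
  x <- rnorm(50)
  same <- group_difference_test(list(a = x, b = x), "parametric")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_equal(same$method, "welch_t")

  four <- group_difference_test(
    list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10)),
    "nonparametric"
  )
  expect_s3_class(four, "pairing_report")

  # power: 1 SD shift at n = 200 rejects essentially always
  power <- vapply(1:10, function(s) {
    set.seed(900 + s)
    g1 <- rnorm(200)
    g2 <- rnorm(200, 1)
    group_difference_test(list(g1, g2), "parametric")$p_value < 0.05
  }, logical(1))
  expect_equal(mean(power), 1)
})

test_that("annotation split and accuracy arithmetic are exact", {
  sp <- holdout_split(5280, 0.8)
  expect_equal(sp$train, 4224L)
  expect_equal(sp$test, 1056L)

  acc <- classifier_accuracy_summary(c(91, 94, 93), unclassified_pct = 3)
  expect_equal(round(acc$mean_accuracy_pct, 1), 92.7)
  expect_equal(round(acc$misclassification_pct, 1), 4.3)
})
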