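#' Stratify a cohort into aggression groups
#'
#' Assigns the `floor(q * n)` highest scores to the high-aggression group
#' (HA), the `floor(q * n)` lowest to the low-aggression group (LA) and
#' the remainder to the medium group (MA). Ties at a boundary are broken
#' by stable input order: earlier individuals claim the extreme group
#' first. At `n = 200` and `q = 0.25` this yields exactly 50/100/50.
#'
#' @param scores Numeric vector of aggression scores (length >= 4).
#' @param quartile_fraction Fraction per extreme group, in `(0, 0.5]`.
#' @return A factor of labels `HA`, `MA`, `LA`, same length as `scores`.
#' @examples
#' table(stratify(rnorm(200)))
#' @export
stratify <- function(scores, quartile_fraction = 0.25) {
  n <- length(scores)
  if (n < 4) {
    abort("stratification needs at least 4 scores",
          class = "taiscore_parameter_error")
  }
  if (quartile_fraction <= 0 || quartile_fraction > 0.5) {
    abort("quartile_fraction must lie in (0, 0.5]",
          class = "taiscore_parameter_error")
  }
  n_q <- floor(quartile_fraction * n)
  labels <- rep("MA", n)
  ord_desc <- order(-scores) # radix sort: stable for ties
  ha <- ord_desc[seq_len(n_q)]
  labels[ha] <- "HA"
  remaining <- setdiff(seq_len(n), ha)
  la <- remaining[order(scores[remaining])][seq_len(n_q)]
  labels[la] <- "LA"
  factor(labels, levels = c("HA", "MA", "LA"))
}

#' Normality gate
#'
#' Tests whether a sample is compatible with a normal distribution and
#' returns the analysis branch: parametric when the test does not reject
#' (p > alpha), nonparametric otherwise. Shapiro-Wilk by default;
#' Kolmogorov-Smirnov (against a normal with the sample's moments) is
#' selectable.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @param alpha Significance level of the gate.
#' @param method `"shapiro"` or `"ks"`.
#' @return A list: `branch` (`"parametric"`/`"nonparametric"`),
#'   `statistic`, `p_value`, `method`.
#' @export
normality_gate <- function(values, alpha = 0.05, method = c("shapiro", "ks")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    abort("normality test needs at least 3 values",
          class = "taiscore_parameter_error")
  }
  if (sd(values) == 0) {
    abort("normality test undefined for a constant sample",
          class = "taiscore_parameter_error")
  }
  res <- if (method == "shapiro") {
    shapiro.test(values)
  } else {
    suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  }
  list(
    branch = if (res$p.value > alpha) "parametric" else "nonparametric",
    statistic = unname(res$statistic),
    p_value = res$p.value,
    method = method
  )
}

#' Z-score standardization
#'
#' Centers and scales to sample mean 0 and sample SD 1 (denominator
#' `n - 1`).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Standardized vector.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  if (length(values) < 2) {
    abort("z-score needs at least 2 values",
          class = "taiscore_parameter_error")
  }
  s <- sd(values)
  if (is.na(s) || s == 0) {
    abort("z-score undefined for a constant sample",
          class = "taiscore_parameter_error")
  }
  (values - mean(values)) / s
}

#' Correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    abort("x and y must have equal length",
          class = "taiscore_parameter_error")
  }
  if (length(x) < 3) {
    abort("correlation needs at least 3 pairs",
          class = "taiscore_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined when either input has zero variance",
          class = "taiscore_parameter_error")
  }
  res <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(
    estimate = unname(res$estimate),
    p_value = res$p.value,
    n = length(x),
    method = method
  )
}

#' Reference regression-model prediction
#'
#' Evaluates the previously established two-predictor aggression model
#' `Y = 0.023 X1 - 0.001 X2 - 0.002`, where X1 is relative movement
#' distance and X2 freezing duration. Used as the comparison method in the
#' agreement battery.
#'
#' @param x1 Relative movement distance (dimensionless).
#' @param x2 Freezing duration (s).
#' @return Predicted aggression score(s).
#' @examples
#' reference_model_predict(10, 100)
#' @export
reference_model_predict <- function(x1, x2) {
  0.023 * x1 - 0.001 * x2 - 0.002
}

#' Intraclass correlation, two-way consistency model
#'
#' Single-measure ICC(C,1) and average-measure ICC(C,K) from the two-way
#' ANOVA decomposition of an n-subjects-by-k-measurements matrix, with
#' F-based 95% confidence intervals. Consistency agreement: the column
#' (method) effect is removed, so a constant offset between methods does
#' not reduce the coefficient.
#'
#' @param ratings Numeric matrix (or data frame), subjects in rows,
#'   measurements/methods in columns; n >= 5, k >= 2, no missing cells.
#' @param conf_level Confidence level of the intervals.
#' @return An object of class `icc_fit`: `icc1`, `icck`, `ci1`, `cik`,
#'   mean squares, `n`, `k`. Supports [tidy()].
#' @export
icc_consistency <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) {
    abort("ICC requires a complete matrix (no missing cells)",
          class = "taiscore_parameter_error")
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5 || k < 2) {
    abort("ICC needs at least 5 subjects and 2 measurements",
          class = "taiscore_parameter_error")
  }
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df_r <- n - 1
  df_e <- (n - 1) * (k - 1)
  msr <- ss_rows / df_r
  mse <- ss_err / df_e
  icc1 <- (msr - mse) / (msr + (k - 1) * mse)
  icck <- (msr - mse) / msr
  alpha <- 1 - conf_level
  f_obs <- msr / mse
  fl <- f_obs / qf(1 - alpha / 2, df_r, df_e)
  fu <- f_obs * qf(1 - alpha / 2, df_e, df_r)
  structure(
    list(
      icc1 = icc1,
      icck = icck,
      ci1 = c(lower = (fl - 1) / (fl + k - 1),
              upper = (fu - 1) / (fu + k - 1)),
      cik = c(lower = 1 - 1 / fl, upper = 1 - 1 / fu),
      msr = msr, mse = mse, n = n, k = k,
      conf_level = conf_level
    ),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "ICC(C,1) = %.3f [%.3f, %.3f]; ICC(C,%d) = %.3f [%.3f, %.3f] (n = %d)\n",
    x$icc1, x$ci1[1], x$ci1[2], x$k, x$icck, x$cik[1], x$cik[2], x$n
  ))
  invisible(x)
}

#' Single-to-average measurement reliability (Spearman-Brown)
#'
#' Converts a single-measurement intraclass correlation to the reliability
#' of the mean of k measurements: `k * icc1 / (1 + (k - 1) * icc1)`.
#'
#' @param icc1 Single-measure ICC, in `(-1, 1]`.
#' @param k Number of measurements averaged (>= 1).
#' @return The average-measure ICC.
#' @examples
#' spearman_brown(0.554, 2)
#' @export
spearman_brown <- function(icc1, k) {
  if (any(icc1 <= -1) || any(icc1 > 1) || any(k < 1)) {
    abort("icc1 must lie in (-1, 1] and k must be >= 1",
          class = "taiscore_parameter_error")
  }
  den <- 1 + (k - 1) * icc1
  if (any(den <= 0)) {
    abort("Spearman-Brown denominator is non-positive",
          class = "taiscore_domain_error")
  }
  k * icc1 / den
}

#' Bland-Altman agreement analysis
#'
#' Pairwise differences `a - b` with their mean, 95% limits of agreement
#' (mean +/- 1.96 SD), the confidence interval of the mean difference and
#' the fraction of points inside the limits.
#'
#' @param a,b Numeric vectors of equal length >= 3 (the two methods'
#'   measurements, pairwise).
#' @return An object of class `bland_altman`: `mean_diff`, `loa`
#'   (lower/upper), `ci_mean` (lower/upper), `frac_within_loa`, `n` and
#'   the per-pair `data`. Supports [tidy()] and [autoplot()].
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    abort("a and b must have equal length",
          class = "taiscore_parameter_error")
  }
  if (length(a) < 3) {
    abort("Bland-Altman needs at least 3 pairs",
          class = "taiscore_parameter_error")
  }
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  loa <- c(lower = md - 1.96 * s, upper = md + 1.96 * s)
  ci <- c(lower = md - 1.96 * s / sqrt(length(d)),
          upper = md + 1.96 * s / sqrt(length(d)))
  structure(
    list(
      mean_diff = md,
      loa = loa,
      ci_mean = ci,
      frac_within_loa = mean(d >= loa[1] & d <= loa[2]),
      n = length(d),
      data = tibble::tibble(mean = (a + b) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean diff %.4f [%.4f, %.4f], LoA [%.4f, %.4f], %.1f%% within (n = %d)\n",
    x$mean_diff, x$ci_mean[1], x$ci_mean[2], x$loa[1], x$loa[2],
    100 * x$frac_within_loa, x$n
  ))
  invisible(x)
}

#' Pairing-trial analysis: Kruskal-Wallis with Dunn's post hoc
#'
#' Compares attack counts across pairing contexts with a tie-corrected
#' Kruskal-Wallis test, followed by Dunn's pairwise z tests on mean ranks
#' with Bonferroni adjustment over all pairwise comparisons.
#'
#' @param data A tibble with columns `context` (group label) and `attacks`
#'   (count or score per trial), e.g. from [simulate_pairing_trials()].
#' @return An object of class `pairing_report`: per-context `summary`
#'   (n, mean, sd), `kw` (H statistic, df, p), and the Dunn table
#'   `dunn` (comparison, z, p, adjusted p). Supports [tidy()] and
#'   [glance()].
#' @export
pairing_analysis <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("context", "attacks") %in% names(data))) {
    abort("pairing data needs columns `context` and `attacks`",
          class = "taiscore_parameter_error")
  }
  counts <- table(data$context)
  if (length(counts) < 2) {
    abort("pairing analysis needs at least 2 contexts",
          class = "taiscore_parameter_error")
  }
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    abort(sprintf("context with fewer than 2 trials: %s",
                  paste(thin, collapse = ", ")),
          class = "taiscore_parameter_error")
  }
  grp <- factor(data$context)
  kw <- kruskal.test(data$attacks, grp)
  summary_tbl <- data |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$attacks),
      sd = sd(.data$attacks),
      zero_fraction = mean(.data$attacks == 0),
      .groups = "drop"
    )
  dunn <- dunn_posthoc(data$attacks, grp)
  structure(
    list(
      summary = summary_tbl,
      kw = list(statistic = unname(kw$statistic),
                df = unname(kw$parameter),
                p_value = kw$p.value),
      dunn = dunn
    ),
    class = "pairing_report"
  )
}

# Dunn's pairwise z tests on mean ranks with tie-corrected variance and
# Bonferroni adjustment over all pairs.
dunn_posthoc <- function(x, grp) {
  N <- length(x)
  r <- rank(x)
  lv <- levels(grp)
  rbar <- tapply(r, grp, mean)
  nn <- tapply(r, grp, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sigma2_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    se <- sqrt(sigma2_base * (1 / nn[[g1]] + 1 / nn[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(
      comparison = paste(g1, "vs", g2),
      z = z,
      p_value = p,
      p_adjusted = min(1, p * m)
    )
  })
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.2f, df = %d, p = %.3g\n",
              x$kw$statistic, x$kw$df, x$kw$p_value))
  print(x$summary)
  cat("Dunn's post hoc (Bonferroni adjusted):\n")
  print(x$dunn)
  invisible(x)
}

#' Group-difference test dispatched on the normality gate
#'
#' With exactly two groups on the parametric branch, a Welch two-sample
#' t-test; otherwise the Kruskal-Wallis path (with Dunn's post hoc when
#' more than two groups are given).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param gate `"parametric"`, `"nonparametric"`, or the result of
#'   [normality_gate()].
#' @return For the t-test and two-group KW, a one-row tibble
#'   (`statistic`, `p_value`, `method`); for > 2 nonparametric groups,
#'   a [pairing_analysis()] report.
#' @export
group_difference_test <- function(groups, gate = "parametric") {
  if (is.list(gate) && !is.null(gate$branch)) gate <- gate$branch
  if (!gate %in% c("parametric", "nonparametric")) {
    abort("gate must be 'parametric' or 'nonparametric'",
          class = "taiscore_parameter_error")
  }
  if (length(groups) < 2) {
    abort("need at least 2 groups", class = "taiscore_parameter_error")
  }
  if (length(groups) == 2 && gate == "parametric") {
    res <- stats::t.test(groups[[1]], groups[[2]])
    return(tibble::tibble(
      statistic = unname(res$statistic),
      p_value = res$p.value,
      method = "welch_t"
    ))
  }
  long <- tibble::tibble(
    context = rep(names(groups) %||% as.character(seq_along(groups)),
                  lengths(groups)),
    attacks = unlist(groups, use.names = FALSE)
  )
  if (length(groups) == 2) {
    kw <- kruskal.test(long$attacks, factor(long$context))
    return(tibble::tibble(
      statistic = unname(kw$statistic),
      p_value = kw$p.value,
      method = "kruskal_wallis"
    ))
  }
  pairing_analysis(long)
}

#' Split counts for a training/test partition
#'
#' @param n Total number of annotated items.
#' @param train_frac Fraction assigned to training.
#' @return A list with integer `train` and `test` counts summing to `n`.
#' @examples
#' holdout_split(5280, 0.8)
#' @export
holdout_split <- function(n, train_frac = 0.8) {
  if (n < 1 || train_frac < 0 || train_frac > 1) {
    abort("invalid split", class = "taiscore_parameter_error")
  }
  train <- as.integer(floor(n * train_frac))
  list(train = train, test = as.integer(n) - train)
}

#' Summarize classifier accuracy
#'
#' Mean of per-class accuracies and the implied overall misclassification
#' rate given the unclassified residual: `100 - mean - unclassified`
#' (percentages).
#'
#' @param per_class_pct Per-class accuracies in percent.
#' @param unclassified_pct Percentage of frames left unclassified.
#' @return A one-row tibble: `mean_accuracy_pct`,
#'   `misclassification_pct`, `unclassified_pct`.
#' @examples
#' classifier_accuracy_summary(c(91, 94, 93), 3)
#' @export
classifier_accuracy_summary <- function(per_class_pct, unclassified_pct = 0) {
  m <- mean(per_class_pct)
  tibble::tibble(
    mean_accuracy_pct = m,
    misclassification_pct = 100 - m - unclassified_pct,
    unclassified_pct = unclassified_pct
  )
}
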