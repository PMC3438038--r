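# Cohort-level statistics: correlation with least-squares line, paired and
# two-group comparisons with normality-based test selection, the two-group
# sample-size computation, and Table-style cohort summaries.

#' Pearson correlation with least-squares line
#'
#' Pearson r, r-squared, two-sided p from the t transform, and the
#' least-squares slope and intercept of y on x.
#'
#' @param x,y Finite numeric vectors of equal length (>= 3).
#' @return A `correlation_result`: list with `r`, `r_squared`, `p`, `n`,
#'   `slope`, `intercept`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::coef(stats::lm(y ~ x))
  structure(list(r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p = ct$p.value,
                 n = length(x),
                 slope = unname(fit[2]),
                 intercept = unname(fit[1])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (r^2 = %.3f), p = %.3g, n = %d; y = %.4g + %.4g x\n",
              x$r, x$r_squared, x$p, x$n, x$intercept, x$slope))
  invisible(x)
}

# Kolmogorov-Smirnov normality check against a normal with the sample's
# own mean and SD (returns NA for degenerate samples).
ks_normality_p <- function(x) {
  if (stats::sd(x) == 0) return(NA_real_)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' Paired or two-group comparison
#'
#' Runs the paired or independent-samples t-test when the data look normal,
#' otherwise the Wilcoxon signed-rank or Mann-Whitney test. When
#' `parametric` is not given, normality is checked with the
#' Kolmogorov-Smirnov test (on the paired differences, or on each arm) and
#' the nonparametric test is chosen if any check rejects at 0.05. All tests
#' are two-sided.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired comparison?
#' @param parametric Force the t-test (`TRUE`) or rank test (`FALSE`);
#'   `NULL` (default) auto-selects via the normality check.
#' @return A `comparison_result`: list with `test`, `statistic`, `p`, `n`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `paired`, `flag`.
#' @export
compare_groups <- function(a, b, paired = FALSE, parametric = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations per arm")
  if (paired && length(a) != length(b)) stop("paired arms must have equal length")
  flag <- "ok"
  eps <- 1e-12 * max(1, abs(mean(a)), abs(mean(b)))
  degenerate <- if (paired) stats::sd(a - b) <= eps else
    (stats::sd(a) <= eps && stats::sd(b) <= eps)
  if (degenerate) {
    identical_arms <- if (paired) all(a == b) else FALSE
    res <- list(test = if (paired) "paired t-test" else "t-test",
                statistic = 0,
                p = if (identical_arms) 1 else NA_real_,
                n = length(a),
                mean_a = mean(a), sd_a = stats::sd(a),
                mean_b = mean(b), sd_b = stats::sd(b),
                paired = paired,
                flag = "degenerate: zero-variance differences")
    return(structure(res, class = "comparison_result"))
  }
  if (is.null(parametric)) {
    ps <- if (paired) ks_normality_p(a - b) else
      c(ks_normality_p(a), ks_normality_p(b))
    parametric <- !any(ps < 0.05, na.rm = TRUE)
  }
  if (parametric) {
    ht <- stats::t.test(a, b, paired = paired)
    test <- if (paired) "paired t-test" else "t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p = ht$p.value,
                 n = length(a),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 paired = paired,
                 flag = flag),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.3g, n = %d (%s)\n",
              x$test, x$statistic, x$p, x$n,
              if (x$paired) "paired" else "independent"))
  cat(sprintf("  a: %.3f +/- %.3f   b: %.3f +/- %.3f\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Two-group sample size under the normal approximation
#'
#' Per-group `n = ceil( 2 * ((z_{1-alpha/2} + z_{power}) * sd / delta)^2 )`;
#' returns the total over both groups. With `delta = 0.04`, `sd = 0.03`,
#' `alpha = 0.05` and 80% power this gives a total of 18.
#'
#' @param delta Smallest difference to detect (> 0).
#' @param sd Common SD (> 0).
#' @param alpha Two-sided significance level.
#' @param power Desired power (fraction).
#' @return Total n over both groups (even integer).
#' @export
two_group_sample_size <- function(delta, sd, alpha = 0.05, power = 0.8) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  per_group <- ceiling(2 * (z * sd / delta)^2)
  2 * per_group
}

#' Analytic power of the paired t-test
#'
#' Closed-form power for detecting a mean paired difference `delta` with
#' difference SD `sd` at sample size `n` (noncentral t).
#'
#' @param delta Mean of the paired differences.
#' @param sd SD of the paired differences.
#' @param n Number of pairs.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
paired_t_power <- function(delta, sd, n, alpha = 0.05) {
  ncp <- delta / (sd / sqrt(n))
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  stats::pt(-crit, df = n - 1, ncp = ncp) +
    1 - stats::pt(crit, df = n - 1, ncp = ncp)
}

#' Summarise a cohort table with baseline/follow-up pairs
#'
#' Mean and SD for every summarised column; for columns declared as
#' baseline/follow-up pairs, a paired comparison p-value
#' ([compare_groups()]).
#'
#' @param table A `cohort_table` (or data frame).
#' @param pairs Named list; each element `c(baseline_col, followup_col)`.
#' @param columns Additional single columns to summarise; default all
#'   numeric columns not used in `pairs` (minus `subject`).
#' @return A `cohort_summary` data frame with columns `variable`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`, `p`.
#' @export
summarize_cohort <- function(table,
                             pairs = list(CURE = c("CURE_acute",
                                                   "CURE_followup")),
                             columns = NULL) {
  needed <- unique(unlist(pairs))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(columns)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    columns <- setdiff(num, c("subject", needed))
  }
  rows <- list()
  for (nm in names(pairs)) {
    a <- table[[pairs[[nm]][1]]]
    b <- table[[pairs[[nm]][2]]]
    cmp <- compare_groups(a, b, paired = TRUE)
    rows[[nm]] <- data.frame(variable = nm,
                             baseline_mean = mean(a), baseline_sd = stats::sd(a),
                             followup_mean = mean(b), followup_sd = stats::sd(b),
                             p = cmp$p)
  }
  for (nm in columns) {
    x <- table[[nm]]
    rows[[nm]] <- data.frame(variable = nm,
                             baseline_mean = mean(x), baseline_sd = stats::sd(x),
                             followup_mean = NA_real_, followup_sd = NA_real_,
                             p = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}
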