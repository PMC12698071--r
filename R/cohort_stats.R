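#' Group summary with a normal-approximation confidence interval
#'
#' Mean, standard deviation (n-1 denominator) and a symmetric interval
#' `mean +/- z(level) * sd / sqrt(n)`.  The z multiplier (1.959964 at 95%)
#' rather than a Student t quantile is used because with cohort sizes in
#' the thousands the two are indistinguishable and the z form is the
#' convention in large-sample cost reporting.
#'
#' Either pass a raw `values` vector, or the summary statistics `mean`,
#' `sd`, `n` directly (useful for checking published tables).
#'
#' @param values Numeric vector of per-patient values (costs), or `NULL`.
#' @param level Confidence level (default 0.95).
#' @param mean,sd,n Summary statistics, used when `values` is `NULL`.
#' @return Object of class `group_summary`: list with `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `level`.
#' @examples
#' group_summary(mean = 94.62, sd = 72.54, n = 3820)  # CI [92.32, 96.92]
#' @export
group_summary <- function(values = NULL, level = 0.95,
                          mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(values)) {
    n <- length(values)
    if (n < 2) stop_input("group_summary needs n >= 2")
    mean <- base::mean(values)
    sd <- stats::sd(values)
  } else {
    if (is.null(mean) || is.null(sd) || is.null(n))
      stop_input("provide either values or all of mean, sd, n")
    if (n < 2) stop_input("group_summary needs n >= 2")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sd / sqrt(n)
  structure(
    list(n = as.integer(n), mean = mean, sd = sd,
         ci_low = mean - half, ci_high = mean + half, level = level),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.2f (SD %.2f; %g%% CI %.2f-%.2f)\n",
              x$n, round_cents(x$mean), round_cents(x$sd), 100 * x$level,
              round_cents(x$ci_low), round_cents(x$ci_high)))
  invisible(x)
}

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "acu_test_result")
}

#' @export
print.acu_test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", format(x$df)),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two samples, suited to
#' right-skewed cost distributions.  U is the number of pairs where the
#' first sample exceeds the second, counting ties as 1/2; the p-value uses
#' the normal approximation with midrank tie correction and continuity
#' correction (appropriate at the cohort sizes this package targets).
#'
#' @param a,b Numeric vectors (non-empty).
#' @return An `acu_test_result` with the U statistic for sample `a`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop_input("both samples must be non-empty")
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  new_test_result(wt$statistic, NA_real_, wt$p.value,
                  "Mann-Whitney U (normal approximation, tie-corrected)")
}

#' Two-sample t test on raw values
#'
#' Two-tailed t test for a mean difference; Welch's unequal-variance form
#' by default, pooled-variance form via `var_equal = TRUE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance (Student) form.
#' @return An `acu_test_result`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop_input("each sample needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
                  if (var_equal) "Two-sample t (pooled)" else "Welch two-sample t")
}

#' Two-sample t test from summary statistics
#'
#' Same test as [welch_t()] but computed from published `(mean, sd, n)`
#' triples, so printed group tables can be checked without raw data.
#'
#' @param mean1,sd1,n1 First group summary statistics.
#' @param mean2,sd2,n2 Second group summary statistics.
#' @param var_equal Use the pooled-variance form.
#' @return An `acu_test_result`.
#' @export
welch_t_stats <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stop_input("each sample needs n >= 2")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t (pooled, summary statistics)"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t (summary statistics)"
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_test_result(t, df, p, method)
}

#' Pearson chi-square test on a contingency table
#'
#' @param table Two-dimensional matrix/table of counts with at least two
#'   rows and two columns; all expected counts must be positive.
#' @return An `acu_test_result` with `df = (r-1)(c-1)` (no continuity
#'   correction).
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_input("contingency table needs at least 2 rows and 2 columns (df would be 0)")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0))
    stop_input("zero expected count; merge sparse categories before testing")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result(ct$statistic, ct$parameter, ct$p.value,
                  "Pearson chi-square")
}

#' Per-patient cumulative costs at checkpoint days
#'
#' Cumulative cost reached by each patient at each checkpoint day (e.g.
#' 30/90/180), the quantities compared between groups with [welch_t()].
#'
#' @param cm A `cohort_cost_matrix`.
#' @param checkpoints Integer vector of days within the window
#'   (default `c(30, 90, 180)`).
#' @return Long data.frame with columns `patient_id`, `day`, `cum_cost`.
#' @export
interval_costs <- function(cm, checkpoints = c(30L, 90L, 180L)) {
  stopifnot(inherits(cm, "cohort_cost_matrix"))
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 1) || any(checkpoints > cm$window_days))
    stop_input("checkpoints must lie within 1..window_days")
  cum <- cumulative_curve(cm)
  out <- do.call(rbind, lapply(checkpoints, function(d) {
    data.frame(patient_id = cm$patient_id, day = d,
               cum_cost = unname(cum[, d]), row.names = NULL)
  }))
  out
}

#' Group comparison report for a costed cohort
#'
#' Convenience wrapper producing the standard two-group comparison: CCPD
#' and TCPP summaries per group, the Mann-Whitney test on TCPP, and Welch
#' t tests on cumulative costs at the checkpoint days.
#'
#' @param cm A `cohort_cost_matrix`.
#' @param acu_flag Logical/0-1 vector aligned with `cm$patient_id`; TRUE =
#'   patient had at least one acute care use (ACU) event.
#' @param checkpoints Checkpoint days for the t tests.
#' @param level Confidence level for group summaries.
#' @return List with `summaries` (data.frame, one row per group x measure)
#'   and `tests` (data.frame: method, statistic, df, p_value, day).
#' @export
compare_groups <- function(cm, acu_flag, checkpoints = c(30L, 90L, 180L),
                           level = 0.95) {
  stopifnot(inherits(cm, "cohort_cost_matrix"))
  acu_flag <- as.logical(acu_flag)
  if (length(acu_flag) != length(cm$patient_id))
    stop_input("acu_flag must align with the cohort (one value per patient)")

  tot <- tcpp(cm)
  day <- ccpd(cm)
  groups <- list(acu = acu_flag, non_acu = !acu_flag)
  summaries <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    do.call(rbind, lapply(c(tcpp = "tcpp", ccpd = "ccpd"), function(meas) {
      v <- if (meas == "tcpp") tot[sel] else day[sel]
      s <- group_summary(v, level = level)
      data.frame(group = g, measure = meas, n = s$n,
                 mean = round_cents(s$mean), sd = round_cents(s$sd),
                 ci_low = round_cents(s$ci_low), ci_high = round_cents(s$ci_high),
                 row.names = NULL)
    }))
  }))

  mw <- mann_whitney(tot[acu_flag], tot[!acu_flag])
  ic <- interval_costs(cm, checkpoints)
  tests <- rbind(
    data.frame(method = mw$method, statistic = mw$statistic, df = NA_real_,
               p_value = mw$p_value, day = NA_integer_),
    do.call(rbind, lapply(checkpoints, function(d) {
      v <- ic$cum_cost[ic$day == d]
      f <- acu_flag[match(ic$patient_id[ic$day == d], cm$patient_id)]
      tt <- welch_t(v[f], v[!f])
      data.frame(method = tt$method, statistic = tt$statistic, df = tt$df,
                 p_value = tt$p_value, day = d)
    }))
  )
  row.names(tests) <- NULL
  list(summaries = summaries, tests = tests)
}
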