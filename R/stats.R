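#' Percent difference between control and case means
#'
#' The study's effect statistic: the difference between control and case
#' group means expressed as a percent of the lung-cancer (case) mean,
#' `100 * (mean_control - mean_case) / mean_case`. Positive values mean
#' decreased activity in cancer.
#'
#' @param case_values Numeric vector for the lung-cancer group.
#' @param control_values Numeric vector for the non-cancer group.
#' @return Percent difference.
#' @examples
#' percent_difference(rep(100, 5), rep(109.5, 5))  # 9.5
#' @export
percent_difference <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  mc <- mean(case_values)
  if (mc <= 0)
    stop("undefined denominator: lung-cancer mean must be positive", call. = FALSE)
  100 * (mean(control_values) - mc) / mc
}

#' Per-feature two-sample t tests across the panel
#'
#' Runs a two-sample Student's t test (pooled variance by default; set
#' `welch = TRUE` for Welch's correction) for every sensor-by-timepoint
#' feature, lung cancer versus non-cancer, with two-sided p-values. No
#' multiple-testing correction is applied by default, mirroring the raw
#' `p <= 0.01` reporting convention; `adjust = "BH"` switches on
#' Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param welch Use Welch's t instead of the pooled-variance Student's t.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per feature: `feature`, `mean_case`,
#'   `mean_control`, `percent_difference` (`NA` with a warning when the case
#'   mean is zero), `t_statistic`, `p_value` (and `p_adjusted` if requested).
#' @seealso [fraction_significant()]
#' @export
timepoint_tests <- function(features, welch = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  fcols <- feature_columns(features)
  case <- features$label == "LC"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("each class needs >= 2 observations", call. = FALSE)
  rows <- lapply(fcols, function(f) {
    x <- features[[f]][case]
    y <- features[[f]][!case]
    tt <- t.test(y, x, var.equal = !welch)
    pd <- if (mean(x) > 0) percent_difference(x, y) else NA_real_
    tibble::tibble(feature = f, mean_case = mean(x), mean_control = mean(y),
                   percent_difference = pd,
                   t_statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$percent_difference))
    warning("features with zero case mean excluded from percent difference",
            call. = FALSE)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Fraction of features significant at a threshold
#'
#' @param tests Output of [timepoint_tests()].
#' @param alpha Significance threshold on the raw p-value.
#' @return Fraction of features with `p_value <= alpha`.
#' @export
fraction_significant <- function(tests, alpha = 0.01) {
  mean(tests$p_value <= alpha)
}

#' Two-sample Hotelling's T-squared test
#'
#' Multivariate generalisation of the two-sample t test. With pooled
#' covariance `S` and mean difference `d`,
#' `T^2 = n1 * n2 / (n1 + n2) * d' S^-1 d`, converted to
#' `F = T^2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)` on
#' `(p, n1 + n2 - p - 1)` degrees of freedom; the p-value is the upper
#' F tail. For `p = 1` the F statistic equals the squared pooled t.
#'
#' @param x_case,x_control Numeric matrices (rows = observations, columns =
#'   features) for the two groups.
#' @return A `hotelling_test` list: `t2`, `f_statistic`, `df1`, `df2`,
#'   `p_value`, `n1`, `n2`.
#' @export
hotelling_t2 <- function(x_case, x_control) {
  x1 <- as.matrix(x_case); x2 <- as.matrix(x_control)
  p <- ncol(x1)
  if (ncol(x2) != p) stop("groups must share the same features", call. = FALSE)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 + n2 - 2 < p)
    stop("too few observations: need n1 + n2 - 2 >= p", call. = FALSE)
  d <- colMeans(x1) - colMeans(x2)
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; reduce the feature set", call. = FALSE))
  t2 <- as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% Sinv %*% d)
  df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  structure(list(t2 = t2, f_statistic = f, df1 = p, df2 = df2,
                 p_value = pf(f, p, df2, lower.tail = FALSE),
                 n1 = n1, n2 = n2),
            class = "hotelling_test")
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from Beta-distribution quantiles:
#' lower `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,trials Non-negative integer counts, `successes <= trials`.
#' @param level Confidence level (default 0.95).
#' @return A list: `successes`, `trials`, `level`, `estimate`, `lower`,
#'   `upper`.
#' @examples
#' clopper_pearson(63, 70)
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials and trials >= 1", call. = FALSE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1, trials - successes)
  list(successes = as.integer(successes), trials = as.integer(trials),
       level = level, estimate = successes / trials,
       lower = lower, upper = upper)
}

#' Classification metrics with exact confidence intervals
#'
#' Sensitivity, specificity, NPV, PPV and accuracy from the confusion table,
#' each with a Clopper-Pearson interval on its own denominator. A metric
#' with an empty denominator (e.g. PPV with no positive calls) is reported
#' as `NA`, not 0.
#'
#' @param truth,calls Logical vectors (`TRUE` = positive / lung cancer).
#' @param level Confidence level.
#' @return A tibble: `metric`, `estimate`, `lower`, `upper`, `successes`,
#'   `trials`.
#' @export
classification_metrics <- function(truth, calls, level = 0.95) {
  stopifnot(is.logical(truth), is.logical(calls), length(truth) == length(calls))
  if (!any(truth) || all(truth))
    stop("both classes must be present in `truth`", call. = FALSE)
  tp <- sum(truth & calls); fn <- sum(truth & !calls)
  tn <- sum(!truth & !calls); fp <- sum(!truth & calls)
  one <- function(metric, x, n) {
    if (n == 0)
      return(tibble::tibble(metric = metric, estimate = NA_real_,
                            lower = NA_real_, upper = NA_real_,
                            successes = NA_integer_, trials = 0L))
    ci <- clopper_pearson(x, n, level)
    tibble::tibble(metric = metric, estimate = ci$estimate,
                   lower = ci$lower, upper = ci$upper,
                   successes = ci$successes, trials = ci$trials)
  }
  dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("npv", tn, tn + fn),
    one("ppv", tp, tp + fp),
    one("accuracy", tp + tn, length(truth))
  )
}

#' Assay precision from triplicate classifications
#'
#' Precision is the percent of triplicate donors whose three repeated
#' classifier calls agree fully. (A per-call concordance variant --- the
#' fraction of calls matching the donor's majority call --- is available via
#' `method = "per_call"`; the full-concordance definition is the default.)
#'
#' @param donor_id Donor identifier per call.
#' @param calls Logical classifier calls, three per donor.
#' @param method `"concordance"` (default) or `"per_call"`.
#' @return Precision in percent.
#' @export
precision_from_replicates <- function(donor_id, calls,
                                      method = c("concordance", "per_call")) {
  method <- match.arg(method)
  stopifnot(length(donor_id) == length(calls), is.logical(calls))
  grp <- split(calls, donor_id)
  sizes <- lengths(grp)
  if (any(sizes != 3))
    stop(sprintf("each donor needs exactly 3 calls (found sizes: %s)",
                 paste(unique(sizes), collapse = ", ")), call. = FALSE)
  if (method == "concordance") {
    100 * mean(vapply(grp, function(g) length(unique(g)) == 1, logical(1)))
  } else {
    100 * mean(vapply(grp, function(g) mean(g == (sum(g) >= 2)), numeric(1)))
  }
}
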