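test_that("percent difference follows its definition and sign convention", {
  expect_equal(percent_difference(c(5, 5), c(5, 5)), 0)
  expect_equal(percent_difference(rep(100, 4), rep(109.5, 4)), 9.5)
  expect_equal(percent_difference(rep(100, 4), rep(105.4, 4)), 5.4)
  ## Not antisymmetric: swapping groups changes the denominator.
  expect_equal(percent_difference(rep(109.5, 4), rep(100, 4)),
               100 * (100 - 109.5) / 109.5)
  expect_error(percent_difference(c(0, 0), c(1, 2)), "denominator")
  expect_error(percent_difference(numeric(0), 1), "non-empty")
})

test_that("per-feature t tests match the closed-form pooled computation", {
  x <- c(12.1, 9.8, 11.4, 10.2, 10.9)   # case
  y <- c(13.0, 12.2, 14.1, 12.8, 13.5)  # control
  feats <- tibble::tibble(assay_id = sprintf("a%d", 1:10),
                          donor_id = sprintf("D%d", 1:10),
                          label = rep(c("LC", "non-LC"), each = 5),
                          BM01_10 = c(x, y))
  out <- timepoint_tests(feats)
  ## Oracle: textbook pooled-variance t.
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_manual <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_manual <- 2 * pt(-abs(t_manual), df = 8)
  expect_equal(out$t_statistic, t_manual, tolerance = 1e-10)
  expect_equal(out$p_value, p_manual, tolerance = 1e-10)
  expect_equal(out$percent_difference, percent_difference(x, y))
  ## Identical group values give t = 0, p = 1.
  feats$BM01_10 <- rep(c(1, 2, 3, 4, 5), 2)
  out0 <- timepoint_tests(feats)
  expect_equal(out0$t_statistic, 0)
  expect_equal(out0$p_value, 1)
  ## Welch variant diverges under variance heterogeneity.
  feats$BM01_10 <- c(x * 10, y)
  expect_false(isTRUE(all.equal(timepoint_tests(feats)$p_value,
                                timepoint_tests(feats, welch = TRUE)$p_value)))
})

test_that("t-test p-values are uniform under the null", {
  ## 48 null feature matrices x 108 features, 300/150 split.
  set.seed(314)
  pvals <- unlist(lapply(1:48, function(i) {
    m <- matrix(rnorm(450 * 108), 450)
    colnames(m) <- paste0(rep(sprintf("BM%02d", 1:18), each = 6), "_",
                          rep(seq(10, 60, 10), 18))
    feats <- dplyr::bind_cols(
      tibble::tibble(assay_id = sprintf("a%d", 1:450),
                     donor_id = sprintf("D%d", 1:450),
                     label = rep(c("LC", "non-LC"), c(150, 300))),
      tibble::as_tibble(m))
    suppressWarnings(timepoint_tests(feats)$p_value)
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  ## Fraction significant at 0.01 is about 1%.
  expect_lt(abs(mean(pvals <= 0.01) - 0.01), 0.006)
})

test_that("Hotelling's T2 reduces to the squared pooled t in one dimension", {
  set.seed(5)
  x <- matrix(rnorm(12, 1), ncol = 1)
  y <- matrix(rnorm(15), ncol = 1)
  ht <- hotelling_t2(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(ht$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Hotelling's T2 matches a brute-force matrix oracle on 2 features", {
  x <- matrix(c(4.1, 5.0, 3.8, 4.4, 4.9, 4.6,
                2.0, 2.6, 1.7, 2.2, 2.8, 2.3), ncol = 2)
  y <- matrix(c(5.2, 5.9, 4.8, 5.5, 6.1, 5.0,
                1.4, 2.1, 1.2, 1.8, 2.4, 1.6), ncol = 2)
  ht <- hotelling_t2(x, y)
  ## Oracle: explicit sums of squares and the analytic 2x2 inverse.
  n <- 6
  d <- colMeans(x) - colMeans(y)
  ssq <- function(m) {
    c_ <- sweep(m, 2, colMeans(m))
    t(c_) %*% c_
  }
  S <- (ssq(x) + ssq(y)) / (2 * n - 2)
  det2 <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) / det2
  t2_manual <- (n * n / (2 * n)) * drop(t(d) %*% Sinv %*% d)
  expect_equal(ht$t2, t2_manual, tolerance = 1e-10)
  expect_equal(ht$df1, 2)
  expect_equal(ht$df2, 2 * n - 3)
  ## Equal mean vectors: mirror the data so means match exactly.
  x2 <- rbind(x, sweep(-sweep(x, 2, colMeans(x)), 2, colMeans(x), "+"))
  y2 <- sweep(sweep(y, 2, colMeans(y)), 2, colMeans(x2), "+")
  ht0 <- hotelling_t2(x2, y2)
  expect_equal(ht0$t2, 0, tolerance = 1e-10)
  expect_equal(ht0$p_value, 1)
})

test_that("Hotelling's T2 is invariant under common affine rescaling", {
  set.seed(6)
  x <- matrix(rnorm(60, 1), ncol = 4)
  y <- matrix(rnorm(80), ncol = 4)
  h1 <- hotelling_t2(x, y)
  h2 <- hotelling_t2(37.2 * x - 11, 37.2 * y - 11)
  expect_equal(h1$t2, h2$t2, tolerance = 1e-8)
  expect_error(hotelling_t2(x[1:3, ], y[1:2, ]), "too few|singular")
})

test_that("Clopper-Pearson intervals match closed forms and cover", {
  ci0 <- clopper_pearson(0, 10)
  expect_equal(ci0$lower, 0)
  expect_equal(ci0$upper, 1 - 0.025^(1 / 10), tolerance = 1e-10)
  cin <- clopper_pearson(10, 10)
  expect_equal(cin$upper, 1)
  ## Oracle: invert the Beta CDF numerically, independent of qbeta.
  ci <- clopper_pearson(63, 70)
  lo <- uniroot(function(q) pbeta(q, 63, 8) - 0.025, c(0, 1), tol = 1e-12)$root
  hi <- uniroot(function(q) pbeta(q, 64, 7) - 0.975, c(0, 1), tol = 1e-12)$root
  expect_equal(ci$lower, lo, tolerance = 1e-6)
  expect_equal(ci$upper, hi, tolerance = 1e-6)
  expect_true(ci$lower <= 63 / 70 && 63 / 70 <= ci$upper)
  expect_error(clopper_pearson(5, 3), "successes")
})

test_that("classification metrics come from the confusion table with CIs", {
  truth <- rep(c(TRUE, FALSE), c(6, 14))
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$estimate, rep(1, 5))
  ## All-positive calls: sensitivity 1, specificity 0, PPV = prevalence.
  allpos <- classification_metrics(truth, rep(TRUE, 20))
  expect_equal(allpos$estimate[allpos$metric == "sensitivity"], 1)
  expect_equal(allpos$estimate[allpos$metric == "specificity"], 0)
  expect_equal(allpos$estimate[allpos$metric == "ppv"], 6 / 20)
  expect_true(is.na(allpos$estimate[allpos$metric == "npv"]))  # undefined, not 0
  ## Fixed 20-record example: tp=4, fn=2, fp=3, tn=11 by direct counting.
  calls <- c(rep(TRUE, 4), rep(FALSE, 2), rep(TRUE, 3), rep(FALSE, 11))
  m <- classification_metrics(truth, calls)
  est <- function(k) m$estimate[m$metric == k]
  expect_equal(est("sensitivity"), 4 / 6)
  expect_equal(est("specificity"), 11 / 14)
  expect_equal(est("npv"), 11 / 13)
  expect_equal(est("ppv"), 4 / 7)
  expect_equal(est("accuracy"), 15 / 20)
})

test_that("Clopper-Pearson coverage is at least nominal at n=70, p=0.9", {
  set.seed(77)
  draws <- rbinom(10000, 70, 0.9)
  cis <- vapply(0:70, function(x) {
    ci <- clopper_pearson(x, 70)
    c(ci$lower, ci$upper)
  }, numeric(2))
  covered <- cis[1, draws + 1] <= 0.9 & 0.9 <= cis[2, draws + 1]
  expect_gte(mean(covered), 0.95)
})

test_that("triplicate precision counts fully concordant donors", {
  ids <- rep(sprintf("D%02d", 1:50), each = 3)
  expect_equal(precision_from_replicates(ids, rep(TRUE, 150)), 100)
  ## 45 of 50 concordant.
  calls <- rep(TRUE, 150)
  calls[(0:4) * 3 + 1] <- FALSE
  expect_equal(precision_from_replicates(ids, calls), 90)
  ## Per-call variant: discordant donors have 2/3 agreement with majority.
  expect_equal(precision_from_replicates(ids, calls, method = "per_call"),
               100 * (45 + 5 * 2 / 3) / 50)
  expect_error(precision_from_replicates(ids[-1], calls[-1]), "exactly 3")
  ## Random coin flips concord with probability 2 * 0.5^3 = 25%.
  set.seed(8)
  est <- mean(vapply(1:40, function(i)
    precision_from_replicates(ids, sample(c(TRUE, FALSE), 150, TRUE)),
    numeric(1)))
  expect_lt(abs(est - 25), 4)
})
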