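test_that("identical groups compare as indistinguishable", {
  x <- c(1.2, 3.4, 2.2, 4.1, 2.8, 3.3, 1.9, 2.4)
  g <- compare_groups(x, x)
  expect_equal(g$mean_difference, 0)
  if (g$test_used == "mann_whitney") expect_equal(g$p_value, 1)
  else expect_equal(g$p_value, 1, tolerance = 1e-9)
})

test_that("the normality gate routes to t or Mann-Whitney as the KS decision says", {
  set.seed(73)
  a <- stats::rnorm(100, 1, 1)
  b <- stats::rnorm(100, 0, 1)
  g <- compare_groups(a, b)
  # oracle: the same gate decision computed directly
  both_normal <- nortest::lillie.test(a)$p.value > 0.05 &&
    nortest::lillie.test(b)$p.value > 0.05
  expect_true(both_normal)
  expect_identical(g$test_used, "t")
  expect_lt(g$p_value, 0.001)
  expect_true(g$ci95[1] < g$mean_difference && g$mean_difference < g$ci95[2])

  heavy <- stats::rcauchy(120)
  expect_lt(nortest::lillie.test(heavy)$p.value, 0.05)
  g2 <- compare_groups(a, heavy)
  expect_identical(g2$test_used, "mann_whitney")
  # pooled-vs-Welch and plain-KS options stay available
  g3 <- compare_groups(a, b, var_equal = FALSE, normality = "ks")
  expect_identical(g3$test_used, "t")
  expect_error(compare_groups(a[1:2], b), "at least 3")
})

test_that("sensitivity/specificity follow the confusion-matrix arithmetic", {
  perfect <- sens_spec(c(1, 2, 10, 40), c(0, 2, 20, 50), cutoff = 8)
  expect_identical(perfect$sensitivity, 100)
  expect_identical(perfect$specificity, 100)
  # constant predictor below the cutoff
  low <- sens_spec(rep(0, 10), c(rep(20, 6), rep(0, 4)), cutoff = 8)
  expect_identical(low$sensitivity, 0)
  expect_identical(low$specificity, 100)
  # 14 diseased / 13 test-positive, 6 healthy / 2 test-positive
  pred <- c(rep(10, 13), 0, rep(10, 2), rep(0, 4))
  true <- c(rep(30, 14), rep(0, 6))
  got <- sens_spec(pred, true, cutoff = 8)
  expect_equal(got$sensitivity, 100 * 13 / 14, tolerance = 1e-9)
  expect_equal(got$specificity, 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(round(got$sensitivity, 1), 92.9)
  expect_equal(round(got$specificity, 1), 66.7)
  # one-class cohorts flag the undefined rate instead of NaN
  allpos <- sens_spec(c(10, 10), c(20, 30), cutoff = 8)
  expect_identical(allpos$undefined, "specificity")
  expect_true(is.na(allpos$specificity))
})

test_that("extreme cutoffs hit the ROC corners", {
  pred <- stats::runif(50, 0, 60)
  true <- stats::runif(50, 0, 60)
  lo <- sens_spec(pred, true, cutoff = -Inf)
  expect_identical(c(lo$sensitivity, lo$specificity), c(100, 0))
  hi <- sens_spec(pred, true, cutoff = Inf)
  expect_identical(c(hi$sensitivity, hi$specificity), c(0, 100))
})

test_that("AUC equals the normalized Mann-Whitney U statistic, ties included", {
  expect_identical(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(79)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    scores <- sample(1:8, n, replace = TRUE)      # heavy ties
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), auc_rank_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  # permutation null: AUC near 0.5
  scores <- stats::rnorm(2000)
  labels <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.03)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("Bland-Altman bias and limits follow their definitions", {
  a <- c(1, 2, 3, 4)
  expect_identical(bland_altman(a, a)$bias, 0)
  expect_identical(bland_altman(a, a)$loa_low, 0)
  shifted <- bland_altman(a + 5, a)
  expect_identical(shifted$bias, 5)
  expect_identical(c(shifted$loa_low, shifted$loa_high), c(5, 5))
  set.seed(83)
  x <- stats::rnorm(10000, 0, 10)
  ba <- bland_altman(x, rep(0, 10000))
  coverage <- mean(x >= ba$loa_low & x <= ba$loa_high)
  expect_lt(abs(coverage - 0.95), 0.01)
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("Pearson correlation matches its closed-form extremes and band", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(89)
  z <- stats::rnorm(500)
  y <- 0.7 * z + sqrt(1 - 0.49) * stats::rnorm(500)
  r <- pearson_r(z, y)
  expect_gt(r$r, 0.64)
  expect_lt(r$r, 0.76)
  expect_lt(r$p, 1e-10)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("design power reproduces the two-sample closed form", {
  p <- power_two_sample(0.15, 0.2, 25, 75, 0.05)
  expect_gte(p, 0.90)
  # direct normal-approximation arithmetic
  se <- 0.2 * sqrt(1 / 25 + 1 / 75)
  direct <- stats::pnorm(0.15 / se - stats::qnorm(0.975)) +
    stats::pnorm(-0.15 / se - stats::qnorm(0.975))
  expect_equal(p, direct, tolerance = 1e-12)
  # null case: power equals the two-sided size
  expect_equal(power_two_sample(0, 0.2, 25, 75, 0.05), 0.05,
               tolerance = 1e-9)
  # monotone in delta, n and decreasing in sd
  expect_gt(power_two_sample(0.3, 0.2, 25, 75), p)
  expect_gt(power_two_sample(0.15, 0.2, 50, 150), p)
  expect_lt(power_two_sample(0.15, 0.4, 25, 75), p)
  # noncentral-t variant close to the normal approximation at this n
  expect_equal(power_two_sample(0.15, 0.2, 25, 75, method = "t"), p,
               tolerance = 0.01)
  expect_error(power_two_sample(0.15, 0.2, 25, 75, alpha = 1.5), "alpha")
})

test_that("Cohen's kappa matches direct formula arithmetic", {
  expect_identical(cohen_kappa(diag(c(10, 20, 5))), 1)
  # independent marginals: outer-product matrix has kappa 0
  m <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohen_kappa(m), 0, tolerance = 1e-12)
  expect_equal(cohen_kappa(matrix(c(55, 5, 10, 30), 2, byrow = TRUE)),
               0.680851, tolerance = 1e-6)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
})
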