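test_that("Student t reproduces printed group summaries and handles raw vectors", {
  # anthropometric weight row: pooled t from printed summaries
  res <- student_t(c(n = 17, mean = 70.76, sd = 16.01),
                   c(n = 17, mean = 68.59, sd = 15.89))
  expect_equal(res$p_two_sided, 0.694, tolerance = 0.002)
  expect_equal(res$df, 32)

  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  ours <- student_t(a, b)
  base_t <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$statistic, unname(base_t$statistic), tolerance = 1e-12)
  expect_equal(ours$p_two_sided, base_t$p.value, tolerance = 1e-12)
  w <- student_t(a, b, welch = TRUE)
  expect_equal(w$p_two_sided, stats::t.test(a, b)$p.value, tolerance = 1e-12)

  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  expect_lt(student_t(a, a + 10 * sd(a))$p_two_sided, 1e-6)
  expect_error(student_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("paired t matches the hand-computed example and errors on zero variance", {
  res <- paired_t(c(0, 0, 0), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_two_sided, 0.0742, tolerance = 1e-3)
  x <- c(4, 2, 9)
  expect_error(paired_t(x, x), "zero variance of paired differences")
  # symmetric in direction: swapping arms flips the estimate, not the p
  set.seed(6); a <- rnorm(15); b <- a + rnorm(15, 0.4)
  expect_equal(paired_t(a, b)$p_two_sided, paired_t(b, a)$p_two_sided)
  expect_equal(paired_t(a, b)$estimate, -paired_t(b, a)$estimate)
})

test_that("paired-t type-I error is nominal and power detects programmed shifts", {
  set.seed(2024)
  null_rej <- mean(vapply(1:600, function(i) {
    x0 <- rnorm(17); x1 <- x0 + rnorm(17)
    paired_t(x0, x1)$p_two_sided < 0.05
  }, logical(1)))
  expect_gt(null_rej, 0.028)
  expect_lt(null_rej, 0.075)

  shift_rej <- mean(vapply(1:200, function(i) {
    x0 <- rnorm(17, 0, 1500); x1 <- x0 + rnorm(17, 2000, 1500)
    paired_t(x0, x1)$p_two_sided < 0.05
  }, logical(1)))
  expect_gt(shift_rej, 0.99)
})

test_that("Lilliefors-corrected KS is calibrated and detects non-normality", {
  # statistic identical to the reference implementation
  set.seed(1); x <- rnorm(80)
  expect_equal(ks_normality(x, reps = 500, seed = 2)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)

  ps_null <- vapply(1:200, function(s) {
    set.seed(s); ks_normality(rnorm(100), reps = 2000, seed = 99)$p_two_sided
  }, numeric(1))
  # nominal non-rejection rate 0.95; band = +/- 4 binomial SE over 200 draws
  expect_gt(mean(ps_null > 0.05), 0.95 - 4 * sqrt(0.95 * 0.05 / 200))
  expect_lt(mean(ps_null > 0.05), 1)

  ps_exp <- vapply(1:100, function(s) {
    set.seed(s); ks_normality(rexp(100), reps = 2000, seed = 99)$p_two_sided
  }, numeric(1))
  expect_gt(mean(ps_exp < 0.05), 0.90)

  expect_error(ks_normality(c(1, 2, 3, 4)), "n >= 5")
  expect_error(ks_normality(rep(2, 10)), "constant sample")
})

test_that("ANCOVA separates covariate and group signals", {
  set.seed(8)
  n <- 200
  grp <- rep(c("MAD", "MMA"), each = n / 2)
  age <- rnorm(n, 40, 10)
  res_age <- ancova_group_age(2 * age + rnorm(n), grp, age)
  expect_lt(res_age$p_age, 0.001)
  expect_gt(res_age$p_group, 0.05)

  res_grp <- ancova_group_age(ifelse(grp == "MAD", 0, 3) + rnorm(n), grp, age)
  expect_lt(res_grp$p_group, 0.001)
  expect_gt(res_grp$p_age, 0.05)

  expect_error(ancova_group_age(rnorm(10), rep(c("a", "b"), 5), rep(1, 10)),
               "age is constant")
  expect_error(ancova_group_age(rnorm(9), rep(c("a", "b", "c"), 3), rnorm(9)),
               "two groups")
})

test_that("ANCOVA null p-values are uniform", {
  set.seed(99)
  ps <- t(vapply(1:300, function(i) {
    grp <- rep(c("A", "B"), each = 50)
    age <- rnorm(100, 40, 10)
    res <- ancova_group_age(rnorm(100), grp, age)
    c(res$p_age, res$p_group)
  }, numeric(2)))
  expect_gt(stats::ks.test(ps[, 1], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(ps[, 2], "punif")$p.value, 0.01)
})

test_that("Pearson correlation matches its t transform and edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, x)$estimate, 1)
  set.seed(10)
  y <- -x + rnorm(5, sd = 0.1)
  expect_lt(pearson_correlation(x, y)$estimate, -0.9)
  a <- rnorm(17); b <- rnorm(17)
  res <- pearson_correlation(a, b)
  r <- cor(a, b)
  expect_equal(res$statistic, r * sqrt(15 / (1 - r^2)), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("chi-square reproduces the printed sex distribution and is transpose-invariant", {
  res <- chi_square_2x2(matrix(c(9, 8, 7, 10), 2, 2, byrow = TRUE))
  expect_equal(res$p_two_sided, 0.492, tolerance = 5e-4)
  expect_equal(res$statistic, 0.472, tolerance = 5e-3)
  expect_equal(res$df, 1)

  even <- chi_square_2x2(matrix(5, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_two_sided, 1)
  expect_lt(chi_square_2x2(diag(c(20, 20)) + 0)$p_two_sided, 1e-6)

  m <- matrix(c(12, 5, 3, 14), 2, 2)
  expect_equal(chi_square_2x2(t(m))$statistic, chi_square_2x2(m)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), "margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("paired sample size follows the noncentral-t oracle and monotonicity", {
  # study effect: total-volume change 1261.6 +/- 1476.2, alpha .05, power .90
  n_study <- sample_size_paired_t(1261.6, 1476.2)
  expect_gte(as.integer(n_study), 16)
  # independent oracle: stats::power.t.test solves the same noncentral-t power
  oracle <- ceiling(stats::power.t.test(delta = 1261.6 / 1476.2, sd = 1,
                                        power = 0.90, type = "paired")$n)
  expect_identical(as.integer(n_study), as.integer(oracle))

  expect_identical(as.integer(sample_size_paired_t(0.5, 1, power = 0.80)),
                   as.integer(ceiling(stats::power.t.test(delta = 0.5, power = 0.80,
                                                          type = "paired")$n)))
  expect_lte(as.integer(sample_size_paired_t(10, 1)), 3)

  # non-increasing in effect size, non-decreasing in power
  ns <- vapply(c(0.3, 0.5, 0.8, 1.2), function(d)
    as.integer(sample_size_paired_t(d, 1)), integer(1))
  expect_true(all(diff(ns) <= 0))
  np <- vapply(c(0.5, 0.8, 0.9, 0.99), function(p)
    as.integer(sample_size_paired_t(0.5, 1, power = p)), integer(1))
  expect_true(all(diff(np) >= 0))
  expect_gte(attr(sample_size_paired_t(0.5, 1), "power"), 0.90)
})

test_that("treatment success applies the AHI reduction rule", {
  expect_identical(classify_treatment_success(40, 9), "success")      # AHI < 10
  expect_identical(classify_treatment_success(40, 20), "success")     # 50% cut
  expect_identical(classify_treatment_success(30, 22), "partial/failure")
  expect_identical(classify_treatment_success(c(40, 30), c(9, 22)),
                   c("success", "partial/failure"))
  expect_error(classify_treatment_success(-1, 5), "nonnegative")
})

test_that("test objects tidy into one-row tibbles", {
  td <- tidy(student_t(c(1, 2, 3, 4), c(2, 3, 4, 6)))
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_true(all(c("statistic", "p.value", "estimate") %in% names(td)))
})
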