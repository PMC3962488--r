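test_that("difference-of-means interval behaves at its edges and flags the known exception", {
  same <- diff_mean_interval(group_stats(10, 2, 5), group_stats(10, 2, 5))
  expect_equal(same$center, 0)
  expect_equal(same$lower, -same$upper)
  expect_false(same$excludes_zero)
  expect_error(diff_mean_interval(group_stats(1, 0, 1), group_stats(2, 1, 3)),
               "n >= 2")
  degenerate <- diff_mean_interval(group_stats(5, 0, 3), group_stats(5, 0, 3))
  expect_equal(c(degenerate$lower, degenerate$upper), c(0, 0))

  # the one significant transfer-time comparison: X2 class, vials 0.1 vs 0.3
  iv <- diff_mean_interval(group_stats(0.218, 0.015, 3),
                           group_stats(0.161, 0.016, 3), level = 0.975)
  expect_true(iv$excludes_zero)
  expect_equal(iv$center, 0.057)
  # recompute the half-width with an independent quantile evaluation
  se <- sqrt(0.015^2 / 3 + 0.016^2 / 3)
  df <- se^4 / ((0.015^2 / 3)^2 / 2 + (0.016^2 / 3)^2 / 2)
  expect_equal(iv$upper - iv$center, qt(0.9875, df) * se, tolerance = 1e-12)
  expect_equal(se, 0.0127, tolerance = 0.01)
})

test_that("the interval converges to the normal-quantile interval for large n", {
  n <- 1e6
  iv <- diff_mean_interval(group_stats(0.3, 1, n), group_stats(0.1, 1.5, n),
                           level = 0.975)
  se <- sqrt((1 + 1.5^2) / n)
  expect_equal(iv$upper, 0.2 + qnorm(0.9875) * se, tolerance = 1e-3)
  expect_equal(iv$lower, 0.2 - qnorm(0.9875) * se, tolerance = 1e-3)
})

test_that("subset scan flags exactly the one printed comparison", {
  scan <- pairwise_subset_scan(xyy_fixture("table3"), level = 0.975)
  expect_equal(nrow(scan$results), 72)
  expect_equal(scan$n_significant, 1)
  sig <- scan$significant
  expect_equal(sig$y1, "ROMA")
  expect_equal(sig$y2, "10B")
  expect_equal(sig$class, "X2")
  expect_setequal(c(sig$subset_a, sig$subset_b), c("0.1", "0.3"))
})

test_that("subset scan responds to constructed fixtures", {
  flat <- expand.grid(y1 = "A", y2 = "B", subset = c("1", "2", "3", "0.1", "0.2", "0.3"),
                      class = gamete_classes, stringsAsFactors = FALSE)
  flat$n <- 3; flat$mean <- 0.2; flat$sd <- 0.05
  expect_equal(pairwise_subset_scan(flat)$n_significant, 0)

  apart <- flat
  move <- apart$class == "X" & apart$subset == "1"
  # shift one cell by ten pooled SDs
  apart$mean[move] <- 0.2 + 10 * sqrt(2) * 0.05
  scan <- pairwise_subset_scan(apart)
  expect_equal(scan$n_significant, 2)  # vial 1 differs from both 2 and 3
  expect_true(all(scan$significant$class == "X"))
  expect_true(all(scan$significant$subset_a == "1"))

  expect_error(pairwise_subset_scan(flat[flat$subset != "2", ]), "missing cell")
})

test_that("frequency regression matches closed-form least squares", {
  exact <- frequency_regression(c(1, 2, 3, 4), c(3, 5, 7, 9))  # y = 2x + 1
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- frequency_regression(c(1, 2, 3), c(4, 4, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(61)
  for (i in 1:10) {
    x <- runif(8, 40, 110); y <- runif(8, 5, 25)
    fit <- frequency_regression(x, y)
    # normal equations, written out independently of lm
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
  expect_error(frequency_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(frequency_regression(c(1, 2), c(1, 2)), "three")
})

test_that("required sample size reproduces the power analysis and is monotone", {
  n_X1 <- required_sample_size(group_stats(17.8, 6.8, 32),
                               group_stats(16.0, 5.6, 25))
  expect_lt(abs(n_X1 / 90 - 1), 0.05)
  n_2 <- required_sample_size(group_stats(22.4, 8.8, 32),
                              group_stats(24.2, 6.1, 25))
  expect_lt(abs(n_2 / 139 - 1), 0.05)

  # a ten-pooled-SD separation needs a single vial
  expect_equal(required_sample_size(group_stats(10, 1, 3),
                                    group_stats(10 + 10 * sqrt(2), 1, 3)), 1L)
  expect_error(required_sample_size(group_stats(5, 1, 3),
                                    group_stats(5, 2, 3)), "equal")

  base <- required_sample_size(group_stats(10, 3, 3), group_stats(12, 3, 3))
  wider <- required_sample_size(group_stats(10, 4, 3), group_stats(12, 3, 3))
  farther <- required_sample_size(group_stats(10, 3, 3), group_stats(14, 3, 3))
  expect_gt(wider, base)
  expect_lt(farther, base)
})

test_that("null behavior of the 97.5% interval: matches Welch t.test, conservative at n=3, calibrated for larger vials", {
  # decision-for-decision agreement with the Welch two-sample t as
  # implemented independently in stats::t.test
  set.seed(72)
  for (i in 1:500) {
    a <- rnorm(3); b <- rnorm(3, sd = runif(1, 0.5, 2))
    mine <- diff_mean_interval(group_stats(mean(a), sd(a), 3),
                               group_stats(mean(b), sd(b), 3), level = 0.975)
    oracle <- t.test(a, b, conf.level = 0.975)
    expect_equal(unname(c(mine$lower, mine$upper)),
                 unname(as.numeric(oracle$conf.int)), tolerance = 1e-10)
    expect_equal(mine$excludes_zero, oracle$p.value < 0.025)
  }

  # the Welch-Satterthwaite df is data-estimated, which makes the interval
  # conservative for three-vial groups (null exclusion below the nominal
  # 2.5%) and asymptotically calibrated as vials accumulate
  set.seed(71)
  null_rate <- function(n, n_pairs) {
    mean(vapply(seq_len(n_pairs), function(i) {
      a <- rnorm(n); b <- rnorm(n)
      diff_mean_interval(group_stats(mean(a), sd(a), n),
                         group_stats(mean(b), sd(b), n),
                         level = 0.975)$excludes_zero
    }, logical(1)))
  }
  se <- sqrt(0.025 * 0.975 / 4000)
  expect_lt(null_rate(3, 4000), 0.025 + 3 * se)
  expect_lt(abs(null_rate(30, 4000) - 0.025), 3 * se)
})
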