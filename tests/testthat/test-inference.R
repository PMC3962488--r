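test_that("cross summaries reproduce the printed control-cross statistics", {
  t1 <- xyy_fixture("table1")
  expected <- list(B = c(53.4, 0.5), ROMA = c(48.3, 0.2),
                   `10B` = c(50.1, 0.6), `473` = c(50.0, 0.8))
  for (i in seq_len(nrow(t1))) {
    s <- summarize_cross(t1[i, -1])
    ex <- expected[[t1$y_chromosome[i]]]
    expect_equal(round(s$percent_female, 1), ex[1])
    expect_equal(round(s$percent_aneuploid, 1), ex[2])
  }
})

test_that("pooled frequencies come from summed counts, not averaged ratios", {
  tab <- data.frame(`X` = c(10, 100), `12` = c(10, 0), X1 = c(10, 0),
                    `2` = c(10, 0), X2 = c(10, 0), `1` = c(10, 0),
                    check.names = FALSE)
  s <- summarize_cross(tab)
  expect_equal(unname(s$pooled_pct[["X"]]), 100 * 110 / 160)
  expect_false(isTRUE(all.equal(s$pooled_pct, s$vial_mean_pct)))
  # single vial: pooled equals the vial mean and the SD is flagged undefined
  one <- summarize_cross(tab[1, ])
  expect_equal(one$pooled_pct, one$vial_mean_pct)
  expect_false(one$sd_defined)
  expect_true(all(is.na(one$vial_sd_pct)))
  expect_error(summarize_cross(tab[0, ]), "empty")
  expect_error(summarize_cross(data.frame(A = 1, B = 2)), "class columns")
})

test_that("moments estimator inverts the pairing model", {
  u <- estimate_mixture_moments(rep(1/6, 6))
  expect_equal(unclass(u$point), c(L = 1/3, M = 1/3, N = 1/3),
               tolerance = 1e-12)
  expect_true(u$assumes_unit_viability)

  # round-trip identity on the simplex interior
  set.seed(41)
  for (i in 1:50) {
    m <- random_mixture()
    est <- estimate_mixture_moments(zygote_distribution(pairing_mixture(m)))
    expect_equal(as.numeric(est$point), m, tolerance = 1e-12)
    expect_false(est$projected)
  }

  # pooled B/10B frequencies from the scored crosses
  f <- c(15.8, 8.4, 16.8, 23.4, 16.5, 19.1) / 100
  est <- estimate_mixture_moments(f / sum(f))
  expect_equal(as.numeric(round(est$point, 3)), c(0.196, 0.288, 0.516))

  expect_error(estimate_mixture_moments(rep(0.2, 6)), "sum to 1")
  # an out-of-model frequency vector is projected and flagged
  skew <- c(0.49, 0.49, 0.005, 0.005, 0.005, 0.005)
  proj <- estimate_mixture_moments(skew)
  expect_true(proj$projected)
  expect_equal(sum(proj$point), 1)
  expect_true(all(proj$point >= 0))
})

test_that("moments estimate matches an independent least-squares solve", {
  # design matrix of the linear model f = A %*% p (unit viability)
  A <- cbind(L = gamete_distribution("L"), M = gamete_distribution("M"),
             N = gamete_distribution("N"))
  set.seed(43)
  for (i in 1:20) {
    f <- zygote_distribution(pairing_mixture(random_mixture()))
    ls <- qr.solve(A, as.numeric(f))
    est <- estimate_mixture_moments(f)
    expect_equal(as.numeric(est$point), unname(ls), tolerance = 1e-10)
  }
})

test_that("vial bootstrap gives calibrated, reproducible intervals", {
  m <- pairing_mixture(0.2, 0.3, 0.5)
  tab <- simulate_xyy_vials(m, design = vial_design(50, 150, 30), seed = 3)
  e1 <- estimate_mixture_bootstrap(tab, n_boot = 300, seed = 5)
  e2 <- estimate_mixture_bootstrap(tab, n_boot = 300, seed = 5)
  expect_identical(e1$interval, e2$interval)
  expect_true(all(e1$interval[, "lower"] <= as.numeric(e1$point) + 1e-12))
  expect_true(all(e1$interval[, "upper"] >= as.numeric(e1$point) - 1e-12))

  # degenerate table: every vial identical at exact model frequencies
  z <- zygote_distribution(m)
  exact <- as.data.frame(t(replicate(5, round(z * 1000))))
  names(exact) <- gamete_classes
  deg <- estimate_mixture_bootstrap(exact, n_boot = 200, seed = 1)
  expect_equal(unname(deg$interval[, "upper"] - deg$interval[, "lower"]),
               rep(0, 3), tolerance = 1e-12)

  expect_error(estimate_mixture_bootstrap(tab[1, ], seed = 1), "two vials")
  expect_warning(estimate_mixture_bootstrap(tab, n_boot = 50, seed = 1),
                 "100")
})

test_that("bootstrap intervals cover the true mixture at roughly the nominal rate", {
  m <- pairing_mixture(0.2, 0.3, 0.5)
  hits <- matrix(0, 60, 3)
  for (r in seq_len(nrow(hits))) {
    tab <- simulate_xyy_vials(m, design = vial_design(50, 150, 0),
                              seed = 1000 + r)
    e <- estimate_mixture_bootstrap(tab, n_boot = 200, level = 0.95,
                                    seed = 2000 + r)
    hits[r, ] <- e$interval[, "lower"] <= m & m <= e$interval[, "upper"]
  }
  cover <- colMeans(hits)
  se <- sqrt(0.95 * 0.05 / nrow(hits))
  expect_true(all(cover > 0.95 - 4 * se))
})

test_that("nondisjunction rate reproduces the printed percentages", {
  r <- nondisjunction_rate(5, 8220)
  expect_equal(round(r$rate_pct, 2), 0.06)
  expect_lt(r$lower_pct, r$rate_pct)
  expect_gt(r$upper_pct, r$rate_pct)

  z <- nondisjunction_rate(0, 1000)
  expect_equal(z$rate_pct, 0)
  expect_equal(z$lower_pct, 0)
  expect_gt(z$upper_pct, 0)

  expect_equal(round(nondisjunction_rate(19, 4191)$rate_pct, 1), 0.5)
  t1 <- xyy_fixture("table1")
  from_tab <- nondisjunction_rate(t1[1, -1])
  expect_equal(from_tab$exceptional, 19)
  expect_equal(from_tab$total, 4191)
  expect_error(nondisjunction_rate(0, 0), "positive")
})

test_that("complementary classes co-vary only when the mixture itself varies", {
  set.seed(51)
  m <- c(0.4, 0.3, 0.3)
  med_varying <- apply(replicate(25, complementary_covariance(
    simulate_mixture_varying_vials(m, kappa = 10, n_vials = 40,
                                   vial_size = 300))), 1, median)
  expect_true(all(med_varying > 0))

  # fixed probabilities: multinomial covariance -p_i p_j / n makes the
  # correlations mildly negative
  med_fixed <- apply(replicate(25, complementary_covariance(
    simulate_xyy_vials(pairing_mixture(m),
                       design = vial_design(40, 300, 0),
                       seed = sample.int(1e6, 1)))), 1, median)
  expect_true(all(med_fixed < 0.15))
  expect_lt(mean(med_fixed), 0)

  const <- data.frame(`X` = rep(10, 4), `12` = 10, X1 = 10, `2` = 10,
                      X2 = 10, `1` = 10, check.names = FALSE)
  cc <- complementary_covariance(const)
  expect_true(all(is.na(cc)))
  expect_equal(attr(cc, "undefined"), c("X:12", "X1:2", "X2:1"))
  expect_error(complementary_covariance(const[1:2, ]), "three vials")
})

test_that("differential viability biases the moments estimator detectably", {
  # subviable XYY males (class 12 at 0.6) break the unit-viability
  # assumption; the estimator must drift from the truth while declaring
  # that assumption
  m <- c(1/3, 1/3, 1/3)
  v <- viability_vector(c(X = 1, `12` = 0.6, X1 = 1, `2` = 1, X2 = 1, `1` = 1))
  z <- zygote_distribution(pairing_mixture(m), v)
  est <- estimate_mixture_moments(z)
  expect_true(est$assumes_unit_viability)
  expect_gt(max(abs(as.numeric(est$point) - m)), 0.02)
})
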