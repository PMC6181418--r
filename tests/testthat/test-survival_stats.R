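test_that("KM estimate matches hand product-limit calculations", {
  # all events: survival is 1 - ECDF
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))

  # censoring reduces the risk set without a step
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(0, 1, 2, 3))
  expect_equal(km2$survival, c(1, 2 / 3, 2 / 3, 0))

  # all censored: flat at 1
  km3 <- km_estimate(c(4, 8, 15), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
})

test_that("KM curve is a valid survival function with consistent counts", {
  withr::local_seed(3)
  d <- random_surv_data(40)
  km <- km_estimate(d$time, d$event)
  expect_equal(km$survival[1], 1)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  # risk set shrinks by events + censorings between rows
  for (i in 2:(nrow(km) - 1)) {
    expect_equal(km$n_risk[i + 1],
                 km$n_risk[i] - km$n_event[i] - km$n_censor[i])
  }
})

test_that("KM equals 1 - ECDF at every time under no censoring", {
  withr::local_seed(8)
  times <- sample(1:15, 30, replace = TRUE)
  km <- km_estimate(times, rep(1, 30))
  ecdf_fn <- ecdf(times)
  expect_equal(km$survival[-1], 1 - ecdf_fn(km$time[-1]))
})

test_that("km_estimate rejects bad input", {
  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "positive")
})

test_that("log-rank matches the brute-force hypergeometric oracle", {
  # 8-patient toy set with a tied event time across groups
  time <- c(3, 5, 5, 7, 2, 5, 9, 11)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  group <- c(0, 0, 0, 0, 1, 1, 1, 1)
  res <- logrank_test(time, event, group)
  expect_equal(res$chi_square, oracle_logrank2(time, event, group == 1),
               tolerance = 1e-10)
  expect_equal(sum(res$observed), sum(res$expected), tolerance = 1e-8)
})

test_that("identical groups give chi-square 0 and two-group relabeling is safe", {
  time <- c(2, 4, 6, 8)
  event <- c(1, 1, 0, 1)
  res <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("A", "B"), each = 4))
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  withr::local_seed(19)
  d <- random_surv_data(20)
  r1 <- logrank_test(d$time, d$event, d$group)
  r2 <- logrank_test(d$time, d$event, 1 - d$group)
  expect_equal(r1$chi_square, r2$chi_square, tolerance = 1e-10)
  expect_identical(r1$df, r2$df)
})

test_that("k groups give df = k - 1; degenerate inputs error", {
  withr::local_seed(23)
  time <- sample(1:20, 50, replace = TRUE)
  event <- rbinom(50, 1, 0.7)
  groups <- sample(letters[1:5], 50, replace = TRUE)
  expect_equal(logrank_test(time, event, groups)$df, 4)
  expect_error(logrank_test(time, event, rep("a", 50)), "two groups")
  expect_error(logrank_test(time, rep(0, 50), groups), "at least one event")
})

test_that("trend log-rank reduces to the two-group test and detects order", {
  withr::local_seed(29)
  d <- random_surv_data(30)
  two <- logrank_test(d$time, d$event, d$group)
  trend <- logrank_trend(d$time, d$event, d$group)
  expect_equal(trend$chi_square, two$chi_square, tolerance = 1e-10)
  expect_equal(trend$df, 1)

  # identical groups -> statistic 0
  t0 <- logrank_trend(rep(c(2, 4, 6), 3), rep(c(1, 1, 0), 3),
                      rep(0:2, each = 3))
  expect_equal(t0$chi_square, 0, tolerance = 1e-12)

  # hazard monotone in grade: trend chi exceeds heterogeneity chi / df
  cohort <- generate_cohort(sim_config(seed = 101, n_patients = 500))
  scored <- score_cohort(cohort, c(cd3_ct = 490, cd3_im = 290,
                                   cd8_ct = 116, cd8_im = 70))
  tr <- logrank_trend(scored$os_months, scored$os_event, scored$immunoscore)
  het <- logrank_test(scored$os_months, scored$os_event, scored$immunoscore)
  expect_gt(tr$chi_square, het$chi_square / het$df)
})

test_that("Cox log-HR matches brute-force partial-likelihood maximization", {
  withr::local_seed(37)
  # n = 10, binary covariate, continuous times (no ties)
  x <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  time <- round(rexp(10, ifelse(x == 1, 0.3, 0.1)), 3)
  time <- time + seq(0.001, 0.01, length.out = 10)  # break accidental ties
  event <- rep(1, 10)
  fit <- cox_fit(data.frame(x = x), time, event)
  expect_equal(fit$table$log_hr, oracle_cox1(x, time, event),
               tolerance = 1e-4)
})

test_that("Cox output is internally consistent and unit-invariant", {
  cohort <- generate_cohort(sim_config(seed = 51, n_patients = 300))
  scored <- score_cohort(cohort, c(cd3_ct = 490, cd3_im = 290,
                                   cd8_ct = 116, cd8_im = 70))
  covs <- data.frame(cd8_high = as.integer(scored$call_cd8_im == "high"),
                     lvi = scored$lvi)
  fit <- cox_fit(covs, scored$os_months, scored$os_event)
  expect_true(fit$converged)
  expect_equal(fit$table$hr, exp(fit$table$log_hr))
  expect_equal(fit$table$ci_lower,
               exp(fit$table$log_hr - qnorm(0.975) * fit$table$se))
  expect_true(all(fit$table$hr > 0))

  # months -> years leaves the hazard ratios unchanged
  fit_y <- cox_fit(covs, scored$os_months / 12, scored$os_event)
  expect_equal(fit$table$log_hr, fit_y$table$log_hr, tolerance = 1e-8)
})

test_that("Cox rejects constant covariates and flags separation", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  expect_error(cox_fit(data.frame(flat = rep(1, 6)), time, event),
               "'flat' is constant")
  # perfectly separating covariate -> flagged, not silent
  sep <- data.frame(x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- cox_fit(sep, time, event), "flagged")
  expect_false(fit$converged)
})

test_that("duplicating patients with opposite covariates shrinks the effect", {
  cohort <- generate_cohort(sim_config(seed = 61, n_patients = 100))
  x <- as.integer(cohort$cd8_im > 70)
  fit1 <- cox_fit(data.frame(x = x), cohort$os_months, cohort$os_event)
  fit2 <- cox_fit(data.frame(x = c(x, 1 - x)),
                  rep(cohort$os_months, 2), rep(cohort$os_event, 2))
  expect_lt(abs(fit2$table$log_hr), abs(fit1$table$log_hr))
})

test_that("rank-sum comparison matches exact enumeration and handles ties", {
  res <- compare_density_groups(c(1, 2, 3, 10, 20, 30),
                                rep(c("a", "b"), each = 3))
  # exact enumeration: 20 equally likely assignments, the observed complete
  # separation is one of 2 extreme tables -> two-sided p = 2/20
  expect_equal(res$p_value, 0.1)

  same <- compare_density_groups(rep(c(5, 6, 7), 2),
                                 rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)

  expect_error(compare_density_groups(1:3, rep("a", 3)), "two levels")
})

test_that("rank-sum detects a one-log-unit density shift at n = 30/30", {
  withr::local_seed(71)
  hits <- 0
  for (b in 1:500) {
    resp <- rlnorm(30, meanlog = 5.25, sdlog = 0.9)
    nonresp <- rlnorm(30, meanlog = 4.25, sdlog = 0.9)
    p <- compare_density_groups(c(resp, nonresp),
                                rep(c("r", "n"), each = 30))$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.8)
})
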