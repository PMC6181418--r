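test_that("candidate cutoffs respect the minimum group size", {
  expect_equal(candidate_cutoffs(1:10, 0.2), 2:8)       # k = 2
  expect_equal(candidate_cutoffs(c(1, 2, 3, 4), 0.5), 2) # only the 2/2 split
  expect_error(candidate_cutoffs(rep(5, 10), 0.1), "distinct")
  expect_error(candidate_cutoffs(c(1, 2), 0.5) -> x, NA)
  expect_equal(x, 1)
  # min_group_frac outside (0, 0.5] rejected
  expect_error(candidate_cutoffs(1:10, 0), "min_group_frac")
  expect_error(candidate_cutoffs(1:10, 0.6), "min_group_frac")
})

test_that("scan chi-squares match the brute-force log-rank oracle", {
  # n = 12 toy cohort with tied event times and tied densities
  dens <- c(5, 10, 10, 20, 30, 35, 40, 40, 55, 60, 80, 90)
  time <- c(2, 4, 4, 6, 3, 8, 8, 12, 14, 14, 20, 24)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1)
  scan <- scan_cutpoints(dens, time, event, min_group_frac = 0.2)
  for (i in seq_len(nrow(scan))) {
    expect_equal(scan$chi_square[i],
                 oracle_logrank2(time, event, dens > scan$cutoff[i]),
                 tolerance = 1e-10)
  }
  expect_equal(scan$n_low + scan$n_high, rep(12, nrow(scan)))
})

test_that("scan also agrees with survdiff at every candidate", {
  withr::local_seed(31)
  d <- random_surv_data(25)
  dens <- runif(25, 0, 100)
  scan <- scan_cutpoints(dens, d$time, d$event, min_group_frac = 0.15)
  for (i in seq_len(nrow(scan))) {
    sd_chi <- survival::survdiff(
      survival::Surv(d$time, d$event) ~ I(dens > scan$cutoff[i]))$chisq
    expect_equal(scan$chi_square[i], unname(sd_chi), tolerance = 1e-8)
  }
})

test_that("identical survival on both sides of every split gives chi ~ 0", {
  # duplicated cohort halves: same times/events regardless of density
  time <- rep(c(3, 5, 8, 11, 15, 20), 2)
  event <- rep(c(1, 1, 0, 1, 1, 0), 2)
  dens <- c(rep(10, 6), rep(100, 6))
  scan <- scan_cutpoints(dens, time, event, min_group_frac = 0.5)
  expect_true(all(scan$chi_square < 1e-10))
})

test_that("optimize_cutpoint returns the oracle argmax and honors ties", {
  withr::local_seed(13)
  for (rep in 1:10) {
    n <- sample(15:30, 1)
    d <- random_surv_data(n)
    dens <- round(runif(n, 0, 50))       # rounded -> density ties
    if (length(unique(dens)) < 2) next
    res <- optimize_cutpoint(dens, d$time, d$event, min_group_frac = 0.15,
                             correction = "none")
    orc <- oracle_best_cutpoint(dens, d$time, d$event, 0.15)
    expect_equal(res$cutoff, orc$cutoff)
    expect_equal(res$chi_square, orc$chi, tolerance = 1e-10)
    expect_equal(res$n_candidates, length(orc$candidates))
  }
})

test_that("single-candidate scans return that candidate unchanged", {
  dens <- c(1, 2, 3, 4)
  time <- c(5, 7, 3, 9)
  event <- c(1, 1, 1, 0)
  res <- optimize_cutpoint(dens, time, event, min_group_frac = 0.5,
                           correction = "none")
  expect_equal(res$cutoff, 2)
  expect_equal(res$n_candidates, 1L)
  expect_equal(res$corrected_p, res$raw_p)
})

test_that("the Miller-Siegmund correction matches an independent oracle", {
  # frozen values from an independent numerical implementation of the
  # normal-tail formula (scipy): ms(0.001, 0.1, 0.9), ms(0.01, 0.1, 0.9)
  expect_equal(miller_siegmund_correct(0.001, 0.1, 0.9),
               0.025485226351106238, tolerance = 1e-12)
  expect_equal(miller_siegmund_correct(0.01, 0.1, 0.9),
               0.16146061519190402, tolerance = 1e-12)
})

test_that("the Miller-Siegmund correction is monotone and clamped", {
  expect_lt(miller_siegmund_correct(0.001, 0.1, 0.9),
            miller_siegmund_correct(0.01, 0.1, 0.9))
  expect_equal(miller_siegmund_correct(1 - 1e-12, 0.1, 0.9), 1)
  expect_equal(miller_siegmund_correct(1, 0.1, 0.9), 1)
  expect_error(miller_siegmund_correct(0, 0.1, 0.9), "> 0")
  # clamp keeps corrected >= raw even where the approximation dips
  p <- 0.4
  expect_gte(miller_siegmund_correct(p, 0.1, 0.9), p)
})

test_that("permutation correction is seeded, floored and reproducible", {
  withr::local_seed(17)
  cohort <- generate_cohort(sim_config(seed = 23, n_patients = 60))
  p1 <- permutation_correct(cohort$cd8_im, cohort$os_months,
                            cohort$os_event, n_perm = 199, seed = 99)
  p2 <- permutation_correct(cohort$cd8_im, cohort$os_months,
                            cohort$os_event, n_perm = 199, seed = 99)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_lte(p1, 1)
  expect_error(permutation_correct(cohort$cd8_im, cohort$os_months,
                                   cohort$os_event, n_perm = 50),
               "n_perm")
})

test_that("corrected p-values never fall below the raw minimum p", {
  cohort <- generate_null_cohort(sim_config(seed = 77, n_patients = 200))
  res_ms <- optimize_cutpoint(cohort$cd8_im, cohort$os_months,
                              cohort$os_event,
                              correction = "miller_siegmund")
  expect_gt(res_ms$corrected_p, res_ms$raw_p)
  expect_gt(res_ms$n_candidates, 1L)
  res_perm <- optimize_cutpoint(cohort$cd8_im, cohort$os_months,
                                cohort$os_event, correction = "permutation",
                                n_perm = 199, seed = 5)
  expect_gt(res_perm$corrected_p, res_perm$raw_p)
  # reproducible for fixed input and seed
  res_perm2 <- optimize_cutpoint(cohort$cd8_im, cohort$os_months,
                                 cohort$os_event,
                                 correction = "permutation",
                                 n_perm = 199, seed = 5)
  expect_identical(res_perm$corrected_p, res_perm2$corrected_p)
})

test_that("missing densities are excluded from the scan only", {
  withr::local_seed(41)
  d <- random_surv_data(30)
  dens <- runif(30, 0, 100)
  dens[c(3, 11)] <- NA
  scan <- scan_cutpoints(dens, d$time, d$event, min_group_frac = 0.15)
  expect_equal(unique(scan$n_low + scan$n_high), 28)
})

test_that("scan input errors are informative", {
  expect_error(scan_cutpoints(1:5, 1:4, rep(1, 4)), "equal length")
  expect_error(scan_cutpoints(1:5, 1:5, rep(0, 5)), "at least one event")
})
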