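test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(seed = 42, n_patients = 67)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_null_cohort(cfg), generate_null_cohort(cfg))
  expect_false(identical(generate_cohort(sim_config(seed = 43)),
                         generate_cohort(cfg)))
})

test_that("cohort contract: row count, positive densities, DFS <= OS", {
  cohort <- generate_cohort(sim_config(seed = 1, n_patients = 67))
  expect_identical(nrow(cohort), 67L)
  for (comp in c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")) {
    expect_true(all(cohort[[comp]] > 0))
  }
  expect_true(all(cohort$dfs_months <= cohort$os_months))
  expect_true(all(cohort$os_event %in% 0:1))
  expect_true(all(cohort$dfs_event %in% 0:1))
  expect_true(all(is.na(cohort$nac_response) | cohort$chemo == 1))
})

test_that("covariate prevalences and density marginals match the config", {
  cfg <- sim_config(seed = 7, n_patients = 10000)
  cohort <- generate_cohort(cfg)
  expect_lt(abs(mean(cohort$lvi) - 0.701), 0.02)
  # per-compartment log-density mean and SD within 3 standard errors
  for (comp in c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")) {
    x <- log(cohort[[comp]])
    mu <- cfg$density_meanlog[[comp]]
    sg <- cfg$density_sdlog[[comp]]
    expect_lt(abs(mean(x) - mu), 3 * sg / sqrt(10000))
    expect_lt(abs(sd(x) - sg), 3 * sg / sqrt(2 * 9999))
  }
})

test_that("null cohorts decouple density from survival", {
  cohort <- generate_null_cohort(sim_config(seed = 9, n_patients = 10000))
  r <- cor(log(cohort$cd8_im), log(cohort$os_months))
  expect_lt(abs(r), 0.05)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_patients = 0), ">= 20")
  expect_error(sim_config(n_patients = 10), ">= 20")
  bad_cor <- matrix(c(1, 0.99, 0.99, 0.99,
                      0.99, 1, -0.99, 0.99,
                      0.99, -0.99, 1, 0.99,
                      0.99, 0.99, 0.99, 1), 4, 4)
  expect_error(sim_config(density_cor = bad_cor), "positive-definite")
  expect_error(sim_config(censor_horizon = 0), "censor_horizon")
  expect_error(sim_config(covariate_prevalence = c(organ_confined = 1.2,
                                                   lvi = 0.7, margin = 0.1,
                                                   intravesical = 0.26,
                                                   chemo = 0.4)),
               "\\[0, 1\\]")
})

test_that("expression generator honors counts, membership and determinism", {
  cfg <- expression_sim_config(seed = 3)
  sim <- generate_expression(cfg)
  expect_identical(ncol(sim$expression), 189L)   # 121 luminal + 68 basal
  expect_identical(length(sim$gene_set), 113L)
  expect_true(all(sim$gene_set %in% rownames(sim$expression)))
  expect_identical(sim, generate_expression(cfg))
  expect_error(expression_sim_config(n_genes = 200,
                                     n_cytotoxicity_genes = 300),
               "n_genes")
})

test_that("expression effect size is recovered and the null is flat", {
  sim <- generate_expression(expression_sim_config(seed = 5, n_genes = 300,
                                                   effect_size = 2,
                                                   noise_sd = 1))
  basal <- sim$labels$subtype == "basal"
  diffs <- rowMeans(sim$expression[sim$gene_set, basal]) -
    rowMeans(sim$expression[sim$gene_set, !basal])
  expect_lt(abs(mean(diffs) - 2), 0.2)

  null_sim <- generate_expression(expression_sim_config(seed = 6,
                                                        n_genes = 300,
                                                        effect_size = 0))
  basal <- null_sim$labels$subtype == "basal"
  null_diffs <- rowMeans(null_sim$expression[, basal]) -
    rowMeans(null_sim$expression[, !basal])
  # members indistinguishable from non-members under the null
  member <- rownames(null_sim$expression) %in% null_sim$gene_set
  expect_gt(t.test(null_diffs[member], null_diffs[!member])$p.value, 0.01)
})

test_that("cohort round-trips through CSV and config through JSON", {
  cfg <- sim_config(seed = 21, n_patients = 30, missing_frac = 0.1)
  cohort <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$cd8_im, cohort$cd8_im, tolerance = 1e-12)
  expect_identical(back$os_event, cohort$os_event)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, jpath)
  cfg2 <- read_sim_config(jpath)
  expect_equal(cfg2[names(cfg2) != "density_cor"],
               cfg[names(cfg) != "density_cor"], tolerance = 1e-12)
  expect_equal(generate_cohort(cfg2), generate_cohort(cfg),
               tolerance = 1e-10)
})
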