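test_that("configurations are schema-validated and round-trip through YAML", {
  cfg <- run_config(seed = 9, n = 500,
                    mcmc = list(chains = 2, burnin = 100, draws = 100))
  expect_s3_class(cfg, "run_config")
  expect_error(run_config(nonsense = 1), "unknown configuration key")
  expect_error(run_config(mcmc = list(walkers = 7)), "unknown mcmc key")
  expect_error(run_config(priors = list(tau = 2)), "unknown priors key")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("the end-to-end recovery study is reproducible and carries all stage outputs", {
  cfg <- run_config(seed = 33, n = 400, fit_indices = TRUE,
                    mcmc = list(chains = 2, burnin = 150, draws = 150))
  b1 <- suppressWarnings(run_recovery_study(cfg))
  expect_true(is.finite(b1$convergence$max_psr))
  expect_true(is.finite(b1$convergence$min_ess))
  expect_s3_class(b1$recovery$table, "data.frame")
  expect_equal(nrow(b1$recovery$table), 26)  # every free parameter reported
  expect_true(all(c("BRMSEA", "BCFI", "BTLI", "BGammaHat", "BMc")
                  %in% rownames(b1$fit_indices$indices)))
  expect_true(nzchar(b1$config_hash))

  b2 <- suppressWarnings(run_recovery_study(cfg))
  expect_identical(colMeans(bstarts:::flat_draws(b1$fit)),
                   colMeans(bstarts:::flat_draws(b2$fit)))

  out <- withr::local_tempdir()
  cfg3 <- run_config(seed = 33, n = 400, fit_indices = FALSE, out_dir = out,
                     mcmc = list(chains = 2, burnin = 150, draws = 150))
  suppressWarnings(run_recovery_study(cfg3))
  expect_true(file.exists(file.path(out, "bundle.json")))
  expect_true(file.exists(file.path(out, "recovery.csv")))
})

test_that("rendered tables follow the grouped structural layout", {
  cfg <- run_config(seed = 34, n = 400, fit_indices = FALSE,
                    mcmc = list(chains = 2, burnin = 150, draws = 150))
  b <- suppressWarnings(run_recovery_study(cfg))
  tab <- render_tables(b)
  expect_true("Completely stable trait correlation" %in% tab$block)
  expect_true("Autoregressive trait disturbance correlations" %in% tab$block)
  cor_rows <- tab$block %in% c("Completely stable trait correlation",
                               "State correlations",
                               "Autoregressive traits correlation at wave 1",
                               "Autoregressive trait disturbance correlations")
  expect_true(all(abs(tab$standardized[cor_rows]) <= 1))
  expect_warning(render_tables(list(summary = NULL)), "header only")

  tf <- withr::local_tempfile(fileext = ".csv")
  export_traces(b$fit, tf)
  tr <- utils::read.csv(tf)
  expect_equal(nrow(tr), 2 * 150)
  expect_true(all(c("chain", "iteration", "autoreg_EM") %in% names(tr)))
})
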