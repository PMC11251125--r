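test_that("the backed-out generating set is valid with time-consistent trait variances", {
  o <- backout_params()
  expect_identical(validate_starts_params(o), character(0))
  expect_s3_class(o, "generating_oracle")
  expect_true(all(nzchar(attr(o, "provenance"))))

  # per-wave stable-trait variances from loadings x scaled wave variances:
  # near-constant across waves, which is the internal-consistency check of
  # the time-invariant trait
  cstw <- attr(o, "cst_var_by_wave")
  expect_equal(unname(cstw[, "EM"]), c(0.219, 0.220, 0.215, 0.213),
               tolerance = 0.002)
  cv_em <- stats::sd(cstw[, "EM"]) / mean(cstw[, "EM"])
  expect_lt(cv_em, 0.02)

  # raw/standardized identity for the wave-1 trait covariance:
  # sd(ART_EM1) * sd(ART_CL1) = raw / standardized
  expect_equal(sqrt(o$art1_cov[1, 1] * o$art1_cov[2, 2]), 0.113 / 0.940,
               tolerance = 0.001)
})

test_that("the oracle's standardized solution reproduces the published wave-2 state correlation", {
  std <- starts_standardize(backout_params())
  expect_lt(abs(std$state_cor[2] - (-0.149)), 0.01)
  expect_lt(abs(unname(std$autoreg_std[1, 1]) - 0.775), 0.01)
})

test_that("inconsistent printed inputs are rejected with the offending component named", {
  tabs <- gui_printed_tables()
  bad_load <- tabs[c("lambda_cst", "lambda_art")]
  bad_load$lambda_cst[1, 1] <- 1.2
  expect_error(backout_params(table2_loadings = bad_load), "loadings")
  expect_error(backout_params(table1_sds = -tabs$sds), "SDs")
  # trait loadings so large at wave 2 that the disturbance variance goes
  # negative in the back-out
  bad2 <- tabs[c("lambda_cst", "lambda_art")]
  bad2$lambda_art[2, ] <- c(0.05, 0.05)
  expect_error(backout_params(table2_loadings = bad2), "disturbance")
})

test_that("cohort generation discretizes to instrument ranges and is covariate-invariant at zero effects", {
  o <- backout_params()
  coh <- generate_cohort(o, n = 500, seed = 15, discretize = TRUE)
  em <- as.matrix(coh[, paste0("EM", 1:4)])
  cl <- as.matrix(coh[, paste0("CL", 1:4)])
  expect_true(all(em == round(em) & em >= 0 & em <= 10))
  expect_true(all(cl == round(cl) & cl >= 7 & cl <= 35))

  c0 <- generate_cohort(o, n = 500, seed = 16)
  cz <- generate_cohort(o, n = 500, seed = 16,
                        covariate_effects = matrix(0, 6, 2))
  expect_identical(c0[, 1:8], cz[, 1:8])

  prof <- missingness_profile(prob = c(0, 0.1, 0.45, 0.2), seed = 3)
  ca <- generate_cohort(o, n = 2000, seed = 17, attrition = prof)
  expect_gt(mean(is.na(ca$EM3)), 0.4)
  expect_true(all(!is.na(ca$EM1)))
})
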