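test_that("simulation is bit-for-bit reproducible given a seed", {
  p <- small_params()
  a <- simulate_starts_panel(p, 200, seed = 123)
  b <- simulate_starts_panel(p, 200, seed = 123)
  expect_identical(a$y, b$y)
  c_ <- simulate_starts_panel(p, 200, seed = 124)
  expect_false(identical(a$y, c_$y))
})

test_that("latent bookkeeping is exact: y = CST + ART + state", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 100, seed = 5, return_latents = TRUE)
  lat <- attr(pan, "latents")
  for (t in 1:4) {
    expect_equal(pan$y[, t], lat$cst[, 1] + lat$art[, 1, t] + lat$state[, 1, t])
    expect_equal(pan$y[, 4 + t], lat$cst[, 2] + lat$art[, 2, t] + lat$state[, 2, t])
  }
})

test_that("the noise-free random-intercept limit collapses each construct to CST + ART1", {
  eps <- 1e-12
  p <- starts_params(
    cst_cov = diag(c(0.3, 0.2)),
    art1_cov = diag(c(0.25, 0.15)),
    autoreg = c(1, 1),
    crosslag = matrix(0, 3, 2),
    dist_cov = diag(eps, 2),
    state_var = matrix(eps, 4, 2),
    state_cov = 0
  )
  pan <- simulate_starts_panel(p, 50, seed = 8, return_latents = TRUE)
  lat <- attr(pan, "latents")
  base <- lat$cst[, 1] + lat$art[, 1, 1]
  for (t in 1:4) expect_equal(pan$y[, t], base, tolerance = 1e-4)
})

test_that("sample moments at the cohort size match the scaled printed descriptives", {
  o <- backout_params()
  pan <- simulate_starts_panel(o, 7507, seed = 2)
  # wave-1 EM variance on the scaled metric: (1.42 / 1.8225)^2
  target <- (1.42 / mean(c(1.42, 1.73, 2.06, 2.08)))^2
  se <- target * sqrt(2 / 7507)
  expect_lt(abs(stats::var(pan$y[, "EM1"]) - target), 4 * se)
})

test_that("whole-wave attrition reproduces its nominal rates and never empties a dyad", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 1e4, seed = 31)
  prof0 <- missingness_profile(prob = c(0, 0, 0, 0))
  expect_identical(apply_missingness(pan, prof0)$y, pan$y)

  prof <- missingness_profile(prob = c(0, 0.08, 0.45, 0.18), seed = 4)
  out <- apply_missingness(pan, prof)
  rates <- attr(out, "missingness_rates")
  expect_lt(abs(rates[["wave3"]] - 0.45), 0.02)
  expect_lt(abs(rates[["wave2"]] - 0.08), 0.02)
  expect_true(all(rowSums(out$mask) >= 2))  # wave 1 always retained
  # whole-wave: EM and CL missing together
  expect_identical(is.na(out$y[, "EM3"]), is.na(out$y[, "CL3"]))
})

test_that("attrition tied to wave-1 difficulties is selective where random dropout is not", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 2e4, seed = 32)
  prof <- missingness_profile(prob = c(0, 0, 0.3, 0.3),
                              mechanism = "MAR-on-wave1", mar_coef = 1,
                              seed = 6)
  out <- apply_missingness(pan, prof)
  em1 <- pan$y[, "EM1"]
  hi <- em1 >= stats::quantile(em1, 0.75)
  lo <- em1 <= stats::quantile(em1, 0.25)
  miss3 <- is.na(out$y[, "EM3"])
  expect_gt(mean(miss3[hi]), mean(miss3[lo]))
})

test_that("degenerate attrition profiles are rejected", {
  expect_error(missingness_profile(prob = c(0.2, 0, 0, 0)), "wave 1")
  expect_error(missingness_profile(prob = c(0, 1, 1, 1)), "every follow-up")
  expect_error(missingness_profile(prob = c(0, -0.1, 0, 0)), "\\[0, 1\\]")
})
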