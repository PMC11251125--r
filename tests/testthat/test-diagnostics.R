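# split-chain PSR / ESS implemented directly from the textbook formulas,
# independently of the package's code paths, as the reference oracle
ref_split_rhat <- function(draws_ic) {
  n <- nrow(draws_ic); h <- n %/% 2
  x <- cbind(draws_ic[1:h, ], draws_ic[(n - h + 1):n, ])
  m <- ncol(x); nn <- nrow(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- nn * stats::var(mu)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

test_that("identically distributed chains pass the PSR gate and separated chains fail it loudly", {
  set.seed(1)
  arr <- array(stats::rnorm(3 * 1000 * 2), c(3, 1000, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  rep_ok <- psr_report(arr)
  expect_lt(rep_ok$max_psr, 1.02)
  expect_true(rep_ok$pass_psr)

  sep <- array(c(stats::rnorm(1000), stats::rnorm(1000, 5)), c(2, 1000, 1))
  sep <- aperm(array(c(stats::rnorm(1000), stats::rnorm(1000, mean = 5)),
                     c(1000, 2, 1)), c(2, 1, 3))
  rep_bad <- psr_report(sep)
  expect_gt(rep_bad$max_psr, 2)
  expect_false(rep_bad$pass)
})

test_that("effective sample size approaches the draw count for independent draws", {
  set.seed(2)
  arr <- array(stats::rnorm(3 * 1000), c(3, 1000, 1))
  rep <- psr_report(arr, ess_limit = 300)
  expect_gt(rep$min_ess, 0.8 * 3000)
  expect_lte(rep$min_ess, 3000)
  # strongly autocorrelated chains: ESS collapses
  ar <- array(0, c(3, 1000, 1))
  for (c_ in 1:3) ar[c_, , 1] <- as.numeric(stats::filter(
    stats::rnorm(1000), 0.98, method = "recursive"))
  expect_lt(psr_report(ar)$min_ess, 300)
})

test_that("package estimators match the reference formulas on shared fixtures", {
  set.seed(3)
  arr <- array(stats::rnorm(4 * 600 * 3), c(4, 600, 3))
  rep <- psr_report(arr)
  for (p_ in 1:3)
    expect_equal(unname(rep$psr[p_]), ref_split_rhat(t(arr[, , p_])),
                 tolerance = 1e-6)
})

test_that("posterior summaries collapse for degenerate draws and expose the Jensen gap", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 300, seed = 91)
  fit <- suppressWarnings(fit_starts(
    pan, prior_config(),
    mcmc_config(chains = 2, burnin = 150, draws = 150, seed = 92)))
  s <- summarize_posterior(fit)
  expect_true(all(c("mean", "sd", "ci_lower", "ci_upper", "excludes_zero")
                  %in% names(s$raw)))
  # per-draw standardization then averaging differs from standardizing the
  # posterior mean (nonlinear functional)
  expect_false(isTRUE(all.equal(s$standardized$mean,
                                s$standardized$at_posterior_mean,
                                tolerance = 1e-8)))

  fit0 <- fit
  fit0$draws[] <- rep(bstarts:::flat_draws(fit)[1, ],
                      each = prod(dim(fit$draws)[1:2]))
  s0 <- summarize_posterior(fit0, standardized = FALSE)
  expect_equal(max(s0$raw$sd), 0)
  expect_equal(s0$raw$ci_lower, s0$raw$ci_upper)
})

test_that("recovery reports give zero bias at the posterior mean and reject mismatched truths", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 300, seed = 93)
  fit <- suppressWarnings(fit_starts(
    pan, prior_config(),
    mcmc_config(chains = 2, burnin = 150, draws = 150, seed = 94)))
  truth <- posterior_mean_params(fit)
  rec <- recovery_report(truth, fit)
  expect_lt(max(abs(rec$table$bias)), 1e-10)
  expect_equal(rec$coverage_all, 1)

  p2 <- starts_params(cst_cov = diag(2) * 0.2, art1_cov = diag(2) * 0.2,
                      autoreg = c(0.5, 0.5), crosslag = matrix(0, 2, 2),
                      dist_cov = diag(2) * 0.1,
                      state_var = matrix(0.3, 3, 2), state_cov = 0)
  expect_error(recovery_report(p2, fit))
})
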