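test_that("the prior-sample-size parameterization maps to the intended inverse gamma", {
  pr1 <- make_priors(prior_config(nu_phi = 1, sigma0_sq = 1 / 3))
  expect_equal(attr(pr1, "var_shape"), 0.5)
  expect_equal(attr(pr1, "var_rate"), 1 / 6)
  # prior mode of a variance: rate / (shape + 1)
  expect_equal(attr(pr1, "var_rate") / (attr(pr1, "var_shape") + 1), 1 / 9)
  pr3 <- make_priors(prior_config(nu_phi = 3, sigma0_sq = 1 / 3))
  expect_equal(attr(pr3, "var_shape"), 1.5)
  expect_equal(attr(pr3, "var_rate"), 0.5)
  expect_error(prior_config(nu_phi = 0), "positive")
  expect_error(prior_config(sigma0_sq = -1), "positive")
})

test_that("the coefficient prior is standard normal: log-density drop from 0 to 1 is one half", {
  cfg <- prior_config()
  p0 <- small_params(); p0$autoreg <- c(0, p0$autoreg[2])
  p1 <- small_params(); p1$autoreg <- c(1, p1$autoreg[2])
  f <- make_priors(cfg)
  expect_equal(f(p0) - f(p1), 0.5, tolerance = 1e-12)
})

test_that("prior log-density matches an independent density assembly", {
  cfg <- prior_config()
  f <- make_priors(cfg)
  p <- small_params()
  a <- 0.5; b <- 1 / 6
  digl <- function(x) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  vars <- c(diag(p$cst_cov), diag(p$art1_cov), diag(p$dist_cov),
            as.numeric(p$state_var))
  manual <- sum(digl(vars)) + 3 * log(0.5) + log(0.5) +
    sum(stats::dnorm(c(p$autoreg, as.numeric(p$crosslag)), log = TRUE))
  expect_equal(f(p), manual, tolerance = 1e-12)
})

test_that("prior-only sampling reproduces prior quantiles and moments", {
  fit <- fit_starts(NULL, prior_config(),
                    mcmc_config(chains = 2, burnin = 300, draws = 2500,
                                seed = 17, leapfrog_max = 12),
                    use_likelihood = FALSE)
  x <- bstarts:::flat_draws(fit)
  # coefficients: N(0, 1)
  expect_lt(abs(mean(x[, "autoreg_EM"])), 0.08)
  expect_lt(abs(stats::sd(x[, "crosslag_EMtoCL_2"]) - 1), 0.08)
  # variance components: IG(0.5, 1/6); the mean is infinite, so check the
  # median against the analytic value
  med <- 1 / stats::qgamma(0.5, shape = 0.5, rate = 1 / 6)
  expect_lt(abs(stats::median(x[, "cst_var_EM"]) - med) / med, 0.15)
  expect_lt(abs(stats::median(x[, "state_var_CL_2"]) - med) / med, 0.15)
  # correlations: uniform on (-1, 1)
  r <- x[, "cst_cov"] / sqrt(x[, "cst_var_EM"] * x[, "cst_var_CL"])
  qs <- stats::quantile(r, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qs - c(-0.5, 0, 0.5))), 0.08)
})
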