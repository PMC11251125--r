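test_that("the analytic posterior gradient matches central differences", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 250, seed = 3)
  skel <- bstarts:::make_skeleton(4L)
  post <- bstarts:::make_posterior(pan, skel, prior_config())
  th <- bstarts:::constrained_to_theta(
    bstarts:::params_to_constrained(p, skel), skel)
  set.seed(2)
  th <- th + stats::rnorm(length(th)) * 0.05
  g <- post$lp_grad(th)
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * max(1, abs(th[j]))
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    (post$lp(tp) - post$lp(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g$grad - gn) / (abs(gn) + 1)), 1e-5)
})

test_that("fits are deterministic given identical seeds and flag non-convergence", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 200, seed = 21)
  cfg <- mcmc_config(chains = 2, burnin = 100, draws = 100, seed = 77)
  f1 <- suppressWarnings(fit_starts(pan, prior_config(), cfg))
  f2 <- suppressWarnings(fit_starts(pan, prior_config(), cfg))
  expect_identical(f1$draws, f2$draws)
  # too few draws for the gates: returned flagged, with a warning
  expect_warning(
    f3 <- fit_starts(pan, prior_config(),
                     mcmc_config(chains = 2, burnin = 30, draws = 10,
                                 seed = 5)),
    "convergence gates")
  expect_false(f3$converged)
})

test_that("a conjugate single-variance submodel reproduces its analytic inverse-gamma posterior", {
  eps <- 1e-8
  n <- 150
  set.seed(55)
  y <- matrix(stats::rnorm(n * 8, sd = 0.8), n, 8,
              dimnames = list(NULL, bstarts:::panel_col_names(4)))
  pan <- starts_panel(y)
  fixed <- c(
    cst_var_EM = eps, cst_var_CL = eps, cst_cov = 0,
    art1_var_EM = eps, art1_var_CL = eps, art1_cov = 0,
    autoreg_EM = 0, autoreg_CL = 0,
    crosslag_EMtoCL_1 = 0, crosslag_EMtoCL_2 = 0, crosslag_EMtoCL_3 = 0,
    crosslag_CLtoEM_1 = 0, crosslag_CLtoEM_2 = 0, crosslag_CLtoEM_3 = 0,
    dist_var_EM = eps, dist_var_CL = eps, dist_cov = 0,
    stats::setNames(rep(1, 7), c(paste0("state_var_EM_", 2:4),
                                 paste0("state_var_CL_", 1:4))),
    state_cov = 0
  )
  fit <- suppressWarnings(fit_starts(
    pan, prior_config(),
    mcmc_config(chains = 2, burnin = 300, draws = 4800, seed = 42,
                leapfrog_max = 8),
    fixed = fixed))
  v <- bstarts:::flat_draws(fit)[, "state_var_EM_1"]
  v <- v[seq(1, length(v), by = 2)]    # thin to near-independence
  expect_gte(length(v), 4000)
  a_post <- 0.5 + n / 2
  b_post <- 1 / 6 + sum(y[, 1]^2) / 2
  ks <- stats::ks.test(v, function(q)
    stats::pgamma(1 / q, shape = a_post, rate = b_post, lower.tail = FALSE))
  expect_gt(ks$p.value, 0.01)
})

test_that("reduced-scale recovery keeps generating values inside the credible intervals", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 1500, seed = 61)
  fit <- suppressWarnings(fit_starts(
    pan, prior_config(),
    mcmc_config(chains = 2, burnin = 400, draws = 400, seed = 62)))
  rec <- recovery_report(p, fit)
  expect_gte(rec$coverage_structural, 0.8)
  expect_lt(rec$max_abs_bias_structural, 0.35)
})

test_that("conditional fits recover covariate effects and reduce to the unconditional model", {
  o <- backout_params()
  eff <- gui_printed_tables()$covariate_effects
  coh <- generate_cohort(o, n = 3000, seed = 71, covariate_effects = eff)
  pan <- scale_by_average_sd(coh)
  fit <- suppressWarnings(fit_starts_conditional(
    pan, prior_config(),
    mcmc_config(chains = 2, burnin = 400, draws = 400, seed = 72)))
  s <- summarize_posterior(fit, standardized = FALSE)$raw
  ci <- function(par) unlist(s[s$parameter == par, c("ci_lower", "ci_upper")])
  # strongest published effect recovered within its credible interval
  b <- ci("b_child_ill_EM")
  expect_gt(0.124, b[1]); expect_lt(0.124, b[2])
  # a zero-effect covariate covers zero: income has printed effect 0.000 on CL
  b0 <- ci("b_income_CL")
  expect_gt(0, b0[1]); expect_lt(0, b0[2])

  # nesting: with no covariate effects in truth, structural posteriors of the
  # conditional and unconditional fits agree within Monte-Carlo error
  coh0 <- generate_cohort(o, n = 3000, seed = 73)
  pan0 <- scale_by_average_sd(coh0)
  f_un <- suppressWarnings(fit_starts(
    pan0, prior_config(),
    mcmc_config(chains = 2, burnin = 400, draws = 400, seed = 74)))
  pan0c <- pan0
  f_co <- suppressWarnings(fit_starts_conditional(
    pan0c, prior_config(),
    mcmc_config(chains = 2, burnin = 400, draws = 400, seed = 74)))
  m_un <- colMeans(bstarts:::flat_draws(f_un))
  m_co <- colMeans(bstarts:::flat_draws(f_co))
  shared <- c("cst_var_EM", "cst_var_CL", "cst_cov", "autoreg_EM",
              "autoreg_CL", "dist_var_EM", "dist_var_CL")
  expect_lt(max(abs(m_un[shared] - m_co[shared])), 0.1)

  # dual route: compiled joint likelihood equals the reference path built
  # from the joint implied moments in R
  pm <- posterior_mean_params(f_co)
  pan_std <- pan0
  pan_std$covariates <- scale(pan0$covariates)
  skel_c <- f_co$skeleton
  post_c <- bstarts:::make_posterior(pan_std, skel_c, prior_config())
  th_c <- bstarts:::constrained_to_theta(
    bstarts:::params_to_constrained(pm, skel_c), skel_c)
  mom_j <- bstarts:::starts_implied_moments_joint(pm, attr(pm, "cov_var"))
  ll_r <- bstarts:::loglik_from_moments(mom_j$mean, mom_j$cov,
                                        bstarts:::joint_panel(pan_std))
  expect_equal(post_c$lp(th_c) -
                 bstarts:::log_prior_theta(th_c, skel_c, prior_config()),
               ll_r, tolerance = 1e-8)

  # constant covariate rejected
  pan_bad <- pan0
  pan_bad$covariates[, "sex"] <- 1
  expect_error(fit_starts_conditional(pan_bad, prior_config(),
                                      mcmc_config(chains = 2, burnin = 50,
                                                  draws = 50, seed = 1)),
               "constant covariate")
})

test_that("prior-sensitivity refits report paired differences and flag large shifts", {
  p <- small_params()
  pan <- simulate_starts_panel(p, 800, seed = 81)
  cfg <- mcmc_config(chains = 2, burnin = 300, draws = 300, seed = 82)
  sens <- suppressWarnings(sensitivity_refit(pan, cfg, threshold = 0.5))
  expect_s3_class(sens, "starts_sensitivity")
  expect_true(all(c("parameter", "mean_ref", "mean_alt", "delta", "flagged")
                  %in% names(sens$table)))
  expect_true(is.finite(sens$max_abs_delta_structural))
  # identical prior and seed: zero difference
  f1 <- suppressWarnings(fit_starts(pan, prior_config(), cfg))
  sens0 <- suppressWarnings(sensitivity_refit(pan, cfg, fit1 = f1,
                                              nu_phi_alt = 1))
  expect_equal(max(abs(sens0$table$delta)), 0)
})
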