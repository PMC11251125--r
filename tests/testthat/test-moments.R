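test_that("decoupled constructs give block-diagonal covariance with the closed-form lag structure", {
  b <- 0.8
  p <- starts_params(
    cst_cov = diag(c(0.3, 0.2)),
    art1_cov = diag(c(0.25, 0.15)),
    autoreg = c(b, b),
    crosslag = matrix(0, 3, 2),
    dist_cov = diag(c(0.1, 0.1)),
    state_var = matrix(0.5, 4, 2),
    state_cov = 0
  )
  mom <- starts_implied_moments(p)
  # no cross-construct covariance anywhere
  expect_equal(max(abs(mom$cov[1:4, 5:8])), 0)
  # within construct: cov(Y_t, Y_s) = cst + b^|t-s| Var(ART_min(t,s))
  A <- numeric(4); A[1] <- 0.25
  for (t in 2:4) A[t] <- b^2 * A[t - 1] + 0.1
  for (t in 1:4) for (s in 1:4) {
    expected <- 0.3 + b^(abs(t - s)) * A[min(t, s)] +
      (t == s) * 0.5
    expect_equal(mom$cov[t, s], expected, tolerance = 1e-12)
  }
})

test_that("variance decomposition is exact and the implied covariance is symmetric PD over random valid draws", {
  set.seed(42)
  for (rep in 1:25) {
    p <- starts_params(
      cst_cov = crossprod(matrix(rnorm(4, sd = 0.5), 2)) + diag(0.05, 2),
      art1_cov = crossprod(matrix(rnorm(4, sd = 0.5), 2)) + diag(0.05, 2),
      autoreg = runif(2, 0.2, 1.1),
      crosslag = matrix(rnorm(6, sd = 0.3), 3, 2),
      dist_cov = crossprod(matrix(rnorm(4, sd = 0.4), 2)) + diag(0.05, 2),
      state_var = matrix(runif(8, 0.2, 0.8), 4, 2),
      state_cov = runif(1, -0.1, 0.1)
    )
    expect_identical(validate_starts_params(p), character(0))
    mom <- starts_implied_moments(p)
    expect_equal(mom$cov, t(mom$cov))
    expect_gt(min(eigen(mom$cov, symmetric = TRUE)$values), 0)
    # per wave/construct: cst + art + state = total implied variance
    std <- starts_standardize(p)
    for (t in 1:4) for (x in 1:2) {
      total <- unname(diag(p$cst_cov)[x] + std$art_var[t, x] + p$state_var[t, x])
      expect_equal(mom$cov[(x - 1) * 4 + t, (x - 1) * 4 + t], total,
                   tolerance = 1e-12)
    }
  }
})

test_that("the generating oracle's wave-1 cross-construct covariance carries the published trait covariance", {
  o <- backout_params()
  mom <- starts_implied_moments(o)
  # wave-1 EM-CL covariance = CST cov + ART1 cov + state cov; the ART1 part
  # contributes the printed 0.113
  expect_equal(mom$cov["EM1", "CL1"] - o$cst_cov[1, 2] - o$state_cov, 0.113,
               tolerance = 1e-12)
})

test_that("implied moments match the Monte-Carlo covariance of one million simulated dyads", {
  o <- backout_params()
  n <- 1e6
  panel <- simulate_starts_panel(o, n, seed = 1L)
  emp <- stats::cov(panel$y)
  mom <- starts_implied_moments(o)
  se <- sqrt((outer(diag(emp), diag(emp)) + emp^2) / n)
  expect_true(all(abs(emp - mom$cov) < 3 * se))
  expect_lt(max(abs(colMeans(panel$y))), 3 * sqrt(max(diag(emp)) / n) * 3)
})

test_that("compiled and reference implementations of the implied covariance agree", {
  set.seed(7)
  for (rep in 1:10) {
    p <- starts_params(
      cst_cov = crossprod(matrix(rnorm(4, sd = 0.5), 2)) + diag(0.05, 2),
      art1_cov = crossprod(matrix(rnorm(4, sd = 0.5), 2)) + diag(0.05, 2),
      autoreg = runif(2, 0.2, 1.1),
      crosslag = matrix(rnorm(6, sd = 0.3), 3, 2),
      dist_cov = crossprod(matrix(rnorm(4, sd = 0.4), 2)) + diag(0.05, 2),
      state_var = matrix(runif(8, 0.2, 0.8), 4, 2),
      state_cov = runif(1, -0.1, 0.1)
    )
    Scpp <- bstarts:::.starts_sigma_cpp(p$cst_cov, p$art1_cov, p$autoreg,
                                        p$crosslag, p$dist_cov, p$state_var,
                                        p$state_cov, 4L)
    expect_equal(unname(starts_implied_moments(p)$cov), Scpp,
                 tolerance = 1e-12)
  }
})
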