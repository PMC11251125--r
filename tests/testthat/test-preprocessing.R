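test_that("composite scoring sums items, propagates missingness, and enforces ranges", {
  items <- data.frame(
    em1_i1 = c(2, 0, 1), em1_i2 = c(2, 1, NA), em1_i3 = c(2, 0, 0),
    em1_i4 = c(2, 0, 1), em1_i5 = c(2, 1, 2),
    cl1_i1 = c(5, 3, 4), cl1_i2 = c(5, 2, 4), cl1_i3 = c(5, 1, 4),
    cl1_i4 = c(5, 5, 4), cl1_i5 = c(5, 4, 4), cl1_i6 = c(5, 3, 4),
    cl1_i7 = c(5, 2, 4),
    id = c("a", "b", "c")
  )
  out <- score_composites(items)
  expect_equal(out$EM1, c(10, 2, NA))       # max; sum; missing item
  expect_equal(out$CL1, c(35, 20, 28))      # closeness maximum is 35
  expect_true("id" %in% names(out))

  bad <- items; bad$em1_i2[1] <- 3
  expect_error(score_composites(bad), "em1_i2.*row 1")
  short <- items[, -3]
  expect_error(score_composites(short), "expected 5")
})

test_that("average-SD scaling reproduces the published arithmetic exactly on constructed data", {
  set.seed(11)
  n <- 500
  sds_em <- c(1.42, 1.73, 2.06, 2.08)
  sds_cl <- c(1.91, 1.99, 2.36, 2.35)
  mk <- function(s) as.numeric(scale(stats::rnorm(n))) * s
  wide <- data.frame(
    EM1 = mk(sds_em[1]), EM2 = mk(sds_em[2]), EM3 = mk(sds_em[3]),
    EM4 = mk(sds_em[4]),
    CL1 = mk(sds_cl[1]), CL2 = mk(sds_cl[2]), CL3 = mk(sds_cl[3]),
    CL4 = mk(sds_cl[4])
  )
  panel <- scale_by_average_sd(wide)
  sc <- attr(panel, "scaling")
  expect_equal(unname(sc$avg_sd["EM"]), 1.8225, tolerance = 1e-12)
  expect_equal(stats::var(panel$y[, "EM1"]), (1.42 / 1.8225)^2,
               tolerance = 1e-10)
  # average of the scaled variances equals the Jensen-gapped arithmetic value
  # (exactly 1 only for equal wave SDs)
  mvar <- mean(apply(panel$y[, 1:4], 2, stats::var))
  expect_equal(mvar, mean((sds_em / 1.8225)^2), tolerance = 1e-10)
  expect_gt(mvar, 0.98); expect_lt(mvar, 1.03)
  expect_lt(max(abs(colMeans(panel$y))), 1e-12)

  # equal SDs: every scaled variance is exactly 1
  eq <- data.frame(EM1 = mk(2), EM2 = mk(2), EM3 = mk(2), EM4 = mk(2),
                   CL1 = mk(3), CL2 = mk(3), CL3 = mk(3), CL4 = mk(3))
  expect_equal(unname(apply(scale_by_average_sd(eq)$y, 2, stats::var)),
               rep(1, 8), tolerance = 1e-10)

  # round trip back to the raw metric
  expect_equal(as.matrix(unscale_panel(panel)[, names(wide)]),
               as.matrix(wide), tolerance = 1e-12, ignore_attr = TRUE)

  const <- wide; const$EM2 <- 1
  expect_error(scale_by_average_sd(const), "EM2")
})

test_that("descriptive statistics, stars, and VIF behave at their limits", {
  set.seed(12)
  n <- 1e4
  X <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                  c = stats::rnorm(n), d = stats::rnorm(n))
  rep_ind <- descriptives(X)
  expect_lt(abs(rep_ind$vif_average - 1), 0.05)
  expect_true(all(rep_ind$vif >= 1))

  X2 <- X; X2$e <- X$a                          # identical pair
  rep_col <- descriptives(X2, vif_cap = 1e6)
  expect_equal(rep_col$correlations["a", "e"], 1)
  expect_true(any(rep_col$vif_flagged))
  expect_equal(max(rep_col$vif), 1e6)

  Y <- data.frame(u = stats::rnorm(50), v = 1)  # constant column
  rep_c <- descriptives(Y)
  expect_true(is.na(rep_c$correlations["u", "v"]))

  # a strong correlation earns the three-star significance mark
  Z <- data.frame(x = stats::rnorm(200))
  Z$y <- Z$x + stats::rnorm(200, sd = 0.5)
  rep_z <- descriptives(Z)
  expect_equal(rep_z$stars["x", "y"], "***")
})

test_that("a synthetic cohort reproduces the published descriptive moments", {
  o <- backout_params()
  coh <- generate_cohort(o, n = 7507, seed = 14)
  d <- descriptives(coh)
  # wave-4 emotional difficulties: printed mean 2.111 (SD 2.08)
  expect_lt(abs(d$means[["EM4"]] - 2.111), 4 * 2.08 / sqrt(7507))
  expect_lt(abs(d$sds[["EM4"]] - 2.08), 4 * 2.08 * sqrt(2 / 7507))
  expect_lt(abs(d$means[["CL1"]] - 33.805), 4 * 1.91 / sqrt(7507))
  # covariate marginals near the published sample description
  expect_lt(abs(d$means[["sex"]] - 0.4967), 0.02)
  expect_lt(abs(d$means[["ethnicity"]] - 0.8425), 0.02)
})
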