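# Bayesian approximate and noncentrality fit indices (BRMSEA, BCFI, BTLI,
# BGammaHat, BMc). The construction is a posterior-discrepancy analogue of
# the classical indices: per draw i,
#   D_i   = -2 (loglik(theta_i) - loglik_saturated)
#   pD    = mean(D) - D(posterior mean)          (DIC-style effective count)
#   df    = p* - pD,  p* = modeled nonredundant moments
#   nc_i  = D_i - pD - df = D_i - p*             (noncentrality)
# with an independence null model (free variances, same machinery) supplying
# the baseline noncentralities for the incremental indices.

# saturated (unstructured mean + covariance) maximum log-likelihood.
# Complete data: closed form at the MLE. Missing data: EM for the MVN MLE.
saturated_loglik <- function(panel, tol = 1e-8, max_iter = 500) {
  y <- panel$y
  if (all(panel$mask)) {
    n <- nrow(y); p <- ncol(y)
    mu <- colMeans(y)
    S <- crossprod(sweep(y, 2, mu)) / n
    return(-0.5 * n * (p * log(2 * pi) + determinant(S)$modulus[1] + p))
  }
  em <- em_mvn(y, tol = tol, max_iter = max_iter)
  loglik_from_moments(em$mu, em$Sigma, panel)
}

# EM algorithm for the MVN MLE under arbitrary missingness
em_mvn <- function(y, tol = 1e-8, max_iter = 500) {
  n <- nrow(y); p <- ncol(y)
  mu <- colMeans(y, na.rm = TRUE)
  v <- apply(y, 2, stats::var, na.rm = TRUE)
  Sigma <- diag(pmax(v, 1e-6), p)
  pat <- apply(!is.na(y), 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  last <- -Inf
  for (it in seq_len(max_iter)) {
    sum_y <- numeric(p); sum_yy <- matrix(0, p, p)
    for (rows in groups) {
      obs <- which(!is.na(y[rows[1], ]))
      mis <- setdiff(seq_len(p), obs)
      yo <- y[rows, obs, drop = FALSE]
      m <- length(rows)
      if (length(mis) == 0) {
        sum_y <- sum_y + colSums(yo)
        sum_yy <- sum_yy + crossprod(yo)
        next
      }
      Soo <- Sigma[obs, obs, drop = FALSE]
      Smo <- Sigma[mis, obs, drop = FALSE]
      W <- Smo %*% solve(Soo)                        # regression weights
      cond_cov <- Sigma[mis, mis, drop = FALSE] - W %*% t(Smo)
      dev <- sweep(yo, 2, mu[obs])
      ym <- sweep(dev %*% t(W), 2, mu[mis], "+")     # conditional means
      full <- matrix(0, m, p)
      full[, obs] <- yo; full[, mis] <- ym
      sum_y <- sum_y + colSums(full)
      cp <- crossprod(full)
      cp[mis, mis] <- cp[mis, mis] + m * cond_cov
      sum_yy <- sum_yy + cp
    }
    mu <- sum_y / n
    Sigma <- sum_yy / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_from_moments(mu, Sigma, list(y = y, mask = !is.na(y)))
    if (is.finite(last) && abs(ll - last) < tol * (abs(ll) + 1)) break
    last <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it)
}

# independence null model: free variance per column (means at the sample
# mean), conjugate inverse-gamma posterior sampled exactly.
null_model_discrepancies <- function(panel, n_draws, priors, seed) {
  y <- panel$y; mask <- panel$mask
  p <- ncol(y)
  a <- priors$var_shape; b <- priors$var_rate
  n_j <- colSums(mask)
  mu_j <- colMeans(y, na.rm = TRUE)
  ss_j <- vapply(seq_len(p), function(j)
    sum((y[mask[, j], j] - mu_j[j])^2), numeric(1))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # draws x p matrix of variances from IG(a + n/2, b + ss/2)
  v <- vapply(seq_len(p), function(j)
    1 / stats::rgamma(n_draws, shape = a + n_j[j] / 2, rate = b + ss_j[j] / 2),
    numeric(n_draws))
  ll <- function(vars) {
    sum(-0.5 * (n_j * log(2 * pi * vars) + ss_j / vars))
  }
  D <- vapply(seq_len(n_draws), function(i) -2 * ll(v[i, ]), numeric(1))
  v_mean <- colMeans(v)
  list(D = D, D_at_mean = -2 * ll(v_mean))
}

#' Bayesian fit indices for a STARTS fit
#'
#' Computes posterior distributions of BRMSEA, BCFI, BTLI, BGammaHat and
#' McDonald's BMc from per-draw discrepancies against the saturated
#' (unstructured) model, with a DIC-style effective-parameter adjustment
#' and an independence null model (free variances) as the incremental
#' baseline. Conventional good-fit benchmarks: BCFI/BTLI near or above
#' 0.95, BRMSEA below 0.06, BGammaHat/BMc near or above 0.95.
#'
#' @param fit a converged [fit_starts()] result (unconditional model).
#' @param panel the [starts_panel()] the model was fitted to.
#' @param max_draws cap on the number of posterior draws used (subsampled
#'   deterministically if exceeded).
#' @return Object of class `starts_fit_indices`: posterior mean and 90%
#'   interval per index, plus `p_star`, `pD`, `df`, and the null-model
#'   quantities.
#' @export
starts_fit_indices <- function(fit, panel, max_draws = Inf) {
  if (fit$model$conditional)
    stop("fit indices are implemented for the unconditional model")
  x <- flat_draws(fit)
  if (nrow(x) > max_draws) {
    keep <- round(seq(1, nrow(x), length.out = max_draws))
    x <- x[keep, , drop = FALSE]
  }
  n_draws <- nrow(x)
  panel <- with_suffstats(panel)
  ll_sat <- saturated_loglik(panel)
  n <- nrow(panel$y)
  T_ <- fit$model$T_; p <- 2L * T_
  p_star <- p * (p + 1) / 2 + if (fit$model$means_free) p else 0

  ll_i <- vapply(seq_len(n_draws), function(i) {
    starts_loglik(constrained_to_params(x[i, ], fit$skeleton), panel,
                  validate = FALSE)
  }, numeric(1))
  D <- -2 * (ll_i - ll_sat)
  theta_bar <- constrained_to_params(colMeans(x), fit$skeleton)
  D_bar <- -2 * (starts_loglik(theta_bar, panel, validate = FALSE) - ll_sat)
  pD <- mean(D) - D_bar
  df <- p_star - pD
  if (df <= 0)
    stop(sprintf("model is not overidentified: df = %.2f <= 0", df))

  null <- null_model_discrepancies(panel, n_draws, fit$priors, fit$mcmc$seed + 1L)
  pD0 <- mean(null$D) - null$D_at_mean
  df0 <- p_star - pD0

  nc <- D - pD - df
  nc0 <- null$D - pD0 - df0
  brmsea <- sqrt(pmax(0, nc / (df * (n - 1))))
  bcfi <- 1 - pmax(0, nc) / pmax(nc0, nc, 0)
  bcfi[!is.finite(bcfi)] <- 1  # 0/0: both models fit perfectly
  r0 <- (null$D - pD0) / df0
  r1 <- (D - pD) / df
  btli <- (r0 - r1) / (r0 - 1)
  bgamma <- p / (p + 2 * nc / (n - 1))
  bmc <- exp(-0.5 * nc / (n - 1))

  summ <- function(v) c(mean = mean(v),
                        stats::quantile(v, c(0.05, 0.95)))
  tab <- rbind(BRMSEA = summ(brmsea), BCFI = summ(bcfi), BTLI = summ(btli),
               BGammaHat = summ(bgamma), BMc = summ(bmc))
  colnames(tab) <- c("mean", "q05", "q95")
  structure(list(
    indices = as.data.frame(tab),
    draws = data.frame(BRMSEA = brmsea, BCFI = bcfi, BTLI = btli,
                       BGammaHat = bgamma, BMc = bmc),
    p_star = p_star, pD = pD, df = df, pD0 = pD0, df0 = df0,
    D_mean = mean(D), D_at_mean = D_bar, loglik_saturated = ll_sat,
    n = n
  ), class = "starts_fit_indices")
}

#' @export
print.starts_fit_indices <- function(x, ...) {
  cat(sprintf("Bayesian fit indices (n = %d, p* = %d, pD = %.2f, df = %.2f)\n",
              x$n, x$p_star, x$pD, x$df))
  tab <- x$indices
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-10s %.3f  [90%% CrI %.3f, %.3f]\n", rownames(tab)[i],
                tab$mean[i], tab$q05[i], tab$q95[i]))
  invisible(x)
}
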