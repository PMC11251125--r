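#' Full-information marginal log-likelihood of a panel
#'
#' Multivariate-normal log-likelihood of the observed data under the
#' model-implied moments, marginalizing each dyad's missing coordinates
#' (pattern-wise full-information evaluation). Rows are grouped by
#' missingness pattern so each pattern's covariance sub-block is factorized
#' once; a complete-data panel collapses to the sufficient-statistic form
#' \deqn{-\tfrac{n}{2}\left(p\log 2\pi + \log|\Sigma| +
#'   \mathrm{tr}(\Sigma^{-1} S) + (\bar y-\mu)'\Sigma^{-1}(\bar y-\mu)\right)}
#' which makes the evaluation cost independent of the number of dyads.
#'
#' @param params a valid [starts_params()].
#' @param panel a [starts_panel()].
#' @param validate validate `params` first (default `TRUE`).
#' @return scalar log-likelihood.
#' @export
starts_loglik <- function(params, panel, validate = TRUE) {
  if (validate) stop_if_invalid(params)
  mom <- starts_implied_moments(params, validate = FALSE)
  loglik_from_moments(mom$mean, mom$cov, panel)
}

# shared evaluator: works for any implied (mu, Sigma) and panel-like data
loglik_from_moments <- function(mu, Sigma, panel) {
  y <- panel$y; mask <- panel$mask
  if (all(mask)) {
    ss <- panel_suffstats(panel)
    return(loglik_suffstats(mu, Sigma, ss$n, ss$ybar, ss$S))
  }
  pat <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  total <- 0
  for (key in unique(pat)) {
    rows <- which(pat == key)
    obs <- which(mask[rows[1], ])
    yy <- y[rows, obs, drop = FALSE]
    total <- total + dmvnorm_block(yy, mu[obs], Sigma[obs, obs, drop = FALSE])
  }
  total
}

# sum of MVN log densities for a complete block of rows
dmvnorm_block <- function(yy, mu, Sigma) {
  n <- nrow(yy); p <- length(mu)
  L <- chol(Sigma)
  z <- backsolve(L, t(yy) - mu, transpose = TRUE)  # p x n
  -0.5 * (n * p * log(2 * pi) + 2 * n * sum(log(diag(L))) + sum(z * z))
}

loglik_suffstats <- function(mu, Sigma, n, ybar, S) {
  p <- length(mu)
  L <- chol(Sigma)
  # tr(Sigma^-1 S): solve via chol; quadratic form for the mean offset
  Sinv_S <- chol2inv(L) %*% S
  d <- ybar - mu
  zd <- backsolve(L, d, transpose = TRUE)
  -0.5 * n * (p * log(2 * pi) + 2 * sum(log(diag(L))) +
                sum(diag(Sinv_S)) + sum(zd * zd))
}

# n, sample mean, and MLE covariance (divisor n) about the sample mean;
# cached on the panel via an environment-free attribute idiom
panel_suffstats <- function(panel) {
  ss <- attr(panel, "suffstats")
  if (!is.null(ss)) return(ss)
  n <- nrow(panel$y)
  ybar <- colMeans(panel$y)
  yc <- sweep(panel$y, 2L, ybar)
  list(n = n, ybar = ybar, S = crossprod(yc) / n)
}

# attach cached sufficient statistics (used by the sampler on complete data)
with_suffstats <- function(panel) {
  if (all(panel$mask) && is.null(attr(panel, "suffstats")))
    attr(panel, "suffstats") <- panel_suffstats(panel)
  panel
}

# joint (Y, X) panel for the conditional model: columns are y then covariates
joint_panel <- function(panel) {
  if (is.null(panel$covariates)) stop("panel has no covariate block")
  y <- cbind(panel$y, panel$covariates)
  mask <- !is.na(y)
  out <- list(y = y, mask = mask)
  if (all(mask)) {
    n <- nrow(y); ybar <- colMeans(y); yc <- sweep(y, 2L, ybar)
    attr(out, "suffstats") <- list(n = n, ybar = ybar, S = crossprod(yc) / n)
  }
  out
}
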