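# Convergence diagnostics: split-chain potential scale reduction (PSR) and
# autocorrelation-sum effective sample size (ESS), computed per parameter.

# split each chain in half -> 2m half-chains
split_chains <- function(x) {
  # x: iterations x chains
  n <- nrow(x); h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

psr_one <- function(x) {
  # x: iterations x chains (already split)
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0) return(1)  # degenerate chains
  sqrt(var_plus / W)
}

ess_one <- function(x) {
  # combined-chain autocorrelation-sum estimator with Geyer initial
  # positive-pair truncation, on split chains
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  mu <- colMeans(x)
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0 || W <= 0) return(n * m)
  max_lag <- n - 2L
  acov <- vapply(seq_len(m), function(j) {
    xc <- x[, j] - mu[j]
    stats::acf(xc, lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # sum consecutive pairs while positive
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(n * m / tau, n * m)
}

#' Convergence report: split-chain PSR and effective sample size
#'
#' Computes the split-chain potential scale reduction factor (each chain is
#' halved, so stationarity within chains is penalized as well as
#' disagreement between chains) and an autocorrelation-sum effective sample
#' size with Geyer initial-positive-pair truncation, per free parameter.
#' The pass gates follow the estimation protocol: PSR below 1.05
#' (1.1 is retained as a warning level) and ESS of at least 300.
#'
#' @param fit a [fit_starts()] object, or a 3-d array
#'   (`chains x iterations x parameters`) of draws.
#' @param psr_limit,psr_warn,ess_limit the gates.
#' @return Object of class `convergence_report`: per-parameter `psr` and
#'   `ess`, `max_psr`, `min_ess`, and pass flags.
#' @export
psr_report <- function(fit, psr_limit = 1.05, psr_warn = 1.1,
                       ess_limit = 300) {
  if (inherits(fit, "starts_fit")) {
    draws <- fit$draws[, , fit$free, drop = FALSE]
  } else draws <- fit
  if (length(dim(draws)) != 3L) stop("draws must be chains x iterations x parameters")
  m <- dim(draws)[1]; n <- dim(draws)[2]; P <- dim(draws)[3]
  if (m < 2) stop("at least 2 chains are required")
  if (n %/% 2L < 4L) stop("need at least 4 draws per half-chain")
  nms <- dimnames(draws)[[3]]
  if (is.null(nms)) nms <- paste0("par", seq_len(P))
  psr <- ess <- stats::setNames(numeric(P), nms)
  for (p in seq_len(P)) {
    x <- split_chains(t(draws[, , p]))
    if (all(apply(x, 2, stats::var) < 1e-300)) { # constant draws
      psr[p] <- 1; ess[p] <- n * m
    } else {
      psr[p] <- psr_one(x)
      ess[p] <- ess_one(x)
    }
  }
  structure(list(
    psr = psr, ess = ess,
    max_psr = max(psr), min_ess = min(ess),
    psr_limit = psr_limit, psr_warn = psr_warn, ess_limit = ess_limit,
    pass_psr = max(psr) < psr_limit,
    warn_psr = max(psr) >= psr_limit & max(psr) < psr_warn,
    pass_ess = min(ess) >= ess_limit,
    pass = max(psr) < psr_limit && min(ess) >= ess_limit
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: max PSR = %.4f (gate %.2f), min ESS = %.0f (gate %.0f) -> %s\n",
              x$max_psr, x$psr_limit, x$min_ess, x$ess_limit,
              if (x$pass) "PASS" else "FAIL"))
  worst <- names(sort(x$psr, decreasing = TRUE))[seq_len(min(3, length(x$psr)))]
  cat("  highest-PSR parameters:",
      paste(sprintf("%s (%.3f)", worst, x$psr[worst]), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Per parameter: posterior mean, SD, equal-tailed 95% credible interval,
#' and whether the interval excludes zero. Standardized estimates are
#' derived per draw through [starts_standardize()] and then averaged
#' (the mean-then-standardize value is also reported, since the two differ
#' by a Jensen gap for nonlinear functionals).
#'
#' @param fit a [fit_starts()] object.
#' @param standardized also compute per-draw standardized summaries
#'   (default `TRUE` for unconditional fits).
#' @return Object of class `posterior_summary`: data frames `raw` and
#'   (optionally) `standardized`.
#' @export
summarize_posterior <- function(fit, standardized = !fit$model$conditional) {
  x <- flat_draws(fit)
  qs <- t(apply(x, 2, stats::quantile, probs = c(0.025, 0.975)))
  raw <- data.frame(
    parameter = colnames(x),
    mean = colMeans(x),
    sd = apply(x, 2, stats::sd),
    ci_lower = qs[, 1], ci_upper = qs[, 2],
    excludes_zero = qs[, 1] > 0 | qs[, 2] < 0,
    row.names = NULL
  )
  out <- list(raw = raw, n_draws = nrow(x))
  if (standardized) {
    proto <- standardized_vector(
      starts_standardize(posterior_mean_params(fit), validate = FALSE))
    sv <- vapply(seq_len(nrow(x)), function(i) {
      standardized_vector(starts_standardize(
        constrained_to_params(x[i, ], fit$skeleton), validate = FALSE))
    }, proto)
    sq <- t(apply(sv, 1, stats::quantile, probs = c(0.025, 0.975)))
    at_mean <- standardized_vector(
      starts_standardize(posterior_mean_params(fit), validate = FALSE))
    out$standardized <- data.frame(
      parameter = rownames(sv),
      mean = rowMeans(sv),
      sd = apply(sv, 1, stats::sd),
      ci_lower = sq[, 1], ci_upper = sq[, 2],
      at_posterior_mean = at_mean,
      row.names = NULL
    )
  }
  structure(out, class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%d draws)\n", x$n_draws))
  print(format(x$raw, digits = digits), row.names = FALSE)
  if (!is.null(x$standardized)) {
    cat("\nStandardized (per-draw, then averaged):\n")
    print(format(x$standardized, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares a posterior against the generating parameter set: per-parameter
#' bias (posterior mean minus truth), relative bias, and whether the 95%
#' credible interval covers the truth.
#'
#' @param truth a [starts_params()] (the generating values).
#' @param fit a [fit_starts()] object.
#' @return Object of class `recovery_report`: a data frame plus aggregate
#'   maximum absolute structural bias and coverage rate.
#' @export
recovery_report <- function(truth, fit) {
  tv <- params_to_constrained(truth, fit$skeleton)
  if (!identical(names(tv), fit$param_names))
    stop("parameter names of truth and samples do not match")
  x <- flat_draws(fit)
  qs <- t(apply(x, 2, stats::quantile, probs = c(0.025, 0.975)))
  pm <- colMeans(x)
  tab <- data.frame(
    parameter = fit$param_names,
    truth = unname(tv),
    post_mean = unname(pm),
    bias = unname(pm - tv),
    rel_bias = unname(ifelse(abs(tv) > 1e-12, (pm - tv) / tv, NA_real_)),
    ci_lower = qs[, 1], ci_upper = qs[, 2],
    covered = unname(tv >= qs[, 1] & tv <= qs[, 2]),
    row.names = NULL
  )
  tab <- tab[fit$free[match(tab$parameter, fit$param_names)], ]
  struct <- structural_param_names(fit$model$T_)
  st <- tab[tab$parameter %in% struct, ]
  structure(list(
    table = tab,
    max_abs_bias_structural = max(abs(st$bias)),
    coverage_structural = mean(st$covered),
    coverage_all = mean(tab$covered)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat(sprintf("Recovery: max |bias| (structural) = %.4f; CrI coverage %.0f%% (structural), %.0f%% (all)\n",
              x$max_abs_bias_structural, 100 * x$coverage_structural,
              100 * x$coverage_all))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}
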