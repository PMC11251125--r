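#' Standardized loadings, paths, and correlations of a STARTS solution
#'
#' Converts the raw (covariance-metric) parameters to the standardized
#' quantities conventionally reported for latent state-trait models:
#'
#' * trait loadings per wave, \eqn{\lambda_{CST,x,t} = sd(CST_x)/sd(Y_{x,t})}
#'   and \eqn{\lambda_{ART,x,t} = sd(ART_{x,t})/sd(Y_{x,t})}, with
#'   \eqn{sd(Y_{x,t})} taken from the model-implied covariance diagonal;
#' * standardized regression coefficients,
#'   \eqn{\beta_{std} = \beta_{raw} \, sd(\mathrm{predictor}) /
#'   sd(\mathrm{outcome})} using the model-implied latent SDs of the
#'   autoregressive traits at the relevant waves;
#' * correlations for every covariance parameter (stable traits, wave-1
#'   autoregressive traits, disturbances, and each wave's states) using the
#'   model-implied latent variances.
#'
#' @param params a valid [starts_params()].
#' @param validate validate first (default `TRUE`).
#' @return Object of class `starts_standardized`: a list with matrices
#'   `lambda_cst`, `lambda_art` (waves x constructs), `autoreg_std`,
#'   `crosslag_std` (intervals x 2), scalars `cst_cor`, `art1_cor`,
#'   `dist_cor`, vector `state_cor` (per wave), plus the implied latent and
#'   observed SDs used.
#' @export
starts_standardize <- function(params, validate = TRUE) {
  if (validate) stop_if_invalid(params)
  T_ <- params$n_waves
  mom <- starts_implied_moments(params, validate = FALSE)
  sdY <- matrix(sqrt(diag(mom$cov)), T_, 2)  # waves x (EM, CL)

  B <- transition_matrices(params)
  A <- vector("list", T_)
  A[[1]] <- params$art1_cov
  if (T_ > 1)
    for (t in 2:T_)
      A[[t]] <- B[[t - 1]] %*% A[[t - 1]] %*% t(B[[t - 1]]) + params$dist_cov
  art_var <- t(vapply(A, diag, numeric(2)))  # waves x (EM, CL)

  need_pos <- function(v, what) {
    if (any(v <= 0)) stop("degenerate (zero) variance in ", what, call. = FALSE)
    v
  }
  cst_var <- need_pos(diag(params$cst_cov), "cst_cov")
  need_pos(diag(params$art1_cov), "art1_cov")
  dist_var <- need_pos(diag(params$dist_cov), "dist_cov")
  state_var <- params$state_var
  need_pos(as.numeric(state_var), "state_var")
  need_pos(as.numeric(sdY), "implied observed variance")

  lambda_cst <- sweep(matrix(sqrt(cst_var), T_, 2, byrow = TRUE), c(1, 2), sdY, "/")
  lambda_art <- sqrt(art_var) / sdY

  sdA <- sqrt(art_var)
  autoreg_std <- matrix(NA_real_, T_ - 1L, 2,
                        dimnames = list(NULL, construct_names()))
  crosslag_std <- matrix(NA_real_, T_ - 1L, 2,
                         dimnames = list(NULL, c("EMtoCL", "CLtoEM")))
  for (t in seq_len(T_ - 1L)) {
    autoreg_std[t, ] <- params$autoreg * sdA[t, ] / sdA[t + 1L, ]
    crosslag_std[t, 1] <- params$crosslag[t, 1] * sdA[t, 1] / sdA[t + 1L, 2]
    crosslag_std[t, 2] <- params$crosslag[t, 2] * sdA[t, 2] / sdA[t + 1L, 1]
  }

  structure(list(
    lambda_cst = lambda_cst,
    lambda_art = lambda_art,
    autoreg_std = autoreg_std,
    crosslag_std = crosslag_std,
    cst_cor = params$cst_cov[1, 2] / sqrt(prod(cst_var)),
    art1_cor = params$art1_cov[1, 2] / sqrt(prod(diag(params$art1_cov))),
    dist_cor = params$dist_cov[1, 2] / sqrt(prod(dist_var)),
    state_cor = params$state_cov / sqrt(state_var[, 1] * state_var[, 2]),
    sd_observed = sdY,
    sd_art = sdA,
    art_var = art_var
  ), class = "starts_standardized")
}

#' @export
print.starts_standardized <- function(x, ...) {
  T_ <- nrow(x$lambda_cst)
  cat("Standardized STARTS solution\n")
  cat("  CST loadings (EM | CL): ",
      paste(sprintf("%.3f|%.3f", x$lambda_cst[, 1], x$lambda_cst[, 2]),
            collapse = "  "), "\n")
  cat("  ART loadings (EM | CL): ",
      paste(sprintf("%.3f|%.3f", x$lambda_art[, 1], x$lambda_art[, 2]),
            collapse = "  "), "\n")
  for (t in seq_len(T_ - 1L))
    cat(sprintf("  interval %d->%d: carryover EM %.3f CL %.3f; spillover EM->CL %.3f, CL->EM %.3f\n",
                t, t + 1, x$autoreg_std[t, 1], x$autoreg_std[t, 2],
                x$crosslag_std[t, 1], x$crosslag_std[t, 2]))
  cat(sprintf("  correlations: CST %.3f, ART1 %.3f, disturbance %.3f\n",
              x$cst_cor, x$art1_cor, x$dist_cor))
  cat("  state correlations by wave:",
      paste(sprintf("%.3f", x$state_cor), collapse = ", "), "\n")
  invisible(x)
}

# flatten the standardized quantities reported for a 4-wave solution into
# the named layout used by summaries and tests (22 rows for T = 4)
standardized_vector <- function(std) {
  T_ <- nrow(std$lambda_cst)
  out <- c(
    stats::setNames(std$autoreg_std[, 1], paste0("autoreg_EM_", seq_len(T_ - 1))),
    stats::setNames(std$autoreg_std[, 2], paste0("autoreg_CL_", seq_len(T_ - 1))),
    stats::setNames(std$crosslag_std[, 1], paste0("crosslag_EMtoCL_", seq_len(T_ - 1))),
    stats::setNames(std$crosslag_std[, 2], paste0("crosslag_CLtoEM_", seq_len(T_ - 1))),
    art1_cor = std$art1_cor,
    dist_cor = std$dist_cor,
    stats::setNames(std$state_cor, paste0("state_cor_", seq_len(T_))),
    cst_cor = std$cst_cor
  )
  out
}
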