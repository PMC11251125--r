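#' Model-implied mean and covariance of the observed panel
#'
#' Propagates the STARTS decomposition analytically. With
#' \eqn{A_t = Cov(ART_t)} the VAR(1) recursion gives
#' \eqn{A_{t} = B_{t-1} A_{t-1} B_{t-1}' + Q} for \eqn{t \ge 2}, and
#' lagged covariances \eqn{Cov(ART_s, ART_t) = (B_{s-1} \cdots B_t) A_t}
#' for \eqn{s > t}. The observed block covariance between waves \eqn{t}
#' and \eqn{s} is then
#' `cst_cov + Cov(ART_t, ART_s) + (t == s) * state_block_t`.
#'
#' Columns are ordered EM block then CL block
#' (`EM1..EMT, CL1..CLT`), the package-wide convention.
#'
#' @param params a valid [starts_params()] object.
#' @param validate run [validate_starts_params()] first (default `TRUE`;
#'   internal hot paths disable it).
#' @return list with `mean` (length `2T`) and `cov` (`2T x 2T`, symmetric
#'   positive definite), both with observed-variable dimnames.
#' @export
starts_implied_moments <- function(params, validate = TRUE) {
  if (validate) stop_if_invalid(params)
  T_ <- params$n_waves
  B <- transition_matrices(params)
  A <- vector("list", T_)
  A[[1]] <- params$art1_cov
  if (T_ > 1)
    for (t in 2:T_)
      A[[t]] <- B[[t - 1]] %*% A[[t - 1]] %*% t(B[[t - 1]]) + params$dist_cov

  # art_cov[[t]][[s]] for s >= t: Cov(ART_s, ART_t) as rows=wave s constructs
  p <- 2L * T_
  cov <- matrix(0, p, p)
  idx <- function(t) c(t, T_ + t)  # (EM_t, CL_t) positions
  for (t in seq_len(T_)) {
    blk <- params$cst_cov + A[[t]] +
      matrix(c(params$state_var[t, 1], params$state_cov,
               params$state_cov, params$state_var[t, 2]), 2, 2)
    cov[idx(t), idx(t)] <- blk
    if (t < T_) {
      M <- diag(2)
      for (s in (t + 1):T_) {
        M <- B[[s - 1]] %*% M
        cross <- params$cst_cov + M %*% A[[t]]  # Cov(Y_s, Y_t) latent part
        cov[idx(s), idx(t)] <- cross
        cov[idx(t), idx(s)] <- t(cross)
      }
    }
  }
  nm <- panel_col_names(T_)
  dimnames(cov) <- list(nm, nm)
  mu <- c(params$means[, 1], params$means[, 2])
  names(mu) <- nm
  list(mean = mu, cov = cov)
}

panel_col_names <- function(T_ = 4L)
  c(paste0("EM", seq_len(T_)), paste0("CL", seq_len(T_)))

# B_t maps (ART_EM_t, ART_CL_t) to wave t+1: diagonal carryover, off-diagonal
# spillover. crosslag[t, 1] is EM->CL (row CL, col EM); crosslag[t, 2] CL->EM.
transition_matrices <- function(params) {
  lapply(seq_len(params$n_waves - 1L), function(t) {
    matrix(c(params$autoreg[1], params$crosslag[t, 1],
             params$crosslag[t, 2], params$autoreg[2]), 2, 2)
  })
}

# joint implied moments over (Y, X) for the covariate-conditional model:
# Y = starts + Gamma X + ..., X ~ N(0, diag(cov_var)); Gamma is 2T x K with
# equated coefficients per construct.
starts_implied_moments_joint <- function(params, cov_var) {
  mom <- starts_implied_moments(params, validate = FALSE)
  K <- nrow(params$cov_coef)
  T_ <- params$n_waves
  Gamma <- rbind(
    matrix(rep(params$cov_coef[, 1], each = T_), T_, K),
    matrix(rep(params$cov_coef[, 2], each = T_), T_, K)
  )
  Sx <- diag(cov_var, K)
  GS <- Gamma %*% Sx
  cov <- rbind(cbind(mom$cov + GS %*% t(Gamma), GS),
               cbind(t(GS), Sx))
  mu <- c(mom$mean, rep(0, K))
  list(mean = mu, cov = cov)
}
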