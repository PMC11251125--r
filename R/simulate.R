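#' Simulate dyad panels from a STARTS parameter set
#'
#' Draws the stable trait pair, the wave-1 autoregressive trait pair,
#' propagates the autoregressive traits through the interval transition
#' matrices with fresh disturbance draws, and adds occasion-specific state
#' draws. All randomness flows through `seed` (a local RNG stream), so
#' identical `(params, n, seed)` reproduce the panel bit-for-bit.
#'
#' @param params a valid [starts_params()].
#' @param n number of dyads (>= 1).
#' @param seed integer seed.
#' @param return_latents also return the latent component draws.
#' @return A [starts_panel()]; with `return_latents = TRUE` the panel has an
#'   attribute `"latents"` holding `cst` (n x 2), `art` (n x 2 x T) and
#'   `state` (n x 2 x T) so that `y = cst + art + state` exactly.
#' @export
simulate_starts_panel <- function(params, n, seed = 1L, return_latents = FALSE) {
  stop_if_invalid(params)
  if (n < 1) stop("n must be >= 1")
  T_ <- params$n_waves
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  cst <- rmvn2(n, params$cst_cov)
  art <- array(NA_real_, c(n, 2, T_))
  art[, , 1] <- rmvn2(n, params$art1_cov)
  B <- transition_matrices(params)
  for (t in seq_len(T_ - 1L))
    art[, , t + 1] <- art[, , t] %*% t(B[[t]]) + rmvn2(n, params$dist_cov)
  state <- array(NA_real_, c(n, 2, T_))
  for (t in seq_len(T_)) {
    Sblk <- matrix(c(params$state_var[t, 1], params$state_cov,
                     params$state_cov, params$state_var[t, 2]), 2, 2)
    state[, , t] <- rmvn2(n, Sblk)
  }

  y <- matrix(NA_real_, n, 2L * T_)
  for (t in seq_len(T_)) {
    y[, t]      <- cst[, 1] + art[, 1, t] + state[, 1, t] + params$means[t, 1]
    y[, T_ + t] <- cst[, 2] + art[, 2, t] + state[, 2, t] + params$means[t, 2]
  }
  colnames(y) <- panel_col_names(T_)
  panel <- starts_panel(y)
  if (return_latents)
    attr(panel, "latents") <- list(cst = cst, art = art, state = state)
  panel
}

# n draws from N(0, S) for 2x2 (or KxK) S, deterministic column order.
# Degenerate S (zero variance) handled via eigen with floor at 0.
rmvn2 <- function(n, S) {
  K <- nrow(S)
  z <- matrix(stats::rnorm(n * K), n, K)
  L <- tryCatch(chol(S), error = function(e) {
    e <- eigen(S, symmetric = TRUE)
    t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  })
  z %*% L
}

# seed hygiene: run under a temporary RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Whole-wave missingness profile
#'
#' Describes cohort-style attrition: at each wave after the first, a dyad
#' drops that wave (both constructs at once) with the given probability.
#' Wave 1 is always observed (cohort entry). The `"MAR-on-wave1"` mechanism
#' makes dropout at later waves logistic in the dyad's wave-1 emotional
#' difficulties score, so attrition is related to observed (not missing)
#' data; `"MCAR"` drops waves independently of everything.
#'
#' @param prob per-wave dropout probabilities (length T; entry 1 must be 0).
#' @param mechanism `"MCAR"` or `"MAR-on-wave1"`.
#' @param mar_coef logistic slope on the standardized wave-1 EM score for
#'   the MAR mechanism.
#' @param seed integer seed used by [apply_missingness()].
#' @return Object of class `missingness_profile`.
#' @export
missingness_profile <- function(prob, mechanism = c("MCAR", "MAR-on-wave1"),
                                mar_coef = 1, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  if (prob[1] != 0) stop("wave 1 is cohort entry and must have dropout probability 0")
  if (all(prob[-1] >= 1)) stop("profile would mask every follow-up wave for every dyad")
  structure(list(prob = prob, mechanism = mechanism, mar_coef = mar_coef,
                 seed = seed), class = "missingness_profile")
}

#' Apply whole-wave attrition to a panel
#'
#' @param panel a [starts_panel()] (or raw cohort table with EM/CL columns).
#' @param profile a [missingness_profile()].
#' @return The panel with masked waves set to `NA`; realized per-wave
#'   missingness rates are recorded in attribute `"missingness_rates"`.
#'   Rows are never left with zero observed entries (wave 1 is retained).
#' @export
apply_missingness <- function(panel, profile) {
  stopifnot(inherits(panel, "starts_panel"), inherits(profile, "missingness_profile"))
  T_ <- panel$meta$n_waves
  if (length(profile$prob) != T_)
    stop("profile length must equal the number of waves")
  n <- nrow(panel$y)
  old <- local_seed(profile$seed)
  on.exit(restore_seed(old), add = TRUE)

  eta <- 0
  if (profile$mechanism == "MAR-on-wave1") {
    em1 <- panel$y[, 1]
    eta <- profile$mar_coef * (em1 - mean(em1)) / stats::sd(em1)
  }
  y <- panel$y
  for (t in 2:T_) {
    p <- profile$prob[t]
    if (p <= 0) next
    pr <- if (identical(eta, 0)) rep(p, n) else stats::plogis(stats::qlogis(p) + eta)
    drop <- stats::runif(n) < pr
    y[drop, c(t, T_ + t)] <- NA_real_
  }
  out <- starts_panel(y, covariates = panel$covariates,
                      wave_ages = panel$meta$wave_ages)
  rates <- vapply(seq_len(T_), function(t) mean(is.na(y[, t])), numeric(1))
  attr(out, "missingness_rates") <- stats::setNames(rates, paste0("wave", seq_len(T_)))
  out
}
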