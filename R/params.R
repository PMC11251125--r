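#' Construct a bivariate STARTS parameter set
#'
#' Bundles every parameter of the bivariate Stable Trait, Autoregressive
#' Trait, State (STARTS) model in the fixed construct order `c("EM", "CL")`
#' (emotional difficulties first, parent-child closeness second) with waves
#' indexed `1..n_waves` (ages 3/5/7/9 in the motivating four-wave design).
#'
#' The observed score for construct \eqn{x} at wave \eqn{t} decomposes as
#' \deqn{Y_{x,t} = CST_x + ART_{x,t} + S_{x,t}}
#' where the completely stable trait pair \eqn{(CST_{EM}, CST_{CL})} has
#' covariance `cst_cov`, the autoregressive traits follow a first-order
#' vector autoregression
#' \deqn{ART_{t+1} = B_t ART_t + D_{t+1}, \quad D \sim N(0, Q)}
#' with equated carryover coefficients `autoreg` on the diagonal of each
#' \eqn{B_t}, freely varying cross-lagged (spillover) coefficients
#' `crosslag` off the diagonal, and equated disturbance covariance
#' `dist_cov`; and the occasion-specific states \eqn{S_{x,t}} (which absorb
#' measurement error) have free wave-specific variances `state_var` and a
#' single equated within-wave covariance `state_cov`.
#'
#' @param cst_cov 2x2 symmetric covariance of the completely stable traits.
#' @param art1_cov 2x2 symmetric covariance of the wave-1 autoregressive traits.
#' @param autoreg length-2 vector of carryover coefficients (EM, CL),
#'   equated over intervals.
#' @param crosslag (n_waves-1)x2 matrix of cross-lagged coefficients per
#'   interval; column 1 is EM to CL, column 2 is CL to EM.
#' @param dist_cov 2x2 symmetric disturbance covariance Q, equated across
#'   intervals.
#' @param state_var n_waves x 2 matrix of state variances (columns EM, CL).
#' @param state_cov scalar within-wave state covariance, equated across waves.
#' @param means n_waves x 2 matrix of observed-variable means; zero when the
#'   panel is centred (the default analysis metric).
#' @param cov_coef optional K x 2 matrix of time-invariant covariate
#'   regression coefficients on the observed variables (columns EM, CL).
#'
#' @return An object of class `starts_params`.
#' @seealso [validate_starts_params()], [starts_implied_moments()],
#'   [simulate_starts_panel()]
#' @export
starts_params <- function(cst_cov, art1_cov, autoreg, crosslag, dist_cov,
                          state_var, state_cov, means = NULL,
                          cov_coef = NULL) {
  state_var <- as.matrix(state_var)
  crosslag <- as.matrix(crosslag)
  n_waves <- nrow(state_var)
  if (is.null(means)) means <- matrix(0, n_waves, 2)
  p <- structure(
    list(
      cst_cov   = sym2(cst_cov, "cst_cov"),
      art1_cov  = sym2(art1_cov, "art1_cov"),
      autoreg   = as.numeric(autoreg),
      crosslag  = crosslag,
      dist_cov  = sym2(dist_cov, "dist_cov"),
      state_var = state_var,
      state_cov = as.numeric(state_cov)[1],
      means     = as.matrix(means),
      cov_coef  = if (!is.null(cov_coef)) as.matrix(cov_coef) else NULL,
      n_waves   = n_waves
    ),
    class = "starts_params"
  )
  dimnames(p$cst_cov) <- dimnames(p$art1_cov) <- dimnames(p$dist_cov) <-
    list(construct_names(), construct_names())
  colnames(p$state_var) <- colnames(p$means) <- construct_names()
  colnames(p$crosslag) <- c("EMtoCL", "CLtoEM")
  p
}

construct_names <- function() c("EM", "CL")

# coerce to 2x2 symmetric, erroring on shape only (PD is validate's job)
sym2 <- function(m, name) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)))
    stop(sprintf("%s must be a 2x2 matrix", name), call. = FALSE)
  (m + t(m)) / 2
}

#' Validate a STARTS parameter set
#'
#' Collects (rather than throws) violations of the structural invariants:
#' positive-definite trait, wave-1, and disturbance covariance blocks,
#' strictly positive state variances, a state covariance compatible with a
#' positive-definite state block at every wave, interval-consistent
#' cross-lag dimensions, and a positive-definite implied observed
#' covariance matrix.
#'
#' @param params a [starts_params()] object.
#' @return Character vector of human-readable violations; `character(0)`
#'   when the parameter set is valid.
#' @export
validate_starts_params <- function(params) {
  v <- character(0)
  if (!inherits(params, "starts_params")) return("not a starts_params object")
  for (blk in c("cst_cov", "art1_cov", "dist_cov")) {
    m <- params[[blk]]
    if (any(!is.finite(m))) {
      v <- c(v, sprintf("%s has non-finite entries", blk)); next
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      v <- c(v, sprintf("%s must be positive definite", blk))
  }
  T_ <- params$n_waves
  if (length(params$autoreg) != 2L)
    v <- c(v, "autoreg must have exactly 2 entries")
  if (!all(dim(params$crosslag) == c(T_ - 1L, 2L)))
    v <- c(v, sprintf("crosslag must be %d x 2 (one row per interval)", T_ - 1L))
  sv <- params$state_var
  if (!all(dim(sv) == c(T_, 2L)))
    v <- c(v, sprintf("state_var must be %d x 2", T_))
  bad <- which(!(is.finite(sv) & sv > 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    for (i in seq_len(nrow(bad)))
      v <- c(v, sprintf("state_var[%d,%s] must be > 0",
                        bad[i, 1], construct_names()[bad[i, 2]]))
  if (nrow(bad) == 0) {
    lim <- sqrt(min(sv[, 1]) * min(sv[, 2]))
    if (!is.finite(params$state_cov) || abs(params$state_cov) >= lim)
      v <- c(v, sprintf(
        "state_cov (%.4g) must satisfy |state_cov| < %.4g for positive-definite state blocks",
        params$state_cov, lim))
  }
  if (!all(dim(params$means) == c(T_, 2L)))
    v <- c(v, sprintf("means must be %d x 2", T_))
  if (!is.null(params$cov_coef) && ncol(params$cov_coef) != 2L)
    v <- c(v, "cov_coef must have 2 columns (EM, CL)")
  if (length(v) == 0) {
    mom <- try(starts_implied_moments(params, validate = FALSE), silent = TRUE)
    if (inherits(mom, "try-error") ||
        min(eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      v <- c(v, "implied observed covariance must be positive definite")
  }
  v
}

stop_if_invalid <- function(params) {
  v <- validate_starts_params(params)
  if (length(v) > 0)
    stop("invalid STARTS parameters: ", paste(v, collapse = "; "),
         call. = FALSE)
  invisible(params)
}

#' @export
print.starts_params <- function(x, ...) {
  cat(sprintf("Bivariate STARTS parameters (%d waves, constructs EM/CL)\n",
              x$n_waves))
  cat(sprintf("  carryover (autoreg): EM %.3f, CL %.3f\n",
              x$autoreg[1], x$autoreg[2]))
  cat(sprintf("  CST covariance: var %.3f / %.3f, cov %.3f\n",
              x$cst_cov[1, 1], x$cst_cov[2, 2], x$cst_cov[1, 2]))
  cat(sprintf("  ART1 covariance: var %.3f / %.3f, cov %.3f\n",
              x$art1_cov[1, 1], x$art1_cov[2, 2], x$art1_cov[1, 2]))
  cat(sprintf("  disturbance Q: var %.3f / %.3f, cov %.3f (equated)\n",
              x$dist_cov[1, 1], x$dist_cov[2, 2], x$dist_cov[1, 2]))
  cat("  cross-lags per interval (EM->CL, CL->EM):\n")
  for (i in seq_len(nrow(x$crosslag)))
    cat(sprintf("    %d -> %d: %+.3f, %+.3f\n", i, i + 1,
                x$crosslag[i, 1], x$crosslag[i, 2]))
  cat(sprintf("  state covariance: %.3f (equated); state variances by wave:\n",
              x$state_cov))
  for (t in seq_len(x$n_waves))
    cat(sprintf("    wave %d: EM %.3f, CL %.3f\n", t,
                x$state_var[t, 1], x$state_var[t, 2]))
  if (!is.null(x$cov_coef))
    cat(sprintf("  covariate coefficients: %d covariates (equated over waves)\n",
                nrow(x$cov_coef)))
  invisible(x)
}

#' Serialize / deserialize STARTS parameters as JSON
#'
#' The JSON layout uses one named block per parameter group
#' (`cst_cov`, `art1_cov`, `autoreg`, `crosslag`, `dist_cov`, `state_var`,
#' `state_cov`, `means`, and optionally `cov_coef`).
#'
#' @param params a [starts_params()] object.
#' @param path file path; for `read_starts_params`, a path written by
#'   `write_starts_params`.
#' @return `read_starts_params` returns a [starts_params()] object.
#' @export
write_starts_params <- function(params, path) {
  x <- list(
    cst_cov = params$cst_cov, art1_cov = params$art1_cov,
    autoreg = params$autoreg, crosslag = params$crosslag,
    dist_cov = params$dist_cov, state_var = params$state_var,
    state_cov = params$state_cov, means = params$means
  )
  if (!is.null(params$cov_coef)) x$cov_coef <- params$cov_coef
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_starts_params
#' @export
read_starts_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  starts_params(
    cst_cov = x$cst_cov, art1_cov = x$art1_cov, autoreg = x$autoreg,
    crosslag = x$crosslag, dist_cov = x$dist_cov, state_var = x$state_var,
    state_cov = x$state_cov, means = x$means, cov_coef = x$cov_coef
  )
}
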