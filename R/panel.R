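#' Construct an observed dyadic panel
#'
#' Wraps an `N x 2T` matrix of composite scores in the fixed column order
#' `EM1..EMT, CL1..CLT` together with its missingness mask and an optional
#' covariate block. Missing entries are `NA`; every dyad must contribute at
#' least one observed score.
#'
#' @param y numeric matrix or data frame with columns `EM1..EMT, CL1..CLT`
#'   (matched by name when present, by position otherwise).
#' @param covariates optional numeric matrix/data frame of time-invariant
#'   covariates (may contain `NA`).
#' @param wave_ages ages at each wave, metadata only (default `c(3,5,7,9)`
#'   truncated/extended to T).
#' @return Object of class `starts_panel` with elements `y`, `mask`
#'   (logical, TRUE = observed), `covariates`, `meta`.
#' @export
starts_panel <- function(y, covariates = NULL, wave_ages = NULL) {
  y <- as.matrix(as.data.frame(y))
  if (ncol(y) %% 2L != 0L) stop("panel must have an even number of columns (EM block then CL block)")
  T_ <- ncol(y) %/% 2L
  want <- panel_col_names(T_)
  if (!is.null(colnames(y)) && all(want %in% colnames(y))) y <- y[, want, drop = FALSE]
  colnames(y) <- want
  storage.mode(y) <- "double"
  mask <- !is.na(y)
  if (any(rowSums(mask) == 0))
    stop("every row must have at least one observed entry; rows all-missing: ",
         paste(utils::head(which(rowSums(mask) == 0)), collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != nrow(y)) stop("covariates must have one row per dyad")
  }
  if (is.null(wave_ages)) wave_ages <- seq(3, by = 2, length.out = T_)
  structure(list(
    y = y, mask = mask, covariates = covariates,
    meta = list(n_waves = T_, wave_ages = wave_ages,
                constructs = construct_names())
  ), class = "starts_panel")
}

#' @export
print.starts_panel <- function(x, ...) {
  cat(sprintf("STARTS panel: %d dyads x %d waves x 2 constructs\n",
              nrow(x$y), x$meta$n_waves))
  miss <- 1 - colMeans(x$mask)
  cat("  missingness by column:\n    ")
  cat(paste(sprintf("%s %.1f%%", colnames(x$y), 100 * miss), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat(sprintf("  covariates: %d (%s)\n", ncol(x$covariates),
                paste(colnames(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Read / write a panel as wide CSV
#'
#' The on-disk format is a wide CSV with header `EM1..EMT,CL1..CLT` followed
#' by any covariate columns; empty cells denote missing values.
#'
#' @param panel a [starts_panel()].
#' @param path CSV path.
#' @return `read_starts_panel` returns a [starts_panel()].
#' @export
write_starts_panel <- function(panel, path) {
  df <- as.data.frame(panel$y)
  if (!is.null(panel$covariates)) df <- cbind(df, as.data.frame(panel$covariates))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_starts_panel
#' @export
read_starts_panel <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  em <- grep("^EM[0-9]+$", names(df), value = TRUE)
  cl <- grep("^CL[0-9]+$", names(df), value = TRUE)
  if (length(em) == 0 || length(em) != length(cl))
    stop("CSV must contain matching EM1..EMT and CL1..CLT columns")
  ycols <- c(sort(em), sort(cl))
  rest <- setdiff(names(df), ycols)
  starts_panel(df[, ycols, drop = FALSE],
               covariates = if (length(rest)) df[, rest, drop = FALSE] else NULL)
}
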