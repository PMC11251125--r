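# Composite scoring, average-SD scaling, and descriptive statistics for the
# raw cohort metric (SDQ emotional-symptoms composite 0-10; Pianta closeness
# composite 7-35).

#' Score item responses into wave composites
#'
#' Sums item responses into the two composites: emotional difficulties
#' (five SDQ emotional-symptoms items scored 0-2, composite range 0-10)
#' and parent-child closeness (seven Pianta closeness items scored 1-5,
#' composite range 7-35). A composite is missing whenever any of its items
#' is missing (no proration).
#'
#' Item columns follow the convention `em<t>_i<j>` and `cl<t>_i<j>`
#' (construct, wave, item), e.g. `em1_i1 .. em1_i5`, `cl3_i1 .. cl3_i7`.
#'
#' @param item_table data frame of item responses.
#' @return Data frame with composite columns `EM<t>`, `CL<t>` for every
#'   wave present, plus any non-item columns passed through.
#' @export
score_composites <- function(item_table) {
  item_table <- as.data.frame(item_table)
  nm <- names(item_table)
  item_cols <- grep("^(em|cl)[0-9]+_i[0-9]+$", nm, value = TRUE)
  if (length(item_cols) == 0) stop("no item columns (em<t>_i<j> / cl<t>_i<j>) found")
  spec <- list(em = list(n_items = 5L, lo = 0, hi = 2, prefix = "EM"),
               cl = list(n_items = 7L, lo = 1, hi = 5, prefix = "CL"))
  out <- item_table[, setdiff(nm, item_cols), drop = FALSE]
  info <- regmatches(item_cols, regexec("^(em|cl)([0-9]+)_i([0-9]+)$", item_cols))
  cons <- vapply(info, `[`, character(1), 2)
  wave <- as.integer(vapply(info, `[`, character(1), 3))
  for (cn in c("em", "cl")) {
    sp <- spec[[cn]]
    for (w in sort(unique(wave[cons == cn]))) {
      cols <- item_cols[cons == cn & wave == w]
      if (length(cols) != sp$n_items)
        stop(sprintf("%s wave %d has %d items, expected %d", toupper(cn), w,
                     length(cols), sp$n_items))
      m <- as.matrix(item_table[, cols])
      bad <- which(!is.na(m) & (m < sp$lo | m > sp$hi), arr.ind = TRUE)
      if (nrow(bad) > 0)
        stop(sprintf("out-of-range response in %s (row %d): value %g outside [%g, %g]",
                     cols[bad[1, 2]], bad[1, 1], m[bad[1, 1], bad[1, 2]],
                     sp$lo, sp$hi))
      comp <- rowSums(m)  # any missing item -> composite missing
      out[[paste0(sp$prefix, w)]] <- comp
    }
  }
  ord <- c(grep("^EM[0-9]+$", names(out), value = TRUE),
           grep("^CL[0-9]+$", names(out), value = TRUE),
           setdiff(names(out), grep("^(EM|CL)[0-9]+$", names(out), value = TRUE)))
  out[, ord, drop = FALSE]
}

#' Scale repeated measures by the average sample standard deviation
#'
#' Each construct's wave columns are divided by the mean of that
#' construct's wave SDs, so the measures end up with an average
#' within-construct variance near 1 across waves while wave-specific
#' variance ratios are preserved, and are then mean-centred (the model
#' carries no mean structure by default). The scaling constants are stored
#' for exact back-transformation.
#'
#' @param wide data frame or matrix with columns `EM1..EMT, CL1..CLT`
#'   (extra columns become the panel's covariate block).
#' @return A [starts_panel()] with attribute `"scaling"` (a list of the
#'   per-construct average SDs and per-column centres).
#' @seealso [unscale_panel()]
#' @export
scale_by_average_sd <- function(wide) {
  wide <- as.data.frame(wide)
  em <- sort(grep("^EM[0-9]+$", names(wide), value = TRUE))
  cl <- sort(grep("^CL[0-9]+$", names(wide), value = TRUE))
  if (length(em) < 2 || length(cl) < 2)
    stop("need at least 2 waves per construct")
  y <- as.matrix(wide[, c(em, cl)])
  sds <- apply(y, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero or undefined SD in column(s): ",
         paste(names(sds)[!is.finite(sds) | sds == 0], collapse = ", "))
  avg_sd <- c(EM = mean(sds[em]), CL = mean(sds[cl]))
  div <- rep(avg_sd, times = c(length(em), length(cl)))
  ys <- sweep(y, 2, div, "/")
  centers <- colMeans(ys, na.rm = TRUE)
  ys <- sweep(ys, 2, centers)
  rest <- setdiff(names(wide), c(em, cl))
  panel <- starts_panel(ys, covariates = if (length(rest))
    wide[, rest, drop = FALSE] else NULL)
  attr(panel, "scaling") <- list(avg_sd = avg_sd, centers = centers,
                                 wave_sds = sds)
  panel
}

#' Undo average-SD scaling
#'
#' @param panel a panel produced by [scale_by_average_sd()].
#' @return Data frame on the original metric (covariates appended).
#' @export
unscale_panel <- function(panel) {
  sc <- attr(panel, "scaling")
  if (is.null(sc)) stop("panel carries no scaling attribute")
  T_ <- panel$meta$n_waves
  y <- sweep(panel$y, 2, sc$centers, "+")
  div <- rep(sc$avg_sd, each = T_)
  y <- sweep(y, 2, div, "*")
  out <- as.data.frame(y)
  if (!is.null(panel$covariates)) out <- cbind(out, as.data.frame(panel$covariates))
  out
}

#' Descriptive statistics, correlations, and variance inflation factors
#'
#' Pairwise-complete Pearson correlations with two-sided significance
#' stars, per-variable mean, SD and range, and multicollinearity
#' diagnostics for the covariate block: VIF per covariate (the diagonal of
#' the inverted covariate correlation matrix) and the average VIF.
#'
#' @param table data frame of outcome and covariate columns.
#' @param covariate_cols names of the covariate columns for the VIF block
#'   (default: every column not matching `EM<t>` / `CL<t>`).
#' @param vif_cap cap reported for (near-)infinite VIF under perfect
#'   collinearity; such covariates are flagged.
#' @return Object of class `descriptives_report`.
#' @export
descriptives <- function(table, covariate_cols = NULL, vif_cap = 1e6) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  p <- ncol(table); nm <- names(table)
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(nm, grep("^(EM|CL)[0-9]+$", nm, value = TRUE))
  R <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  P <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  N <- matrix(0L, p, p)
  diag(R) <- 1
  for (i in seq_len(p)) for (j in seq_len(i - 1L)) {
    ok <- stats::complete.cases(table[[i]], table[[j]])
    n <- sum(ok)
    N[i, j] <- N[j, i] <- n
    if (n >= 3 && stats::sd(table[[i]][ok]) > 0 && stats::sd(table[[j]][ok]) > 0) {
      r <- stats::cor(table[[i]][ok], table[[j]][ok])
      R[i, j] <- R[j, i] <- r
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      P[i, j] <- P[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  stars <- ifelse(is.na(P), "", ifelse(P < 0.001, "***",
                  ifelse(P < 0.01, "**", ifelse(P < 0.05, "*", ""))))
  vif <- NULL; vif_flag <- NULL
  if (length(covariate_cols) >= 2) {
    Rc <- R[covariate_cols, covariate_cols]
    if (any(is.na(Rc))) {
      vif <- stats::setNames(rep(NA_real_, length(covariate_cols)), covariate_cols)
      vif_flag <- is.na(vif)
    } else {
      inv <- tryCatch(solve(Rc), error = function(e) NULL)
      if (is.null(inv)) {
        vif <- stats::setNames(rep(vif_cap, length(covariate_cols)), covariate_cols)
        vif_flag <- rep(TRUE, length(covariate_cols))
      } else {
        vif <- pmax(diag(inv), 1)
        vif_flag <- vif >= vif_cap
        vif <- pmin(vif, vif_cap)
      }
    }
  }
  structure(list(
    correlations = R, p_values = P, stars = stars, n_pairs = N,
    means = colMeans(as.matrix(table), na.rm = TRUE),
    sds = apply(as.matrix(table), 2, stats::sd, na.rm = TRUE),
    min = suppressWarnings(apply(as.matrix(table), 2, min, na.rm = TRUE)),
    max = suppressWarnings(apply(as.matrix(table), 2, max, na.rm = TRUE)),
    vif = vif, vif_flagged = vif_flag,
    vif_average = if (!is.null(vif)) mean(vif, na.rm = TRUE) else NULL
  ), class = "descriptives_report")
}

#' @export
print.descriptives_report <- function(x, digits = 3, ...) {
  cat("Descriptive statistics\n")
  df <- data.frame(mean = x$means, sd = x$sds, min = x$min, max = x$max)
  print(round(df, digits))
  if (!is.null(x$vif))
    cat(sprintf("Average VIF %.2f (range %.2f-%.2f)\n", x$vif_average,
                min(x$vif, na.rm = TRUE), max(x$vif, na.rm = TRUE)))
  invisible(x)
}

#' Write a descriptives report to CSV + JSON
#'
#' @param report a [descriptives()] result.
#' @param stem file-path stem; writes `<stem>_correlations.csv` and
#'   `<stem>.json`.
#' @export
write_descriptives <- function(report, stem) {
  utils::write.csv(report$correlations, paste0(stem, "_correlations.csv"))
  jsonlite::write_json(list(
    means = as.list(report$means), sds = as.list(report$sds),
    min = as.list(report$min), max = as.list(report$max),
    vif = as.list(report$vif), vif_average = report$vif_average
  ), paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(stem)
}
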