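#' Pearson correlation with t-test
#'
#' Pearson's r with the usual t statistic
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and a two-sided p-value on n - 2 degrees
#' of freedom.  A constant vector has no defined correlation and returns NA
#' with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 3); pairs with missing
#'   values are dropped.
#' @return List with `r`, `n`, `t`, `df`, `p`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, n = n, t = NA_real_, df = n - 2,
                p = NA_real_))
  }
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  if (abs(r) == 1) { t <- sign(r) * Inf; p <- 0 }
  list(r = r, n = n, t = t, df = n - 2, p = p)
}

.stars <- function(p) ifelse(is.na(p), "",
                      ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))

#' Correlation of heterosis with genetic distance and combining ability
#'
#' For every trait, correlates the chosen per-cross heterosis response with
#' four cross-level predictors: molecular genetic distance between the
#' parents, phenotypic genetic distance, the sum of the parents' GCA
#' effects for that trait (the additive prediction of the cross mean), and
#' the SCA effect of the cross for that trait.  Crosses whose parents are
#' missing from a predictor source are excluded with a message.
#'
#' @param h a `"heterosis_table"`.
#' @param gd_mol molecular distance matrix (labels include all parents), or
#'   `NULL` to skip.
#' @param gd_phe phenotypic distance matrix, or `NULL` to skip.
#' @param ca a `"ca_analysis"` (with per-trait fits), or `NULL` to skip the
#'   GCA/SCA predictors.
#' @param response `"mph"`, `"hph"` or `"hi"`.
#' @return A data.frame of class `"cor_report"`: `predictor`, `trait`, `r`,
#'   `n`, `t`, `p`, `stars`.
#' @export
heterosis_correlations <- function(h, gd_mol = NULL, gd_phe = NULL,
                                   ca = NULL,
                                   response = c("mph", "hph", "hi")) {
  response <- match.arg(response)
  traits <- unique(h$trait)
  rows <- list()
  for (tr in traits) {
    d <- h[h$trait == tr, , drop = FALSE]
    y <- d[[response]]
    preds <- list()
    if (!is.null(gd_mol))
      preds$molecular_gd <- .pair_lookup(gd_mol, d$female, d$male)
    if (!is.null(gd_phe))
      preds$phenotypic_gd <- .pair_lookup(gd_phe, d$female, d$male)
    if (!is.null(ca) && tr %in% names(ca$fits)) {
      fit <- ca$fits[[tr]]
      gf <- fit$gca_female[d$female]; gm <- fit$gca_male[d$male]
      preds$gca_sum <- unname(gf + gm)
      preds$sca <- fit$sca[cbind(d$female, d$male)]
    }
    for (pn in names(preds)) {
      x <- preds[[pn]]
      n_drop <- sum(!is.finite(x) & is.finite(y))
      if (n_drop) message("excluding ", n_drop, " cross(es) without ",
                          pn, " for trait ", tr)
      ct <- tryCatch(correlate(x, y), error = function(e)
        list(r = NA_real_, n = sum(is.finite(x) & is.finite(y)),
             t = NA_real_, p = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pn, trait = tr, r = ct$r, n = ct$n, t = ct$t,
        p = ct$p, stars = .stars(ct$p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cor_report", "data.frame")
  out
}

.pair_lookup <- function(d, a, b) {
  out <- rep(NA_real_, length(a))
  ok <- a %in% rownames(d) & b %in% colnames(d)
  out[ok] <- d[cbind(a[ok], b[ok])]
  out
}

#' Genetic-distance-stratified correlation with heterosis
#'
#' Splits the crosses at a genetic-distance threshold and reports the
#' Pearson correlation separately below and above it; used to ask whether
#' distance predicts heterosis only once parents are sufficiently diverged.
#'
#' @param gd per-cross genetic distances.
#' @param het per-cross heterosis values.
#' @param threshold distance cutoff; strata are `gd <= threshold` and
#'   `gd > threshold`.
#' @return List with elements `below` and `above`, each either a
#'   [correlate()] result or `NULL` (undefined: fewer than 3 crosses in the
#'   stratum).
#' @export
stratified_correlation <- function(gd, het, threshold) {
  lo <- gd <= threshold
  run <- function(sel) {
    if (sum(sel, na.rm = TRUE) < 3) return(NULL)
    correlate(gd[sel], het[sel])
  }
  list(below = run(lo), above = run(!lo), threshold = threshold)
}
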