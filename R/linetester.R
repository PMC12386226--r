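#' Fit a line x tester combining-ability model
#'
#' Fits the standard incomplete-diallel (NC II) decomposition to plot-level
#' data: with cell means \eqn{\bar x_{ij}} for female i crossed to male j,
#' \deqn{\bar x_{ij} = \mu + g_i + g_j + s_{ij}}
#' where \eqn{g_i = \bar x_{i.} - \bar x_{..}} (female GCA),
#' \eqn{g_j = \bar x_{.j} - \bar x_{..}} (male GCA) and
#' \eqn{s_{ij} = \bar x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..}}
#' (SCA).  Effects are zero-sum by construction and the decomposition
#' reconstructs every cell mean exactly.
#'
#' With \eqn{r \ge 2} replicates a two-way ANOVA with replication yields
#' variance components
#' \eqn{\sigma^2_e = MS_e}, \eqn{\sigma^2_{SCA} = (MS_{fm} - MS_e)/r},
#' \eqn{\sigma^2_{GCA,f} = (MS_f - MS_{fm})/(mr)},
#' \eqn{\sigma^2_{GCA,m} = (MS_m - MS_{fm})/(fr)}.
#' Negative components are truncated to zero for the percentage and
#' heritability summaries; raw values are retained.  With fully inbred
#' parents the additive and dominance variances are
#' \eqn{\sigma^2_A = c\,\sigma^2_{GCA}} (multiplier `a_mult`, default 2) and
#' \eqn{\sigma^2_D = \sigma^2_{SCA}}, giving narrow- and broad-sense
#' heritabilities
#' \eqn{h^2 = 100\,\sigma^2_A/(\sigma^2_A+\sigma^2_D+\sigma^2_e)} and
#' \eqn{H^2 = 100\,(\sigma^2_A+\sigma^2_D)/(\sigma^2_A+\sigma^2_D+\sigma^2_e)}.
#'
#' @param formula model formula `trait ~ female * male` naming the response
#'   column and the two parent-factor columns of `data`.
#' @param data data.frame of plot values; one row per plot, each (female,
#'   male) cell present with the same number of replicates.
#' @param a_mult multiplier converting GCA variance to additive variance
#'   (2 for fully inbred parents).
#' @param allow_missing if `TRUE`, missing cells are filled with the grand
#'   mean of observed plots (logged); by default a missing cell is an error.
#' @return An object of class `"linetester"` with components `mu`,
#'   `gca_female`, `gca_male`, `sca`, `cell_means`, `anova`, `varcomp`,
#'   `pct` (GCA%/SCA%), `heritability`, `n_female`, `n_male`, `n_rep`,
#'   `trait`, `data`.
#' @seealso [combining_ability()] for the multi-trait wrapper,
#'   [comprehensive_gca()] for the across-trait parent score.
#' @examples
#' plots <- expand.grid(female = paste0("A", 1:3), male = paste0("R", 1:3),
#'                      rep = 1:2)
#' set.seed(1)
#' plots$y <- rnorm(nrow(plots), 50, 2)
#' fit <- linetester(y ~ female * male, plots)
#' coef(fit)$mu
#' @export
linetester <- function(formula, data, a_mult = 2, allow_missing = FALSE) {
  vars <- all.vars(formula)
  if (length(vars) != 3)
    stop("formula must be of the form trait ~ female * male")
  trait <- vars[1]; fcol <- vars[2]; mcol <- vars[3]
  y <- data[[trait]]
  if (!all(is.finite(y))) stop("non-finite trait values")
  f <- factor(data[[fcol]]); m <- factor(data[[mcol]])
  nf <- nlevels(f); nm <- nlevels(m)
  if (nf < 2 || nm < 2) stop("need >= 2 females and >= 2 males")
  counts <- table(f, m)
  if (any(counts == 0)) {
    if (!allow_missing)
      stop("incomplete cross grid: ", sum(counts == 0),
           " missing cell(s); set allow_missing = TRUE to mean-impute")
    message("mean-imputing ", sum(counts == 0), " missing cell(s)")
  }
  if (length(unique(counts[counts > 0])) > 1)
    stop("unbalanced replication across cells")
  r <- max(counts)
  cm <- tapply(y, list(f, m), mean)
  if (any(is.na(cm))) cm[is.na(cm)] <- mean(y)
  mu <- mean(cm)
  gf <- rowMeans(cm) - mu
  gm <- colMeans(cm) - mu
  sca <- sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + mu
  an <- NULL; vc <- NULL; pct <- NULL; herit <- NULL
  if (r >= 2 && all(counts > 0)) {
    fit <- stats::aov(y ~ f * m)
    ss <- summary(fit)[[1]]
    an <- data.frame(
      term = c("female", "male", "female:male", "error"),
      df = ss[["Df"]], sum_sq = ss[["Sum Sq"]], mean_sq = ss[["Mean Sq"]],
      stringsAsFactors = FALSE)
    mse <- an$mean_sq[4]
    an$F <- c((an$mean_sq / mse)[1:3], NA)
    an$p <- c(stats::pf(an$F[1:3], an$df[1:3], an$df[4],
                        lower.tail = FALSE), NA)
    msf <- an$mean_sq[1]; msm <- an$mean_sq[2]; msfm <- an$mean_sq[3]
    vc <- data.frame(
      component = c("gca_female", "gca_male", "sca", "error"),
      raw = c((msf - msfm) / (nm * r), (msm - msfm) / (nf * r),
              (msfm - mse) / r, mse),
      stringsAsFactors = FALSE)
    vc$truncated <- pmax(vc$raw, 0)
    s_gca <- vc$truncated[1] + vc$truncated[2]
    s_sca <- vc$truncated[3]
    s_e <- vc$truncated[4]
    pct <- if (s_gca + s_sca > 0)
      c(gca = 100 * s_gca / (s_gca + s_sca),
        sca = 100 * s_sca / (s_gca + s_sca))
    else c(gca = NA_real_, sca = NA_real_)
    s_a <- a_mult * s_gca; s_d <- s_sca
    tot <- s_a + s_d + s_e
    herit <- if (tot > 0)
      c(narrow = 100 * s_a / tot, broad = 100 * (s_a + s_d) / tot)
    else c(narrow = NA_real_, broad = NA_real_)
  } else if (r < 2) {
    warning("single replicate: error variance inestimable, ",
            "variance components skipped")
  }
  structure(list(mu = mu, gca_female = gf, gca_male = gm, sca = sca,
                 cell_means = cm, anova = an, varcomp = vc, pct = pct,
                 heritability = herit, n_female = nf, n_male = nm,
                 n_rep = r, a_mult = a_mult, trait = trait,
                 cols = c(female = fcol, male = mcol),
                 data = data.frame(y = y, f = f, m = m)),
            class = "linetester")
}

#' @export
print.linetester <- function(x, digits = 3, ...) {
  cat("Line x tester combining-ability fit:", x$trait, "\n")
  cat(sprintf("  %d females x %d males, %d replicate(s); grand mean %.*f\n",
              x$n_female, x$n_male, x$n_rep, digits, x$mu))
  if (!is.null(x$pct))
    cat(sprintf("  GCA%% %.2f / SCA%% %.2f; h2 %.1f%%, H2 %.1f%%\n",
                x$pct["gca"], x$pct["sca"],
                x$heritability["narrow"], x$heritability["broad"]))
  invisible(x)
}

#' @export
coef.linetester <- function(object, ...) {
  list(mu = object$mu, gca_female = object$gca_female,
       gca_male = object$gca_male, sca = object$sca)
}

#' @export
fitted.linetester <- function(object, ...) {
  with(object$data,
       object$cell_means[cbind(as.character(f), as.character(m))])
}

#' @export
residuals.linetester <- function(object, ...) {
  object$data$y - stats::fitted(object)
}

#' @rdname linetester
#' @param object,x a `"linetester"` fit.
#' @param newdata data.frame with the female and male columns used in the
#'   fit; predictions are \eqn{\mu + g_i + g_j + s_{ij}} (the cell mean).
#' @param ... unused.
#' @export
predict.linetester <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object))
  f <- as.character(newdata[[object$cols["female"]]])
  m <- as.character(newdata[[object$cols["male"]]])
  if (any(!f %in% names(object$gca_female)) ||
      any(!m %in% names(object$gca_male)))
    stop("unknown parent in newdata")
  object$cell_means[cbind(f, m)]
}

#' @export
summary.linetester <- function(object, ...) {
  structure(object, class = c("summary.linetester", class(object)))
}

#' @export
print.summary.linetester <- function(x, ...) {
  print.linetester(x)
  if (!is.null(x$anova)) {
    cat("\nANOVA:\n")
    print(x$anova, row.names = FALSE, digits = 4)
    cat("\nVariance components:\n")
    print(x$varcomp, row.names = FALSE, digits = 4)
  }
  cat("\nFemale GCA effects:\n"); print(round(x$gca_female, 3))
  cat("Male GCA effects:\n"); print(round(x$gca_male, 3))
  invisible(x)
}

#' @export
plot.linetester <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  g <- c(x$gca_female, x$gca_male)
  graphics::barplot(g, las = 2, main = paste("GCA effects:", x$trait),
                    col = rep(c("grey40", "grey70"),
                              c(x$n_female, x$n_male)))
  graphics::image(seq_len(x$n_female), seq_len(x$n_male), x$sca,
                  xlab = "female", ylab = "male",
                  main = paste("SCA:", x$trait), axes = FALSE)
  graphics::axis(1, seq_len(x$n_female), rownames(x$sca), las = 2)
  graphics::axis(2, seq_len(x$n_male), colnames(x$sca), las = 2)
  invisible(x)
}

#' @rdname linetester
#' @param nsim number of simulated datasets.
#' @param seed optional seed passed to `set.seed`.
#' @export
simulate.linetester <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sde <- if (!is.null(object$varcomp))
    sqrt(object$varcomp$truncated[4]) else 0
  mu_plot <- stats::fitted(object)
  out <- as.data.frame(replicate(nsim, mu_plot +
                                   stats::rnorm(length(mu_plot), 0, sde)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
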