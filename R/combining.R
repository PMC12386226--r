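#' Combining-ability analysis across traits
#'
#' Fits a [linetester()] model to each trait column of a plot-level
#' phenotype table and collects effects, variance components and
#' heritabilities.
#'
#' @param data plot-level data.frame with female, male and replicate columns
#'   plus one numeric column per trait.
#' @param traits character vector of trait column names; default: all
#'   numeric columns other than the design columns.
#' @param female,male names of the parent columns.
#' @param ... passed to [linetester()] (e.g. `a_mult`, `allow_missing`).
#' @return A list of class `"ca_analysis"`: `fits` (named list of
#'   `"linetester"` objects), `traits`, and matrices `gca_female`,
#'   `gca_male` (parents x traits).
#' @export
combining_ability <- function(data, traits = NULL, female = "female",
                              male = "male", ...) {
  if (is.null(traits)) {
    num <- vapply(data, is.numeric, TRUE)
    traits <- setdiff(names(data)[num], c(female, male, "rep", "replicate"))
  }
  if (length(traits) < 1) stop("no trait columns")
  fits <- lapply(traits, function(tr) {
    fm <- stats::as.formula(paste0("`", tr, "` ~ `", female, "` * `",
                                   male, "`"))
    linetester(fm, data, ...)
  })
  names(fits) <- traits
  gf <- sapply(fits, function(f) f$gca_female)
  gm <- sapply(fits, function(f) f$gca_male)
  structure(list(fits = fits, traits = traits,
                 gca_female = gf, gca_male = gm),
            class = "ca_analysis")
}

#' @export
print.ca_analysis <- function(x, ...) {
  cat("Combining-ability analysis over", length(x$traits), "trait(s):\n ",
      paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Variance-component percentage table across traits
#'
#' One column per trait with GCA%, SCA%, broad- and narrow-sense
#' heritability (all in percent), mirroring the usual genetic-parameter
#' table of diallel studies.
#'
#' @param ca a `"ca_analysis"` object.
#' @return A 4 x traits numeric matrix with rows `gca_pct`, `sca_pct`,
#'   `broad_h2`, `narrow_h2`.
#' @export
variance_table <- function(ca) {
  sapply(ca$fits, function(f) {
    c(gca_pct = unname(f$pct["gca"]), sca_pct = unname(f$pct["sca"]),
      broad_h2 = unname(f$heritability["broad"]),
      narrow_h2 = unname(f$heritability["narrow"]))
  })
}

#' Comprehensive (across-trait) GCA of each parent
#'
#' The default aggregates each parent's per-trait GCA effects after
#' standardizing every trait's GCA vector by its standard deviation, so that
#' traits on different scales contribute equally; `standardize = FALSE`
#' averages raw effects.  A zero-variance trait is skipped under
#' standardization (logged).
#'
#' @param ca a `"ca_analysis"` object (or a parents x traits matrix of GCA
#'   effects).
#' @param weights optional per-trait weights (default equal).
#' @param standardize divide each trait's GCA vector by its sd first.
#' @return Named numeric vector, one comprehensive GCA per parent (females
#'   then males when given a `"ca_analysis"`).
#' @export
comprehensive_gca <- function(ca, weights = NULL, standardize = TRUE) {
  g <- if (inherits(ca, "ca_analysis"))
    rbind(ca$gca_female, ca$gca_male) else as.matrix(ca)
  if (is.null(weights)) weights <- rep(1, ncol(g))
  stopifnot(length(weights) == ncol(g))
  keep <- rep(TRUE, ncol(g))
  if (standardize) {
    s <- apply(g, 2, stats::sd)
    keep <- s > 0
    if (any(!keep))
      message("skipping ", sum(!keep), " zero-variance trait(s)")
    g <- sweep(g[, keep, drop = FALSE], 2, s[keep], "/")
  } else {
    g <- g[, keep, drop = FALSE]
  }
  w <- weights[keep] / sum(weights[keep])
  drop(g %*% w)
}
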