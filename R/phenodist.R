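#' Phenotypic genetic distance between parents
#'
#' Each trait is standardized to mean 0, sd 1 across parents; the distance
#' between two parents is the Euclidean norm of their standardized trait
#' difference.  The result is therefore invariant to any per-trait affine
#' rescaling of the raw measurements.  Zero-variance traits carry no
#' information after standardization and are dropped with a warning.
#'
#' @param profiles data.frame or matrix of parent trait means: either a
#'   matrix with parent row names, or a data.frame whose first column (or a
#'   column named `parent`) holds parent ids and remaining numeric columns
#'   the traits.
#' @param standardize z-score the traits first (default); `FALSE` gives the
#'   plain Euclidean distance on raw trait values.
#' @return Square symmetric labelled distance matrix.
#' @export
phenotypic_distance <- function(profiles, standardize = TRUE) {
  if (is.data.frame(profiles)) {
    idcol <- if ("parent" %in% names(profiles)) "parent"
             else names(profiles)[1]
    ids <- as.character(profiles[[idcol]])
    x <- as.matrix(profiles[setdiff(names(profiles), idcol)])
    rownames(x) <- ids
  } else {
    x <- as.matrix(profiles)
  }
  if (nrow(x) < 2) stop("need >= 2 parents")
  if (ncol(x) < 1) stop("need >= 1 trait")
  if (!all(is.finite(x))) stop("non-finite trait values")
  if (standardize) {
    # population sd, so that two parents at mean +/- sd sit exactly 2 apart
    s <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
    if (any(s == 0)) {
      warning("dropping ", sum(s == 0), " zero-variance trait(s)")
      x <- x[, s > 0, drop = FALSE]
      s <- s[s > 0]
      if (!ncol(x)) stop("all traits zero-variance")
    }
    x <- sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
  }
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}
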