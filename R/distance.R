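#' Identity-by-state (allele-sharing) p-distance
#'
#' For samples i and j the distance is the mean, over loci where both are
#' non-missing, of `|dosage_i - dosage_j| / 2`; it lies in \[0, 1\], is 0 for
#' identical genotypes and 1 for opposite homozygotes at every locus.
#' Missing data are handled by pairwise-complete deletion; a pair sharing no
#' non-missing locus is an error.
#'
#' @param g a `"geno"` object with at least two samples.
#' @return A square symmetric numeric matrix with zero diagonal, labelled by
#'   sample id.
#' @export
ibs_distance <- function(g) {
  d <- g$dosages
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  x <- d / 2
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # sum_k |x_i - x_j| over shared loci; dosage differences take values
  # {0, .5, 1} so |a-b| = a + b - 2*min(a,b); cheaper: loop via crossprod on
  # the three indicator layers
  i0 <- (x0 == 0) & obs
  i1 <- (x0 == 0.5) & obs
  i2 <- (x0 == 1) & obs
  shared <- tcrossprod(obs * 1)
  # |a-b|: 0 vs 2 -> 1 ; 0 vs 1 or 1 vs 2 -> .5
  absdiff <- tcrossprod(i0 * 1, i2 * 1)
  absdiff <- absdiff + t(absdiff)
  half <- tcrossprod(i1 * 1, (i0 | i2) * 1)
  absdiff <- absdiff + 0.5 * (half + t(half))
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(d)[idx[1]], " and ", rownames(d)[idx[2]],
         " share no non-missing locus")
  }
  out <- absdiff / shared
  diag(out) <- 0
  dimnames(out) <- list(rownames(d), rownames(d))
  out
}

.check_distance <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance diagonal must be 0")
  if (any(d < 0)) stop("negative distances")
  invisible(d)
}

#' Write a labelled distance matrix as TSV or PHYLIP
#'
#' @param d square symmetric matrix with dimnames.
#' @param path output path.
#' @param phylip if `TRUE`, write lower-triangle-free full PHYLIP format
#'   (leading line with the number of taxa).
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path, phylip = FALSE) {
  .check_distance(d)
  if (phylip) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(format(nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i],
                         format(d[i, ], digits = 10)), collapse = " "), con)
  } else {
    tab <- data.frame(id = rownames(d), d, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
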