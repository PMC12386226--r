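#' Scan for allele-frequency differentiation between two groups
#'
#' For each locus a 2x2 allele-count table (alt/ref x group) is tested with
#' the continuity-corrected chi-square test, falling back to Fisher's exact
#' test when any observed or expected count is below 5.  Each diploid sample contributes
#' two allele copies; `inbred_haploid = TRUE` halves the counts, treating
#' every fully inbred line as a single independent allele draw.  Loci
#' monomorphic across both groups get p = 1 by convention.
#'
#' No multiple-testing correction is applied by default (flagging uses the
#' raw `alpha`); `fdr = TRUE` adds a Benjamini-Hochberg q-value column.
#'
#' @param g a `"geno"` object.
#' @param groups a `"group_assignment"` or named character vector
#'   sample -> group label; exactly two groups, each with >= 2 samples.
#' @param alpha per-locus significance threshold for the `flagged` column.
#' @param inbred_haploid count one allele copy per sample instead of two.
#' @param fdr also compute BH-adjusted q-values.
#' @return A data.frame of class `"diff_scan"` with one row per locus:
#'   `chrom`, `pos`, `freq_I`, `freq_II`, `p`, `flagged`, `fst` (per-locus
#'   Weir-Cockerham theta), plus attributes `n_flagged`, `frac_flagged`,
#'   `alpha`, `n_monomorphic`.
#' @export
scan_differentiated_loci <- function(g, groups, alpha = 0.01,
                                     inbred_haploid = FALSE, fdr = FALSE) {
  grp <- .group_vector(groups, rownames(g$dosages))
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("exactly two groups required")
  s1 <- names(grp)[grp == lv[1]]; s2 <- names(grp)[grp == lv[2]]
  if (length(s1) < 2 || length(s2) < 2)
    stop("each group needs >= 2 samples")
  d1 <- g$dosages[s1, , drop = FALSE]
  d2 <- g$dosages[s2, , drop = FALSE]
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  alt_full1 <- colSums(d1, na.rm = TRUE)
  alt_full2 <- colSums(d2, na.rm = TRUE)
  alt1 <- alt_full1; alt2 <- alt_full2
  tot1 <- 2 * n1; tot2 <- 2 * n2
  if (inbred_haploid) {
    alt1 <- alt1 / 2; alt2 <- alt2 / 2; tot1 <- n1; tot2 <- n2
  }
  f1 <- ifelse(tot1 > 0, alt1 / tot1, NA_real_)
  f2 <- ifelse(tot2 > 0, alt2 / tot2, NA_real_)
  L <- ncol(g$dosages)
  p <- numeric(L)
  mono <- logical(L)
  for (j in seq_len(L)) {
    tab <- matrix(c(alt1[j], tot1[j] - alt1[j],
                    alt2[j], tot2[j] - alt2[j]), 2, 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {  # monomorphic
      mono[j] <- TRUE; p[j] <- 1; next
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p[j] <- if (any(expd < 5) || any(tab < 5)) {
      stats::fisher.test(round(tab))$p.value
    } else {
      stats::chisq.test(tab, correct = TRUE)$p.value
    }
  }
  if (any(mono))
    message(sum(mono), " monomorphic locus/loci assigned p = 1")
  wc <- .wc_theta(alt_full1, 2 * n1, alt_full2, 2 * n2,
                  h1 = colMeans(d1 == 1, na.rm = TRUE),
                  h2 = colMeans(d2 == 1, na.rm = TRUE))
  out <- data.frame(chrom = g$loci$chrom, pos = g$loci$pos,
                    freq_I = f1, freq_II = f2, p = p,
                    flagged = p < alpha, fst = wc$theta,
                    stringsAsFactors = FALSE)
  if (fdr) out$q <- stats::p.adjust(p, method = "BH")
  attr(out, "n_flagged") <- sum(out$flagged)
  attr(out, "frac_flagged") <- mean(out$flagged)
  attr(out, "alpha") <- alpha
  attr(out, "n_monomorphic") <- sum(mono)
  class(out) <- c("diff_scan", "data.frame")
  out
}

.group_vector <- function(groups, ids) {
  if (inherits(groups, "group_assignment")) groups <- groups$groups
  if (is.null(names(groups)))
    stop("groups must be named by sample id")
  grp <- groups[ids]
  grp <- grp[!is.na(grp)]
  grp
}

# Weir-Cockerham (1984) theta for two populations, from allele counts and
# observed heterozygote frequencies.  alt/tot are per-locus vectors of alt
# copies and total copies; h is the per-locus heterozygote frequency.
.wc_theta <- function(alt1, tot1, alt2, tot2, h1, h2) {
  # sample sizes in individuals (tot are allele copies; /2 unless haploid
  # counting was applied upstream, in which case treat copies as individuals)
  n1 <- tot1 / 2; n2 <- tot2 / 2
  p1 <- ifelse(tot1 > 0, alt1 / tot1, NA_real_)
  p2 <- ifelse(tot2 > 0, alt2 / tot2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom > 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta)
}

#' FST between heterotic groups
#'
#' Two estimators: Weir-Cockerham theta (per-locus components, genome-wide
#' mean by ratio of sums, the standard multilocus average) and Nei's GST =
#' (HT - HS)/HT from unweighted group allele frequencies.  Per-locus WC
#' estimates may be negative; reported per-locus values are clipped to
#' \[0, 1\] in the `fst_clipped` column with the raw value retained.
#'
#' @param g a `"geno"` object.
#' @param groups a `"group_assignment"` or named character vector (two
#'   groups, each >= 2 samples).
#' @param estimator `"weir_cockerham"` or `"nei_gst"`.
#' @param loci optional index of loci to use (e.g. a QTL-region subset).
#' @return A list of class `"fst_estimate"`: `per_locus` (raw), `per_locus_clipped`,
#'   `mean` (ratio-of-sums for WC, mean of per-locus for GST), `estimator`,
#'   `n_loci`.
#' @export
fst_estimate <- function(g, groups,
                         estimator = c("weir_cockerham", "nei_gst"),
                         loci = NULL) {
  estimator <- match.arg(estimator)
  if (!is.null(loci)) g <- subset_geno(g, loci = loci)
  grp <- .group_vector(groups, rownames(g$dosages))
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("exactly two groups required")
  s1 <- names(grp)[grp == lv[1]]; s2 <- names(grp)[grp == lv[2]]
  if (length(s1) < 2 || length(s2) < 2)
    stop("each group needs >= 2 samples")
  d1 <- g$dosages[s1, , drop = FALSE]
  d2 <- g$dosages[s2, , drop = FALSE]
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  alt1 <- colSums(d1, na.rm = TRUE); alt2 <- colSums(d2, na.rm = TRUE)
  p1 <- ifelse(n1 > 0, alt1 / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, alt2 / (2 * n2), NA_real_)
  poly <- !is.na(p1) & !is.na(p2) & (p1 + p2 > 0) & (p1 + p2 < 2)
  if (!any(poly)) stop("all loci monomorphic; FST undefined")
  if (estimator == "weir_cockerham") {
    wc <- .wc_theta(alt1, 2 * n1, alt2, 2 * n2,
                    h1 = colMeans(d1 == 1, na.rm = TRUE),
                    h2 = colMeans(d2 == 1, na.rm = TRUE))
    per <- wc$theta
    mean_fst <- sum(wc$a[poly]) / sum((wc$a + wc$b + wc$c)[poly])
  } else {
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    per <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
    mean_fst <- mean(per[poly])
  }
  structure(list(per_locus = per,
                 per_locus_clipped = pmin(pmax(per, 0), 1),
                 mean = mean_fst, estimator = estimator,
                 n_loci = sum(poly)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("FST (%s): %.4f over %d polymorphic loci\n",
              x$estimator, x$mean, x$n_loci))
  invisible(x)
}
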