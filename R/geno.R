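#' Genotype matrix for a panel of inbred lines
#'
#' Container for samples x loci alternate-allele dosages together with locus
#' coordinates and per-sample line metadata.  Dosage coding is the count of
#' alternate alleles (0, 1, 2; heterozygote = 1 regardless of phase); missing
#' genotypes are `NA`.  Fully inbred lines carry only 0/2.
#'
#' @param dosages integer matrix, samples in rows, loci in columns, values in
#'   \{0, 1, 2, NA\}.  Row names are sample ids, column names locus ids.
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   one row per column of `dosages`.  Positions must be strictly increasing
#'   within a chromosome.
#' @param meta data.frame with columns `sample_id`, `line_type`
#'   (`"sterile"`/`"restorer"`/`"unknown"`) and `cytoplasm`
#'   (`"A1"`/`"A2"`/`"unknown"`).  Missing samples are filled with
#'   `"unknown"`.
#' @return An object of class `"geno"`: a list with elements `dosages`,
#'   `loci`, `meta`.
#' @export
genotype_matrix <- function(dosages, loci = NULL, meta = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample ids in genotype matrix")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(loci)) {
    loci <- data.frame(chrom = "1", pos = seq_len(ncol(dosages)),
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci)
  stopifnot(nrow(loci) == ncol(dosages))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0(loci$chrom, "_", loci$pos)
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  meta <- .complete_meta(meta, rownames(dosages))
  structure(list(dosages = dosages, loci = loci, meta = meta),
            class = "geno")
}

.complete_meta <- function(meta, ids) {
  out <- data.frame(sample_id = ids, line_type = "unknown",
                    cytoplasm = "unknown", stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (anyDuplicated(meta$sample_id))
      stop("duplicate sample id in metadata")
    idx <- match(ids, meta$sample_id)
    if ("line_type" %in% names(meta)) {
      lt <- as.character(meta$line_type[idx])
      bad <- !is.na(lt) & !lt %in% c("sterile", "restorer")
      if (any(bad)) {
        warning("unknown line_type for ", sum(bad),
                " sample(s); set to 'unknown'")
        lt[bad] <- "unknown"
      }
      out$line_type[!is.na(lt)] <- lt[!is.na(lt)]
    }
    if ("cytoplasm" %in% names(meta)) {
      cy <- as.character(meta$cytoplasm[idx])
      cy[!is.na(cy) & !cy %in% c("A1", "A2")] <- "unknown"
      out$cytoplasm[!is.na(cy)] <- cy[!is.na(cy)]
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.geno <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "loci\n")
  cat("  line types:",
      paste(names(table(x$meta$line_type)),
            table(x$meta$line_type), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a `"geno"` object.
#' @param samples character or integer index of samples to keep.
#' @param loci integer or logical index of loci to keep.
#' @return A `"geno"` object.
#' @export
subset_geno <- function(x, samples = NULL, loci = NULL) {
  d <- x$dosages; lo <- x$loci; me <- x$meta
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    me <- me[match(rownames(d), me$sample_id), , drop = FALSE]
    rownames(me) <- NULL
  }
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    lo <- lo[loci, , drop = FALSE]
    rownames(lo) <- NULL
  }
  structure(list(dosages = d, loci = lo, meta = me), class = "geno")
}

#' Read genotypes from VCF or a dosage CSV
#'
#' VCF records that are multiallelic or not simple SNPs are dropped with a
#' message reporting the count.  Dosage is the number of alternate alleles in
#' the GT field; `./.` becomes `NA`.  The CSV layout is samples in rows
#' (first column = sample id) and loci in columns, entries in \{0, 1, 2\} or
#' empty/NA.
#'
#' @param path path to a `.vcf`/`.vcf.gz` file or a CSV dosage matrix.
#' @param metadata optional sample annotation data.frame (see
#'   [genotype_matrix()]).
#' @param format `"auto"` (by extension), `"vcf"` or `"csv"`.
#' @return A `"geno"` object.
#' @export
read_genotypes <- function(path, metadata = NULL,
                           format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (format == "vcf") .read_genotypes_vcf(path, metadata)
  else .read_genotypes_csv(path, metadata)
}

.read_genotypes_vcf <- function(path, metadata) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message("dropped ", n_drop, " non-SNP/multiallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  # count alt alleles in the GT string, phase-agnostic
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  })
  dosages <- t(dos)
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  colnames(dosages) <- paste0(loci$chrom, "_", loci$pos)
  genotype_matrix(dosages, loci, metadata)
}

.read_genotypes_csv <- function(path, metadata) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample id in dosage CSV")
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  loci <- .loci_from_ids(colnames(d))
  genotype_matrix(d, loci, metadata)
}

.loci_from_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3
  if (all(ok)) {
    data.frame(chrom = vapply(m, `[`, "", 2),
               pos = as.integer(vapply(m, `[`, "", 3)),
               ref = "A", alt = "T", stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = "1", pos = seq_along(ids), ref = "A", alt = "T",
               stringsAsFactors = FALSE)
  }
}

#' Write genotypes to a dosage CSV or minimal VCF
#'
#' The CSV round-trips losslessly through [read_genotypes()].  The VCF writer
#' emits an unphased diploid GT-only VCFv4.2 body.
#'
#' @param g a `"geno"` object.
#' @param path output path.
#' @param format `"csv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- data.frame(sample = rownames(g$dosages), g$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT",
                         rownames(g$dosages)), collapse = "\t")), con)
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (j in seq_len(ncol(g$dosages))) {
      d <- g$dosages[, j]
      gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
      writeLines(paste(c(g$loci$chrom[j], g$loci$pos[j],
                         colnames(g$dosages)[j], g$loci$ref[j],
                         g$loci$alt[j], ".", ".", ".", "GT", gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Alternate-allele frequencies per locus
#'
#' Frequency is the alternate-allele count divided by twice the number of
#' non-missing samples at the locus.  A locus entirely missing in the subset
#' gets `NA`.
#'
#' @param g a `"geno"` object.
#' @param samples optional character vector of sample ids (default: all).
#' @return Named numeric vector of frequencies in \[0, 1\] (or `NA`).
#' @export
allele_frequencies <- function(g, samples = NULL) {
  d <- g$dosages
  if (!is.null(samples)) {
    if (length(samples) == 0) stop("empty sample subset")
    d <- d[samples, , drop = FALSE]
  }
  n <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n)
  f[n == 0] <- NA_real_
  f
}
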