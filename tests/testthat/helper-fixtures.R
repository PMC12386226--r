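# shared fixture builders; everything is generated in code

# genotype object straight from a dosage matrix
make_geno <- function(dosages, line_type = NULL) {
  ids <- rownames(dosages)
  if (is.null(ids)) {
    ids <- paste0("S", seq_len(nrow(dosages)))
    rownames(dosages) <- ids
  }
  meta <- if (!is.null(line_type))
    data.frame(sample_id = ids, line_type = line_type,
               cytoplasm = "unknown") else NULL
  genotype_matrix(dosages, meta = meta)
}

# brute-force IBS distance: per-pair mean of |dosage diff|/2 over shared loci
ibs_brute <- function(dos) {
  n <- nrow(dos)
  d <- matrix(0, n, n, dimnames = list(rownames(dos), rownames(dos)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
    d[i, j] <- mean(abs(dos[i, ok] - dos[j, ok]) / 2)
  }
  d
}

# a tiny VCF with 3 samples, 4 SNPs, 1 indel and one ./. genotype
write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tl1\tA\tT\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tl2\tC\tG\t.\t.\t.\tGT\t1/1\t0/0\t./.",
    "1\t300\tl3\tACG\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/0",
    "1\t400\tl4\tG\tA\t.\t.\t.\tGT\t0/1\t0/1\t0/0",
    "2\t100\tl5\tT\tC\t.\t.\t.\tGT\t1/1\t1/1\t0/0")
  writeLines(lines, path)
  path
}

# balanced diallel plot table from a cell-mean matrix (exact, no noise)
diallel_from_cells <- function(cells, r = 2, noise_sd = 0) {
  nf <- nrow(cells); nm <- ncol(cells)
  fem <- rownames(cells); mal <- colnames(cells)
  if (is.null(fem)) fem <- paste0("F", seq_len(nf))
  if (is.null(mal)) mal <- paste0("M", seq_len(nm))
  g <- expand.grid(female = fem, male = mal, rep = seq_len(r),
                   stringsAsFactors = FALSE)
  g$y <- cells[cbind(match(g$female, fem), match(g$male, mal))] +
    rnorm(nrow(g), 0, noise_sd)
  g
}

# random additive tree and its exact leaf-to-leaf distance matrix
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

extdata <- function(f) system.file("extdata", f, package = "sorghet")
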