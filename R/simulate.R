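#' Configuration for the two-group diallel simulator
#'
#' Defaults mirror the desk-scale study design the package is tested
#' against: two differentiated panels of 8 fully inbred parents each
#' (sterile seed parents and restorer pollen parents), 2000 biallelic SNPs
#' at a target FST of 0.3, an 8 x 8 incomplete diallel with 3 replicates,
#' and 10 correlated agronomic traits (GY, PWT, TKW, PL, PH, SD, DF, DM,
#' TL, BIY) sharing one QTL set with trait-specific additive effects and
#' trait-specific directional dominance (positive for yield-type traits,
#' negative for the two phenology traits, so hybrids flower and mature
#' earlier than their parents).
#'
#' @param n_group1,n_group2 parents per panel (group 1 = sterile females,
#'   group 2 = restorer males).
#' @param n_loci number of biallelic SNP loci.
#' @param fst target differentiation between the panels (Balding-Nichols
#'   parameter), in \[0, 1).
#' @param p_anc_range range of the uniform ancestral allele-frequency
#'   distribution.
#' @param n_qtl number of loci (shared across traits) that carry effects.
#' @param a_scale sd of per-QTL additive effects.
#' @param d_ratio named per-trait dominance ratio d/a (sign gives the
#'   direction of dominance); recycled if unnamed scalar.
#' @param sd_plot residual plot-to-plot noise sd.
#' @param n_rep replicates per cross.
#' @param traits trait names.
#' @param baseline per-trait intercept added to genotypic values.
#' @param seed integer seed; identical configs give identical outputs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_group1 = 8, n_group2 = 8, n_loci = 2000,
                       fst = 0.3, p_anc_range = c(0.1, 0.9),
                       n_qtl = 60, a_scale = 1,
                       d_ratio = c(GY = 1.2, PWT = 1, TKW = 0.4, PL = 0.5,
                                   PH = 0.6, SD = 0.2, DF = -0.6,
                                   DM = -0.6, TL = 0.8, BIY = 1.2),
                       sd_plot = 2, n_rep = 3,
                       traits = c("GY", "PWT", "TKW", "PL", "PH", "SD",
                                  "DF", "DM", "TL", "BIY"),
                       baseline = 100, seed = 1) {
  stopifnot(n_group1 >= 1, n_group2 >= 1, n_loci >= 1,
            fst >= 0, fst < 1, n_qtl >= 1, n_rep >= 1, sd_plot >= 0)
  if (n_qtl > n_loci) stop("n_qtl exceeds n_loci")
  if (length(d_ratio) == 1) d_ratio <- rep(d_ratio, length(traits))
  if (is.null(names(d_ratio))) names(d_ratio) <- traits
  d_ratio <- d_ratio[traits]
  if (any(is.na(d_ratio))) stop("d_ratio missing for some traits")
  baseline <- rep(baseline, length.out = length(traits))
  names(baseline) <- traits
  structure(list(n_group1 = n_group1, n_group2 = n_group2,
                 n_loci = n_loci, fst = fst, p_anc_range = p_anc_range,
                 n_qtl = n_qtl, a_scale = a_scale, d_ratio = d_ratio,
                 sd_plot = sd_plot, n_rep = n_rep, traits = traits,
                 baseline = baseline, seed = seed),
            class = "sim_config")
}

#' Simulate two differentiated panels of inbred genotypes
#'
#' Ancestral allele frequencies are uniform on `p_anc_range`; each panel's
#' frequency is drawn from the Balding-Nichols beta distribution with
#' parameter `fst` (for `fst = 0` the panels share the ancestral
#' frequency).  Parents are fully inbred: dosages are 0 or 2, drawn
#' Bernoulli at the panel frequency.
#'
#' @param cfg a `"sim_config"`.
#' @return List: `geno` (a `"geno"` object; samples `A01..` are sterile
#'   females of group I-candidate panel 1, `R01..` restorer males of panel
#'   2) and `truth` (true group labels, per-locus panel frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  p_anc <- stats::runif(L, cfg$p_anc_range[1], cfg$p_anc_range[2])
  draw_freq <- function(p) {
    if (cfg$fst == 0) return(p)
    shape <- (1 - cfg$fst) / cfg$fst
    stats::rbeta(length(p), p * shape, (1 - p) * shape)
  }
  p1 <- draw_freq(p_anc); p2 <- draw_freq(p_anc)
  ids1 <- sprintf("A%02d", seq_len(cfg$n_group1))
  ids2 <- sprintf("R%02d", seq_len(cfg$n_group2))
  d1 <- matrix(2L * stats::rbinom(cfg$n_group1 * L, 1, rep(p1, each = cfg$n_group1)),
               cfg$n_group1, L)
  d2 <- matrix(2L * stats::rbinom(cfg$n_group2 * L, 1, rep(p2, each = cfg$n_group2)),
               cfg$n_group2, L)
  dos <- rbind(d1, d2)
  rownames(dos) <- c(ids1, ids2)
  n_chr <- 10
  chr <- rep(seq_len(n_chr), length.out = L)
  chr <- sort(chr)
  pos <- stats::ave(seq_len(L), chr, FUN = seq_along) * 1000L
  loci <- data.frame(chrom = as.character(chr), pos = pos,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  ord <- order(as.integer(loci$chrom), loci$pos)
  loci <- loci[ord, ]; dos <- dos[, ord, drop = FALSE]
  meta <- data.frame(
    sample_id = c(ids1, ids2),
    line_type = rep(c("sterile", "restorer"),
                    c(cfg$n_group1, cfg$n_group2)),
    cytoplasm = c(sample(c("A1", "A2"), cfg$n_group1, replace = TRUE),
                  rep("unknown", cfg$n_group2)),
    stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, loci, meta)
  truth <- list(group = stats::setNames(
                  rep(c("1", "2"), c(cfg$n_group1, cfg$n_group2)),
                  c(ids1, ids2)),
                p_group1 = p1[ord], p_group2 = p2[ord],
                p_anc = p_anc[ord])
  list(geno = g, truth = truth)
}

#' Simulate diallel phenotypes over a genotype panel
#'
#' Panel-1 samples are the females, panel-2 samples the males.  A shared
#' set of `n_qtl` loci carries, for each trait, additive effects
#' `a ~ N(0, a_scale^2)` and dominance effects `d = d_ratio * |a|` (so the
#' sign of `d_ratio` sets the dominance direction).  A parent's genotypic
#' value is `baseline + sum a * (dosage - 1)`; an F1 adds `d` at every QTL
#' where its parents carry opposite homozygotes.  Plot values add
#' independent `N(0, sd_plot^2)` noise per replicate; parents are scored
#' per se with the same replication and noise.
#'
#' The stored ground truth includes, per trait, the realized GCA-variance
#' share of the noise-free F1 genotypic table: the two-way decomposition of
#' that table gives row/column (GCA) and interaction (SCA) effect sums of
#' squares, and the share is their variance-component analogue
#' `(SSf/(f-1) + SSm/(m-1)) / (SSf/(f-1) + SSm/(m-1) + SSfm/((f-1)(m-1)))`.
#'
#' @param cfg a `"sim_config"`.
#' @param sim result of [simulate_genotypes()] (or `NULL` to generate one).
#' @return List of class `"sim_study"`: `geno`, `pheno` (plot-level F1
#'   data.frame: `female`, `male`, `rep`, traits), `parents` (per-se plot
#'   table: `parent`, `rep`, traits), `truth` (group labels, QTL indices
#'   and effects, true parent additive values, true dominance deviations,
#'   per-trait `gca_share`).
#' @export
simulate_diallel <- function(cfg, sim = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sim)) sim <- simulate_genotypes(cfg)
  set.seed(cfg$seed + 1L)
  g <- sim$geno; truth <- sim$truth
  females <- names(truth$group)[truth$group == "1"]
  males <- names(truth$group)[truth$group == "2"]
  qtl <- sort(sample.int(ncol(g$dosages), cfg$n_qtl))
  K <- length(cfg$traits)
  a_eff <- matrix(stats::rnorm(cfg$n_qtl * K, 0, cfg$a_scale),
                  cfg$n_qtl, K, dimnames = list(NULL, cfg$traits))
  d_eff <- sweep(abs(a_eff), 2, cfg$d_ratio, "*")
  X <- g$dosages[, qtl, drop = FALSE] - 1  # -1 / +1 for inbreds
  add_val <- X %*% a_eff                    # parents x traits
  f_idx <- match(females, rownames(X)); m_idx <- match(males, rownames(X))
  nf <- length(females); nm <- length(males)
  # F1 genotypic values
  G <- array(0, c(nf, nm, K), dimnames = list(females, males, cfg$traits))
  for (i in seq_len(nf)) for (j in seq_len(nm)) {
    xi <- X[f_idx[i], ]; xj <- X[m_idx[j], ]
    hij <- as.numeric(xi != xj)           # opposite homozygotes -> het F1
    G[i, j, ] <- cfg$baseline + ((xi + xj) / 2) %*% a_eff + hij %*% d_eff
  }
  # decompose noise-free table per trait for the true GCA share and
  # dominance deviations
  gca_share <- numeric(K); names(gca_share) <- cfg$traits
  dom_dev <- array(0, c(nf, nm, K), dimnames = dimnames(G))
  for (k in seq_len(K)) {
    M <- G[, , k]
    gf <- rowMeans(M) - mean(M); gm <- colMeans(M) - mean(M)
    s <- sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
    dom_dev[, , k] <- s
    vg <- sum(gf^2) / (nf - 1) + sum(gm^2) / (nm - 1)
    vs <- sum(s^2) / ((nf - 1) * (nm - 1))
    gca_share[k] <- vg / (vg + vs)
  }
  # plot-level tables
  grid <- expand.grid(female = females, male = males,
                      rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  pheno <- grid
  for (k in seq_len(K)) {
    mu <- G[cbind(match(grid$female, females), match(grid$male, males),
                  k)]
    pheno[[cfg$traits[k]]] <- mu + stats::rnorm(nrow(grid), 0, cfg$sd_plot)
  }
  pgrid <- expand.grid(parent = c(females, males),
                       rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pv <- sweep(add_val[match(pgrid$parent, rownames(add_val)), , drop = FALSE],
              2, cfg$baseline, "+")
  parents <- pgrid
  for (k in seq_len(K))
    parents[[cfg$traits[k]]] <- pv[, k] +
      stats::rnorm(nrow(pgrid), 0, cfg$sd_plot)
  truth$qtl <- qtl
  truth$a_eff <- a_eff
  truth$d_eff <- d_eff
  truth$parent_additive <- add_val
  truth$dominance_dev <- dom_dev
  truth$gca_share <- gca_share
  truth$f1_genotypic <- G
  structure(list(geno = g, pheno = pheno, parents = parents,
                 truth = truth, config = cfg),
            class = "sim_study")
}

#' One-call simulation of genotypes plus diallel phenotypes
#'
#' @param cfg a `"sim_config"` (default [sim_config()] defaults).
#' @return A `"sim_study"` list; see [simulate_diallel()].
#' @export
simulate_study <- function(cfg = sim_config()) {
  simulate_diallel(cfg, simulate_genotypes(cfg))
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated study: %d + %d inbred parents, %d loci (target FST %.2f),\n",
              cfg$n_group1, cfg$n_group2, cfg$n_loci, cfg$fst))
  cat(sprintf("  %d x %d diallel, %d rep(s), %d trait(s)\n",
              cfg$n_group1, cfg$n_group2, cfg$n_rep, length(cfg$traits)))
  invisible(x)
}
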