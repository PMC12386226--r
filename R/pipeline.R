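#' Configuration for a full pipeline run
#'
#' Collects file paths and analysis settings for [run_pipeline()].  All
#' referenced input files must exist; outputs are written under `out_dir`
#' and never overwritten unless `force = TRUE`.
#'
#' @param genotypes path to a VCF or dosage CSV.
#' @param phenotypes path to the plot-level F1 phenotype CSV (`female`,
#'   `male`, `rep`, trait columns).
#' @param parent_values path to the parent per-se CSV (`parent`, `rep`,
#'   trait columns).
#' @param metadata optional path to a sample-annotation CSV (`sample_id`,
#'   `line_type`, `cytoplasm`).
#' @param out_dir output directory.
#' @param check_value check trait value(s) for the heterosis index (or
#'   `NULL` to use `check_cross`).
#' @param check_cross length-2 `c(female, male)` naming the check cross.
#' @param k_groups number of heterotic groups to cut.
#' @param alpha significance threshold for the differentiation scan.
#' @param estimator FST estimator (`"weir_cockerham"` or `"nei_gst"`).
#' @param gd_threshold distance cutoff for the stratified correlation.
#' @param response heterosis response for correlations (`"mph"`, `"hph"`,
#'   `"hi"`).
#' @param bootstrap_reps NJ bootstrap replicates (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @param force overwrite existing outputs.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(genotypes, phenotypes, parent_values,
                       metadata = NULL, out_dir = "sorghet_out",
                       check_value = NULL, check_cross = NULL,
                       k_groups = 2, alpha = 0.01,
                       estimator = "weir_cockerham",
                       gd_threshold = NULL,
                       response = "mph", bootstrap_reps = 0, seed = 1,
                       force = FALSE) {
  for (p in c(genotypes, phenotypes, parent_values, metadata))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 parent_values = parent_values, metadata = metadata,
                 out_dir = out_dir, check_value = check_value,
                 check_cross = check_cross, k_groups = k_groups,
                 alpha = alpha, estimator = estimator,
                 gd_threshold = gd_threshold, response = response,
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 force = force),
            class = "run_config")
}

#' Run the full heterosis-analysis pipeline
#'
#' Executes distance -> tree -> groups -> differentiation scan -> combining
#' ability -> heterosis -> correlations and writes the report bundle:
#' ranked strong/weak combinations, variance-component percentages, GCA
#' effects with the comprehensive GCA, phenotypic distances, and the
#' distance/combining-ability correlation grids, plus the newick tree, the
#' group assignment, the per-locus scan and a run log.  Trait columns are
#' emitted under their input names (conventionally the abbreviations GY,
#' PWT, TKW, PL, PH, SD, DF, DM, TL, BIY).
#'
#' @param cfg a `"run_config"`.
#' @return Invisibly, a list with every intermediate result (`geno`,
#'   `distance`, `tree`, `groups`, `scan`, `fst`, `ca`, `heterosis`,
#'   `ranking`, `pgd`, `correlations`, `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(cfg$out_dir) &&
      length(list.files(cfg$out_dir)) && !cfg$force)
    stop("output directory not empty (use force = TRUE): ", cfg$out_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(paste("sorghet", as.character(utils::packageVersion("sorghet"))),
           paste("R", getRversion()), paste("seed", cfg$seed),
           paste("date", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  meta <- if (!is.null(cfg$metadata))
    utils::read.csv(cfg$metadata, stringsAsFactors = FALSE) else NULL
  geno <- read_genotypes(cfg$genotypes, metadata = meta)
  pheno <- utils::read.csv(cfg$phenotypes, stringsAsFactors = FALSE)
  parents <- utils::read.csv(cfg$parent_values, stringsAsFactors = FALSE)
  traits <- setdiff(intersect(names(pheno), names(parents)),
                    c("female", "male", "parent", "rep", "replicate"))

  d <- ibs_distance(geno)
  tree <- if (cfg$bootstrap_reps > 0)
    bootstrap_support(geno, cfg$bootstrap_reps, seed = cfg$seed)
  else nj_tree(d)
  groups <- assign_groups(tree, k = cfg$k_groups, meta = geno$meta)
  scan <- scan_differentiated_loci(geno, groups, alpha = cfg$alpha)
  fst <- fst_estimate(geno, groups, estimator = cfg$estimator)
  log <- c(log,
           sprintf("flagged %d/%d loci (%.1f%%) at alpha %g",
                   attr(scan, "n_flagged"), nrow(scan),
                   100 * attr(scan, "frac_flagged"), cfg$alpha),
           sprintf("mean FST (%s) %.4f", fst$estimator, fst$mean))

  ca <- combining_ability(pheno, traits)
  cg <- comprehensive_gca(ca)
  het <- heterosis_table(pheno, parents, traits,
                         check_value = cfg$check_value,
                         check_cross = cfg$check_cross)
  rank_trait <- traits[1]
  n_cross <- nrow(unique(pheno[c("female", "male")]))
  n_pick <- min(10, n_cross %/% 2)
  ranking <- rank_crosses(het, rank_trait, top_n = n_pick,
                          bottom_n = n_pick, groups = groups)
  pmeans <- stats::aggregate(parents[traits], list(parent = parents$parent), mean)
  pgd <- phenotypic_distance(pmeans)
  cors <- heterosis_correlations(het, gd_mol = d, gd_phe = pgd, ca = ca,
                                 response = cfg$response)
  strat <- NULL
  if (!is.null(cfg$gd_threshold)) {
    hh <- het[het$trait == rank_trait, ]
    strat <- stratified_correlation(.pair_lookup(d, hh$female, hh$male),
                                    hh[[cfg$response]], cfg$gd_threshold)
  }

  out <- function(f) file.path(cfg$out_dir, f)
  wtsv <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                            row.names = FALSE,
                                            quote = FALSE)
  wtsv(ranking, "strong_weak_combinations.tsv")
  vt <- variance_table(ca)
  wtsv(data.frame(parameter = rownames(vt), vt, check.names = FALSE),
       "variance_components.tsv")
  gca_tab <- rbind(ca$gca_female, ca$gca_male)
  wtsv(data.frame(parent = rownames(gca_tab), gca_tab,
                  comprehensive_gca = cg[rownames(gca_tab)],
                  check.names = FALSE),
       "gca_effects.tsv")
  write_distance(pgd, out("phenotypic_distance.tsv"))
  wtsv(cors[cors$predictor %in% c("molecular_gd", "phenotypic_gd"), ],
       "distance_correlations.tsv")
  wtsv(cors[cors$predictor %in% c("gca_sum", "sca"), ],
       "combining_ability_correlations.tsv")
  write_distance(d, out("molecular_distance.tsv"))
  write_tree_newick(tree, out("tree.nwk"))
  wtsv(data.frame(sample = names(groups$groups), group = groups$groups),
       "groups.tsv")
  wtsv(scan, "differentiation_scan.tsv")
  writeLines(log, out("run.log"))
  invisible(list(geno = geno, distance = d, tree = tree, groups = groups,
                 scan = scan, fst = fst, ca = ca,
                 comprehensive_gca = cg, heterosis = het,
                 ranking = ranking, pgd = pgd, correlations = cors,
                 stratified = strat,
                 files = list.files(cfg$out_dir, full.names = TRUE)))
}
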