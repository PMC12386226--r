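test_that("NJ solves the 3-taxon branch lengths exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- tr$edge.length[match(1:3, tr$edge[, 2])]
  names(len) <- tr$tip.label
  expect_equal(len, c(A = 1, B = 1, C = 3))
  # ultrametric equidistant case
  du <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(du) <- 0
  tru <- nj_tree(du)
  expect_equal(unname(tru$edge.length[match(1:3, tru$edge[, 2])]),
               c(1, 1, 1))
})

test_that("NJ recovers the generating additive tree (4 taxa, fixed)", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("NJ is exact on additive distances (random 5-8 leaf trees)", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(5:8, 1)
    at <- random_additive_tree(n)
    tr <- nj_tree(at$dist)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(at$tree), tr)), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(at$dist),
                                           colnames(at$dist)],
                 at$dist, tolerance = 1e-8)
  }
})

test_that("newick round-trips topology and lengths", {
  at <- random_additive_tree(6)
  tr <- nj_tree(at$dist)
  f <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
})

test_that("group cutting recovers the simulated two-group structure", {
  agree <- vapply(1:20, function(s) {
    sg <- simulate_genotypes(sim_config(n_loci = 300, fst = 0.3, seed = s))
    tr <- nj_tree(ibs_distance(sg$geno))
    ga <- assign_groups(tr, 2, meta = sg$geno$meta)
    truth <- sg$truth$group[names(ga$groups)]
    # best label matching
    max(sum((ga$groups == "I") == (truth == "1")),
        sum((ga$groups == "I") == (truth == "2")))
  }, 0)
  expect_true(all(agree >= 15))
  expect_gte(mean(agree == 16), 0.9)
})

test_that("group I is the restorer-rich side and composition sums match", {
  sg <- simulate_genotypes(sim_config(n_loci = 300, fst = 0.4, seed = 5))
  tr <- nj_tree(ibs_distance(sg$geno))
  ga <- assign_groups(tr, 2, meta = sg$geno$meta)
  frac <- tapply(sg$geno$meta$line_type[
    match(names(ga$groups), sg$geno$meta$sample_id)] == "restorer",
    ga$groups, mean)
  expect_gte(frac["I"], frac["II"])
  expect_equal(sum(ga$composition), length(ga$groups))
  expect_equal(as.vector(rowSums(ga$composition)),
               as.vector(table(ga$groups)))
})

test_that("group cutting validates k and breaks ties deterministically", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_error(assign_groups(tr, k = 10), "larger than")
  ga1 <- assign_groups(tr, 2)
  ga2 <- assign_groups(tr, 2)
  expect_identical(ga1$groups, ga2$groups)  # deterministic under ties
  expect_setequal(unique(ga1$groups), c("I", "II"))
  # with no metadata and equal sizes, the component holding the smallest
  # label is II
  expect_equal(unname(ga1$groups["a"]), "II")
})

test_that("bootstrap supports behave: n_reps=1 gives 0/100, seeded runs repeat", {
  sg <- simulate_genotypes(sim_config(n_group1 = 4, n_group2 = 4,
                                      n_loci = 120, fst = 0.5, seed = 9))
  t1 <- bootstrap_support(sg$geno, n_reps = 1, seed = 1)
  expect_true(all(t1$node.label[-1] %in% c(0, 100)))
  t2 <- bootstrap_support(sg$geno, n_reps = 20, seed = 4)
  t3 <- bootstrap_support(sg$geno, n_reps = 20, seed = 4)
  expect_identical(t2$node.label, t3$node.label)
})

test_that("the group-splitting edge gets high support on separated panels", {
  sg <- simulate_genotypes(sim_config(n_loci = 500, fst = 0.5, seed = 7))
  tr <- bootstrap_support(sg$geno, n_reps = 100, seed = 7)
  grp1 <- names(sg$truth$group)[sg$truth$group == "1"]
  bp <- ape::prop.part(tr)
  hit <- vapply(seq_along(bp), function(i) {
    s <- tr$tip.label[bp[[i]]]
    setequal(s, grp1) || setequal(s, setdiff(tr$tip.label, grp1))
  }, TRUE)
  expect_true(any(hit))
  expect_gte(min(tr$node.label[hit], na.rm = TRUE), 95)
})

test_that("subgroup splitting relabels one group's members only", {
  sg <- simulate_genotypes(sim_config(n_group1 = 6, n_group2 = 6,
                                      n_loci = 300, fst = 0.4, seed = 3))
  tr <- nj_tree(ibs_distance(sg$geno))
  ga <- assign_groups(tr, 2, meta = sg$geno$meta)
  sub <- assign_subgroups(tr, ga, group = "I", k_sub = 2)
  expect_setequal(names(sub), names(ga$groups)[ga$groups == "I"])
  expect_true(all(grepl("^I-[0-9]+$", sub)))
})
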