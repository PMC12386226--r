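grp2 <- function(ids1, ids2) {
  stats::setNames(rep(c("I", "II"), c(length(ids1), length(ids2))),
                  c(ids1, ids2))
}

test_that("no loci are flagged when group frequencies are identical", {
  set.seed(41)
  half <- matrix(sample(c(0L, 2L), 5 * 40, replace = TRUE), 5, 40,
                 dimnames = list(paste0("a", 1:5), NULL))
  dos <- rbind(half, half)  # second group duplicates the first
  rownames(dos) <- c(paste0("a", 1:5), paste0("b", 1:5))
  g <- make_geno(dos)
  sc <- suppressMessages(
    scan_differentiated_loci(g, grp2(paste0("a", 1:5), paste0("b", 1:5)),
                             alpha = 0.5))
  expect_equal(attr(sc, "n_flagged"), 0L)
  expect_true(all(sc$p >= 0 & sc$p <= 1))
})

test_that("a fixed difference in 10 vs 10 inbreds hits the Fisher closed form", {
  dos <- rbind(matrix(2L, 10, 1), matrix(0L, 10, 1))
  rownames(dos) <- c(paste0("a", 1:10), paste0("b", 1:10))
  dos <- cbind(dos, dos[, 1])  # second locus so the object has >1 locus
  g <- make_geno(dos)
  sc <- scan_differentiated_loci(g, grp2(paste0("a", 1:10), paste0("b", 1:10)))
  # allele table 20/0 vs 0/20: two-sided exact p = 2 / C(40,20)
  expect_equal(sc$p[1], 2 / choose(40, 20), tolerance = 1e-10)
  expect_true(all(sc$flagged))
  # haploid coding halves the counts: p = 2 / C(20,10)
  sch <- scan_differentiated_loci(g, grp2(paste0("a", 1:10), paste0("b", 1:10)),
                                  inbred_haploid = TRUE)
  expect_equal(sch$p[1], 2 / choose(20, 10), tolerance = 1e-10)
})

test_that("flagged fraction tracks the simulated differentiated fraction", {
  set.seed(42)
  n <- 10; L <- 2000; n_diff <- 600
  p1 <- c(rep(0.02, n_diff), rep(0.5, L - n_diff))
  p2 <- c(rep(0.98, n_diff), rep(0.5, L - n_diff))
  draw <- function(p, ids) {
    m <- matrix(2L * rbinom(n * L, 1, rep(p, each = n)), n, L)
    rownames(m) <- ids; m
  }
  dos <- rbind(draw(p1, paste0("a", 1:n)), draw(p2, paste0("b", 1:n)))
  g <- make_geno(dos)
  sc <- suppressMessages(
    scan_differentiated_loci(g, grp2(paste0("a", 1:n), paste0("b", 1:n)),
                             alpha = 0.01))
  expect_lt(abs(attr(sc, "frac_flagged") - 0.30), 0.05 + 0.01)
  # monotone in alpha
  sc2 <- suppressMessages(
    scan_differentiated_loci(g, grp2(paste0("a", 1:n), paste0("b", 1:n)),
                             alpha = 0.05))
  expect_gte(attr(sc2, "n_flagged"), attr(sc, "n_flagged"))
})

test_that("monomorphic loci get p = 1 with a message", {
  dos <- cbind(matrix(0L, 8, 2), matrix(c(rep(2L, 4), rep(0L, 4)), 8, 1))
  rownames(dos) <- paste0("s", 1:8)
  g <- make_geno(dos)
  expect_message(
    sc <- scan_differentiated_loci(g, grp2(paste0("s", 1:4), paste0("s", 5:8))),
    "monomorphic")
  expect_equal(sc$p[1:2], c(1, 1))
})

test_that("GST matches the closed-form frequency arithmetic", {
  # build inbred panels with exact realized frequencies
  panel <- function(p, n, ids) {
    k <- round(p * n)
    m <- matrix(rep(c(2L, 0L), c(k, n - k)), n, 1)
    rownames(m) <- ids; m
  }
  mk <- function(p1, p2) {
    dos <- rbind(panel(p1, 10, paste0("a", 1:10)),
                 panel(p2, 10, paste0("b", 1:10)))
    make_geno(cbind(dos, dos))
  }
  gr <- grp2(paste0("a", 1:10), paste0("b", 1:10))
  expect_equal(fst_estimate(mk(0.2, 0.8), gr, "nei_gst")$mean, 0.36)
  expect_equal(fst_estimate(mk(0, 1), gr, "nei_gst")$mean, 1)
  g_eq <- mk(0.5, 0.5)
  expect_equal(fst_estimate(g_eq, gr, "nei_gst")$mean, 0)
  expect_error(fst_estimate(mk(0, 0), gr, "nei_gst"), "monomorphic")
})

test_that("GST stays in [0,1] and WC theta recovers the simulated FST", {
  means <- vapply(1:20, function(s) {
    sg <- simulate_genotypes(sim_config(n_group1 = 16, n_group2 = 16,
                                        n_loci = 2000, fst = 0.3, seed = s))
    gr <- stats::setNames(ifelse(sg$truth$group == "1", "I", "II"),
                          names(sg$truth$group))
    gst <- fst_estimate(sg$geno, gr, "nei_gst")
    expect_true(all(gst$per_locus >= 0 & gst$per_locus <= 1, na.rm = TRUE))
    fst_estimate(sg$geno, gr, "weir_cockerham")$mean
  }, 0)
  expect_true(all(abs(means - 0.30) <= 0.05))
})

test_that("null panels give near-zero WC FST", {
  means <- vapply(1:20, function(s) {
    sg <- simulate_genotypes(sim_config(n_group1 = 16, n_group2 = 16,
                                        n_loci = 2000, fst = 0, seed = s))
    gr <- stats::setNames(ifelse(sg$truth$group == "1", "I", "II"),
                          names(sg$truth$group))
    fst_estimate(sg$geno, gr)$mean
  }, 0)
  expect_true(all(abs(means) <= 0.02))
})

test_that("FST on a loci subset supports region comparisons", {
  sg <- simulate_genotypes(sim_config(n_loci = 400, fst = 0.3, seed = 2))
  gr <- stats::setNames(ifelse(sg$truth$group == "1", "I", "II"),
                        names(sg$truth$group))
  whole <- fst_estimate(sg$geno, gr)
  sub <- fst_estimate(sg$geno, gr, loci = 1:100)
  expect_lte(sub$n_loci, 100)
  expect_true(is.finite(sub$mean))
  expect_true(is.finite(whole$mean))
})
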