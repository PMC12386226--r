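test_that("effects match the hand-worked 2x2 decompositions", {
  cells <- matrix(c(10, 14, 12, 16), 2, 2,
                  dimnames = list(c("F1", "F2"), c("M1", "M2")))
  fit <- linetester(y ~ female * male, diallel_from_cells(cells, r = 2))
  expect_equal(fit$mu, 13)
  expect_equal(unname(fit$gca_female), c(-2, 2))
  expect_equal(unname(fit$gca_male), c(-1, 1))
  expect_equal(max(abs(fit$sca)), 0)

  cells2 <- matrix(c(10, 14, 14, 10), 2, 2,
                   dimnames = list(c("F1", "F2"), c("M1", "M2")))
  fit2 <- linetester(y ~ female * male, diallel_from_cells(cells2, r = 2))
  expect_equal(unname(fit2$gca_female), c(0, 0))
  expect_equal(unname(fit2$gca_male), c(0, 0))
  expect_equal(unname(fit2$sca),
               matrix(c(-2, 2, 2, -2), 2, 2))
})

test_that("zero-sum and exact reconstruction identities hold on random data", {
  set.seed(51)
  for (k in 1:10) {
    nf <- sample(3:8, 1); nm <- sample(3:8, 1); r <- sample(2:3, 1)
    cells <- matrix(rnorm(nf * nm, 50, 10), nf, nm)
    d <- diallel_from_cells(cells, r = r, noise_sd = 2)
    fit <- linetester(y ~ female * male, d)
    expect_lt(abs(sum(fit$gca_female)), 1e-9)
    expect_lt(abs(sum(fit$gca_male)), 1e-9)
    expect_lt(max(abs(rowSums(fit$sca))), 1e-9)
    expect_lt(max(abs(colSums(fit$sca))), 1e-9)
    recon <- fit$mu + outer(fit$gca_female, fit$gca_male, "+") + fit$sca
    expect_equal(unname(recon), unname(fit$cell_means), tolerance = 1e-9)
    # ANOVA sums of squares are additive
    ss <- fit$anova$sum_sq
    tot <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(ss), tot, tolerance = 1e-6 * tot)
    # GCA% + SCA% = 100 when both non-negative
    if (all(fit$varcomp$raw[1:3] >= 0))
      expect_equal(sum(fit$pct), 100)
  }
})

test_that("replication-free and degenerate inputs are handled", {
  cells <- matrix(c(10, 14, 12, 16), 2, 2,
                  dimnames = list(c("F1", "F2"), c("M1", "M2")))
  expect_warning(fit1 <- linetester(y ~ female * male,
                                    diallel_from_cells(cells, r = 1)),
                 "single replicate")
  expect_null(fit1$varcomp)
  expect_equal(fit1$mu, 13)
  # zero noise across reps: sigma2_e = 0 and exact reconstruction
  d <- diallel_from_cells(cells, r = 3, noise_sd = 0)
  fit <- linetester(y ~ female * male, d)
  expect_equal(fit$varcomp$raw[4], 0)
  expect_equal(unname(residuals(fit)), rep(0, nrow(d)))
  # missing cell: error unless mean imputation requested
  dm <- d[!(d$female == "F1" & d$male == "M1"), ]
  expect_error(linetester(y ~ female * male, dm), "incomplete cross grid")
  expect_message(linetester(y ~ female * male, dm, allow_missing = TRUE),
                 "mean-imputing")
})

test_that("purely additive simulated traits give GCA% >= 95", {
  shares <- vapply(1:20, function(s) {
    cfg <- sim_config(n_loci = 300, n_qtl = 40, d_ratio = c(GY = 0),
                      traits = "GY", sd_plot = 0.5, seed = s)
    st <- simulate_study(cfg)
    fit <- linetester(GY ~ female * male, st$pheno)
    unname(fit$pct["gca"])
  }, 0)
  expect_true(all(shares >= 95))
})

test_that("purely non-additive (balanced dominance) traits give SCA% >= 95", {
  set.seed(52)
  for (s in 1:20) {
    # 8+8 inbreds, every QTL carried by exactly half of each panel: the
    # dominance architecture then generates no GCA variation
    nq <- 30
    pick <- function() {
      m <- replicate(nq, sample(rep(c(1, -1), 4)))
      rownames(m) <- NULL; m
    }
    Xf <- pick(); Xm <- pick()
    dvals <- abs(rnorm(nq, 1, 0.2))
    females <- paste0("F", 1:8); males <- paste0("M", 1:8)
    G <- matrix(0, 8, 8, dimnames = list(females, males))
    for (i in 1:8) for (j in 1:8)
      G[i, j] <- 100 + sum(dvals * (Xf[i, ] != Xm[j, ]))
    d <- diallel_from_cells(G, r = 3, noise_sd = 0.2)
    fit <- linetester(y ~ female * male, d)
    expect_gte(unname(fit$pct["sca"]), 95)
  }
})

test_that("estimated GCA share recovers the simulator's ground truth", {
  errs <- unlist(lapply(1:50, function(s) {
    ratio <- c(0.3, 1, 3)[(s %% 3) + 1]  # spans high/mid/low GCA shares
    cfg <- sim_config(n_loci = 300, n_qtl = 40,
                      d_ratio = c(GY = ratio), traits = "GY",
                      sd_plot = 1, seed = s)
    st <- simulate_study(cfg)
    fit <- linetester(GY ~ female * male, st$pheno)
    unname(fit$pct["gca"]) / 100 - unname(st$truth$gca_share["GY"])
  }))
  expect_lt(mean(abs(errs)), 0.1)
})

test_that("model methods: coef, predict, fitted, simulate", {
  cells <- matrix(c(10, 14, 12, 16), 2, 2,
                  dimnames = list(c("F1", "F2"), c("M1", "M2")))
  d <- diallel_from_cells(cells, r = 2, noise_sd = 0)
  fit <- linetester(y ~ female * male, d)
  co <- coef(fit)
  expect_named(co, c("mu", "gca_female", "gca_male", "sca"))
  nd <- data.frame(female = "F2", male = "M1")
  expect_equal(unname(predict(fit, nd)), 14)
  expect_error(predict(fit, data.frame(female = "F9", male = "M1")),
               "unknown parent")
  expect_equal(stats::fitted(fit), d$y)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 2L))
})

test_that("comprehensive GCA: identity, cancellation and rank recovery", {
  g1 <- matrix(c(1, -2, 1), 3, 1, dimnames = list(c("a", "b", "c"), "t1"))
  expect_equal(comprehensive_gca(g1, standardize = FALSE),
               c(a = 1, b = -2, c = 1))
  g2 <- cbind(t1 = c(a = 1, b = -2, c = 1), t2 = c(-1, 2, -1))
  expect_equal(unname(comprehensive_gca(g2)), c(0, 0, 0))
  # zero-variance trait skipped under standardization
  g3 <- cbind(g2, t3 = c(5, 5, 5))
  expect_message(cg <- comprehensive_gca(g3), "zero-variance")
  expect_equal(unname(cg), c(0, 0, 0))
  # ranking matches true additive values on low-noise simulations
  # GCA effects are centred within each panel, so ranking is compared
  # within the 8 females and the 8 males separately
  rhos <- vapply(1:20, function(s) {
    cfg <- sim_config(n_loci = 300, n_qtl = 40, d_ratio = c(GY = 0),
                      traits = "GY", sd_plot = 0.2, seed = s)
    st <- simulate_study(cfg)
    ca <- combining_ability(st$pheno)
    cg <- comprehensive_gca(ca, standardize = FALSE)
    truth <- st$truth$parent_additive[names(cg), "GY"]
    fem <- names(ca$fits$GY$gca_female)
    mal <- names(ca$fits$GY$gca_male)
    min(stats::cor(cg[fem], truth[fem], method = "spearman"),
        stats::cor(cg[mal], truth[mal], method = "spearman"))
  }, 0)
  expect_true(all(rhos >= 0.9))
})
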