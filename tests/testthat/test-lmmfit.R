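test_that("heritability formula behaves and reproduces worked examples", {
  expect_equal(round(heritability(477.94, 396.11, 2), 2), 0.71)
  expect_equal(heritability(10, 0, 2), 1)
  # monotone in sigma_g2 and in replication
  h <- vapply(c(1, 5, 25), heritability, 0, sigma_e2 = 10, n_rep = 2)
  expect_true(all(diff(h) > 0))
  hr <- vapply(1:4, function(r) heritability(5, 10, r), 0)
  expect_true(all(diff(hr) > 0))
  expect_true(all(h >= 0 & h <= 1))
  expect_error(heritability(0, 0), "undefined")
})

test_that("REML matches closed-form ANOVA estimators on a balanced one-way design", {
  withr::with_seed(11, {
    n_g <- 30; r <- 4
    g <- rnorm(n_g, 0, 2)
    dat <- data.frame(
      replicate = 1, row = 1, column = 1,
      entry_id = rep(sprintf("G%02d", 1:n_g), each = r),
      population_class = "clone",
      y = rep(g, each = r) + rnorm(n_g * r, 0, 1.5)
    )
  })
  fit <- fit_univariate(dat, "y")
  # ANOVA oracle: sigma_e2 = MSE, sigma_g2 = (MSB - MSE)/r
  means <- tapply(dat$y, dat$entry_id, mean)
  msb <- r * var(means)
  mse <- sum((dat$y - means[dat$entry_id])^2) / (n_g * (r - 1))
  expect_equal(fit$varcomp[["resid_clone"]], mse, tolerance = 1e-4)
  expect_equal(fit$varcomp[["genotype"]], (msb - mse) / r, tolerance = 1e-4)
})

test_that("univariate REML agrees with lme4 on a homoscedastic subset", {
  skip_if_not_installed("lme4")
  pop <- small_pop()
  pc <- pop$pheno[pop$pheno$cycle == "PC" & pop$pheno$population_class == "clone", ]
  fit <- fit_univariate(pc, "SP")
  lf <- lme4::lmer(
    SP ~ 1 + (1 | replicate) + (1 | rowf) + (1 | colf) + (1 | entry_id),
    data = transform(pc, rowf = paste(replicate, row),
                     colf = paste(replicate, column)), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  sg_lme4 <- vc$vcov[vc$grp == "entry_id"]
  se_lme4 <- vc$vcov[vc$grp == "Residual"]
  expect_equal(fit$varcomp[["genotype"]], sg_lme4, tolerance = 0.02)
  expect_equal(fit$varcomp[["resid_clone"]], se_lme4, tolerance = 0.02)
})

test_that("noise-free data give BLUPs that reproduce true values", {
  cfg <- sim_config(n_clones = 40, n_snps = 80, n_chromosomes = 2, n_qtl = 30,
                    cycle_h2 = 1 - 1e-10, spatial_sd = 0, check_reps = 4,
                    seed = 9)
  pop <- sim_population(cfg)
  pc <- pop$pheno[pop$pheno$cycle == "PC", ]
  fit <- suppressWarnings(fit_univariate(pc, "SP"))
  tv <- pop$truth$values
  tv <- tv[tv$cycle == "PC" & tv$population_class == "clone", ]
  b <- fit$blups[match(tv$entry_id, fit$blups$entry_id), ]
  expect_gt(cor(b$blup, tv$SP, method = "spearman"), 0.999)
})

test_that("REML trace is non-decreasing and BLUPs are shrunken", {
  pop <- small_pop()
  pc <- pop$pheno[pop$pheno$cycle == "PC", ]
  fit <- suppressWarnings(fit_univariate(pc, "SW"))
  expect_true(all(diff(fit$trace) > -1e-6))
  clone_blups <- fit$blups$blup[fit$blups$population_class == "clone"]
  expect_lte(var(clone_blups), fit$varcomp[["genotype"]] * (1 + 1e-8))
})

test_that("multivariate fit recovers perfect cross-cycle correlation", {
  withr::with_seed(21, {
    n_c <- 100
    u <- rnorm(n_c, 0, 2)
    dat <- do.call(rbind, lapply(c("PC", "FR"), function(cy) {
      data.frame(cycle = cy,
                 replicate = rep(1:2, each = n_c),
                 row = rep(seq_len(n_c), 2), column = 1,
                 entry_id = rep(sprintf("G%03d", 1:n_c), 2),
                 population_class = "clone",
                 y = rep(u, 2) + rnorm(2 * n_c, 0, 1))
    }))
  })
  fit <- suppressWarnings(fit_multivariate(dat, "y", cycles = c("PC", "FR")))
  expect_gt(fit$genetic_correlation[1, 2], 0.95)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_equal(nrow(fit$blups), n_c * 2)
})

test_that("multivariate genetic variances agree with per-cycle univariate fits", {
  cfg <- sim_config(n_clones = 250, n_snps = 200, n_chromosomes = 2,
                    n_qtl = 80, seed = 13)
  pop <- sim_population(cfg)
  fitm <- suppressWarnings(fit_multivariate(pop$pheno, "SP"))
  for (cy in c("PC", "FR")) {
    fu <- suppressWarnings(
      fit_univariate(pop$pheno[pop$pheno$cycle == cy, ], "SP"))
    expect_equal(fitm$U[cy, cy], fu$varcomp[["genotype"]], tolerance = 0.15)
  }
})

test_that("additive relationship matrix matches its algebraic definition", {
  M <- toy_geno(5, 8, seed = 3)
  K <- suppressWarnings(additive_relationship(M))
  p <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * p)
  expect_equal(unclass(K), tcrossprod(W) / (2 * sum(p * (1 - p))),
               ignore_attr = TRUE, tolerance = 1e-12)
  # duplicate clones: off-diagonal equals the shared diagonal
  M2 <- rbind(M, M[1, , drop = FALSE])
  rownames(M2) <- c(rownames(M), "DUP")
  K2 <- suppressWarnings(additive_relationship(M2))
  expect_equal(K2[1, 6], K2[1, 1], tolerance = 1e-12)
  expect_equal(K2[6, 6], K2[1, 1], tolerance = 1e-12)
})

test_that("unrelated HWE panels give near-zero mean off-diagonal kinship", {
  M <- toy_geno(60, 8000, n_chrom = 4, seed = 7)
  K <- additive_relationship(M)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.03)
})

test_that("monomorphic SNPs are excluded from kinship with a warning", {
  M <- toy_geno(20, 10, seed = 5)
  M[, 3] <- 2
  expect_warning(K <- additive_relationship(M), "monomorphic")
  expect_false(anyNA(K))
})

test_that("PCA variance shares are sane and rank-1 input is fully explained", {
  pc <- pca_population(toy_geno(30, 50, seed = 2), n_pc = 5)
  expect_true(all(diff(pc$pct_var) <= 1e-8))
  expect_lte(sum(pc$pct_var), 100 + 1e-8)
  r1 <- tcrossprod(rnorm(12)) ; r1 <- r1 / max(abs(r1))
  p1 <- pca_population(r1 - mean(r1) + t(r1 - mean(r1)), n_pc = 3)
  expect_gt(p1$pct_var[1], 99.9)
})

test_that("PC1 separates allele-frequency-shifted subpopulations", {
  withr::with_seed(31, {
    p <- 300
    f1 <- runif(p, 0.1, 0.5)
    f2 <- pmin(pmax(f1 + runif(p, -0.25, 0.25), 0.02), 0.95)
    A <- sapply(f1, function(q) rbinom(40, 2, q))
    B <- sapply(f2, function(q) rbinom(40, 2, q))
  })
  M <- rbind(A, B)
  rownames(M) <- sprintf("CL%03d", 1:80)
  colnames(M) <- sprintf("S1_%d", seq_len(p) * 1000L)
  pc <- pca_population(M, n_pc = 2)
  s1 <- pc$scores[1:40, 1]; s2 <- pc$scores[41:80, 1]
  sil <- vapply(1:80, function(i) {
    own <- if (i <= 40) s1 else s2
    oth <- if (i <= 40) s2 else s1
    a <- mean(abs(pc$scores[i, 1] - own))
    b <- mean(abs(pc$scores[i, 1] - oth))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})
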