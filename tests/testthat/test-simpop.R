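test_that("simulated genotypes respect domain, naming and determinism", {
  cfg <- sim_config(n_clones = 4, n_snps = 6, n_chromosomes = 2,
                    ld_rho = 0, n_qtl = 3, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(4L, 6L))
  expect_true(all(unclass(g) %in% 0:2))
  map <- snp_map(g)
  expect_true(all(tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))))
  g2 <- simulate_genotypes(cfg)
  expect_identical(unclass(g), unclass(g2))
})

test_that("no simulated SNP is monomorphic or below the MAF floor", {
  g <- small_pop()$geno
  af <- colMeans(unclass(g)) / 2
  maf <- pmin(af, 1 - af)
  expect_true(all(maf >= sim_config()$maf_range[1] - 1e-12))
  counts <- apply(unclass(g), 2, function(x) tabulate(x + 1L, 3L))
  expect_true(all(colSums(counts) == nrow(g)))
})

test_that("block LD produces the configured adjacent-genotype correlation", {
  cfg <- sim_config(n_clones = 2000, n_snps = 500, n_chromosomes = 1,
                    chrom_length_bp = 5e7, ld_block_size = 10, ld_rho = 0.9,
                    n_qtl = 10, seed = 5)
  g <- unclass(simulate_genotypes(cfg))
  blk <- (seq_len(ncol(g)) - 1L) %/% 10
  adj <- which(diff(blk) == 0)
  cors <- vapply(adj, function(j) cor(g[, j], g[, j + 1]), 0)
  expect_gt(mean(cors), 0.8)
  expect_lt(mean(cors), 0.97)
})

test_that("field design has the right plot counts and unique positions", {
  cfg <- sim_config(n_clones = 432, check_reps = 17, n_snps = 20,
                    n_qtl = 5, ld_rho = 0, seed = 2)
  d <- simulate_field_design(cfg)
  expect_equal(nrow(d), 432 * 2 + 2 * 17)
  tab <- table(d$entry_id[d$population_class == "clone"])
  expect_true(all(tab == 2))
  expect_true(all(table(d$entry_id[startsWith(d$population_class, "check")]) == 17))
  expect_false(any(duplicated(d[, c("replicate", "row", "column")])))

  d1 <- simulate_field_design(sim_config(n_clones = 1, check_reps = 1,
                                         n_snps = 20, n_qtl = 5, ld_rho = 0,
                                         seed = 2))
  expect_equal(nrow(d1), 4L)
})

test_that("true-value cycle correlation follows the configured structure", {
  # perfect correlation: identical ranking across cycles
  C1 <- matrix(1, 3, 3)
  cfg <- sim_config(n_clones = 120, n_snps = 200, n_chromosomes = 2,
                    n_qtl = 60, cycle_genetic_corr = C1, seed = 3)
  g <- simulate_genotypes(cfg)
  tv <- simulate_true_values(g, cfg)
  v <- tv$values[tv$values$population_class == "clone", ]
  w <- tapply(v$SP, list(v$entry_id, v$cycle), identity)
  expect_gt(cor(w[, "PC"], w[, "FR"]), 0.999)

  # identity: near-zero cross-cycle correlation (dominance off so cycles
  # share no effect stream)
  cfg0 <- sim_config(n_clones = 600, n_snps = 400, n_chromosomes = 2,
                     n_qtl = 200, dominance_fraction = 0,
                     cycle_genetic_corr = diag(3), seed = 4)
  g0 <- simulate_genotypes(cfg0)
  tv0 <- simulate_true_values(g0, cfg0)
  v0 <- tv0$values[tv0$values$population_class == "clone", ]
  w0 <- tapply(v0$SP, list(v0$entry_id, v0$cycle), identity)
  expect_lt(abs(cor(w0[, "PC"], w0[, "FR"])), 0.15)
})

test_that("intermediate target correlation is recovered on average", {
  C <- matrix(0.7, 3, 3); diag(C) <- 1
  cors <- vapply(1:6, function(s) {
    cfg <- sim_config(n_clones = 500, n_snps = 300, n_chromosomes = 2,
                      n_qtl = 150, cycle_genetic_corr = C, seed = 100 + s)
    g <- simulate_genotypes(cfg)
    tv <- simulate_true_values(g, cfg)
    v <- tv$values[tv$values$population_class == "clone", ]
    w <- tapply(v$SP, list(v$entry_id, v$cycle), identity)
    cor(w[, "PC"], w[, "FR"])
  }, 0)
  expect_lt(abs(mean(cors) - 0.7), 0.08)
})

test_that("noise-free phenotypes equal genetic value plus fixed structure", {
  cfg <- sim_config(n_clones = 30, n_snps = 60, n_chromosomes = 2,
                    n_qtl = 20, cycle_h2 = 1 - 1e-12, spatial_sd = 0,
                    check_reps = 2, seed = 6)
  pop <- sim_population(cfg)
  ph <- pop$pheno[pop$pheno$population_class == "clone" & pop$pheno$cycle == "PC", ]
  tv <- pop$truth$values
  tv <- tv[tv$cycle == "PC", ]
  g <- tv$SP[match(ph$entry_id, tv$entry_id)]
  expect_equal(ph$SP, cfg$trait_params$mean[1] + g, tolerance = 1e-6)
})

test_that("SP-SW genetic correlation is negative by default", {
  tv <- small_pop()$truth$values
  v <- tv[tv$population_class == "clone" & tv$cycle == "PC", ]
  expect_lt(cor(v$SP, v$SW), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_qtl = 50, n_snps = 10), "n_qtl")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sim_config(cycles = c("PC", "FR"), cycle_genetic_corr = bad,
                          cycle_h2 = 0.6), "positive semidefinite")
  expect_error(sim_config(n_snps = 30, n_qtl = 10, n_chromosomes = 3,
                          ld_block_size = 50), "ld_block_size")
})
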