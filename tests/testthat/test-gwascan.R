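test_that("marker filter applies each rule and reports attrition", {
  expect_equal(round(max_genotype_freq_threshold(432), 3), 0.988)
  # constructed panel: 3 SNPs fail MAF only, 2 fail genotype-frequency only,
  # 5 clean -> 5 survive
  n <- 100
  withr::with_seed(8, {
    clean <- sapply(runif(5, 0.25, 0.45), function(q) rbinom(n, 2, q))
    low_maf <- sapply(1:3, function(i) c(rep(0, n - 2), 1, 1))      # maf 0.01
    # het-heavy: MAF fine (0.5) but one genotype class at 99%
    gf_only <- sapply(1:2, function(i) c(rep(1, n - 1), 0))
  })
  M <- cbind(clean, low_maf, gf_only)
  colnames(M) <- sprintf("S1_%d", seq_len(ncol(M)) * 100L)
  rownames(M) <- sprintf("CL%03d", seq_len(n))
  out <- filter_markers(M, maf_min = 0.02, max_genotype_frequency = 0.98)
  expect_equal(ncol(out), 5L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n[rep$rule == "maf_below_min"], 3L)
  expect_equal(rep$n[rep$rule == "genotype_frequency_above_max"], 2L)
  # monomorphic SNP removed by both rules; filtering is idempotent
  M2 <- cbind(M, mono = rep(0L, n))
  colnames(M2)[ncol(M2)] <- "S1_99999"
  out2 <- filter_markers(M2, maf_min = 0.02, max_genotype_frequency = 0.98)
  expect_equal(ncol(out2), 5L)
  expect_equal(unclass(filter_markers(out2, maf_min = 0.02,
                                      max_genotype_frequency = 0.98)),
               unclass(out2), ignore_attr = TRUE)
  # total attrition leaves nothing -> informative error
  expect_error(filter_markers(M[, 6:8, drop = FALSE], maf_min = 0.02,
                              max_genotype_frequency = 0.98),
               "no markers survive")
})

test_that("gene-action codings match their definitions", {
  expect_equal(encode_gene_action(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_gene_action(c(0, 1, 2), "1-dom-ref"), c(0, 1, 1))
  expect_equal(encode_gene_action(c(0, 1, 2), "1-dom-alt"), c(1, 1, 0))
  expect_error(encode_gene_action(c(0, 3), "additive"), "outside")
})

test_that("LOCO kinship uses only off-chromosome markers", {
  M <- toy_geno(30, 40, n_chrom = 2, seed = 4)
  map <- parse_snp_ids(colnames(M))
  ks <- loco_kinship(M)
  direct1 <- additive_relationship(M[, map$chrom == 2])
  expect_equal(unclass(ks[["1"]]), unclass(direct1), ignore_attr = TRUE,
               tolerance = 1e-12)
  # identical SNP content per chromosome -> identical LOCO matrices
  M2 <- cbind(M[, map$chrom == 1],
              `colnames<-`(M[, map$chrom == 1],
                           sub("^S1_", "S2_", colnames(M)[map$chrom == 1])))
  ks2 <- loco_kinship(M2)
  expect_equal(unclass(ks2[["1"]]), unclass(ks2[["2"]]), ignore_attr = TRUE)
  expect_warning(loco_kinship(M[, map$chrom == 1]), "single chromosome")
})

test_that("identity-kinship additive scan equals ordinary regression", {
  for (s in 1:5) {
    M <- toy_geno(35, 20, n_chrom = 2, seed = 50 + s)
    y <- additive_trait(M, h2 = 0.5, seed = 60 + s)
    sc <- gwas_scan(y, M, coding = "additive", kinships = diag(nrow(M)))
    ols <- vapply(seq_len(ncol(M)), function(j) {
      summary(lm(y ~ M[, j]))$coefficients[2, 4]
    }, 0)
    expect_equal(sc$pvalue[match(colnames(M), sc$snp_id)], ols,
                 tolerance = 1e-6)
  }
})

test_that("a planted QTL is detected above genome background", {
  hits <- vapply(1:5, function(s) {
    M <- toy_geno(300, 200, n_chrom = 4, seed = 70 + s)
    withr::with_seed(80 + s, {
      W <- scale(M, scale = FALSE)
      g <- W[, 10] * 1     # QTL on chromosome 1
      y <- setNames(drop(g) / sd(g) + rnorm(300, 0, 2), rownames(M))
    })
    sc <- gwas_scan(y, M, coding = "additive")
    peak <- sc$neglog10p[which.max(sc$neglog10p)]
    bg <- median(sc$neglog10p[sc$chrom != 1])
    (sc$chrom[which.max(sc$neglog10p)] == 1) && (peak - bg >= 3)
  }, TRUE)
  expect_gte(sum(hits), 4)
})

test_that("BH thresholding equals the brute-force step-up rule", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= q * seq_len(m) / m)
    if (!length(k)) return(0)
    ps[max(k)]
  }
  withr::with_seed(17, {
    for (i in 1:10) {
      p <- runif(20)^sample(1:3, 1)
      f <- fdr_threshold(p, q = 0.1)
      expect_equal(f$p_threshold, brute_bh(p, 0.1))
      expect_equal(f$significant, p <= max(f$p_threshold, 0) & f$p_threshold > 0)
    }
  })
  expect_equal(fdr_threshold(rep(1, 50))$n_significant, 0)
  p <- c(1e-10, runif(9999))
  f <- fdr_threshold(p, q = 0.1)
  expect_true(f$significant[1])
  expect_error(fdr_threshold(numeric(0)), "empty")
})

test_that("QTL clustering respects the 5-Mb window and input order", {
  ids <- c("S10_51068605", "S10_53811870", "S10_55391413")
  cl <- cluster_qtl(ids, pvalues = c(1e-5, 8.55e-6, 2e-5))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$span_bp, 55391413 - 51068605)
  expect_equal(round(cl$span_bp / 1e6, 1), 4.3)
  expect_equal(cl$peak_snp, "S10_53811870")
  # boundary: distance strictly greater than the window splits
  expect_equal(nrow(cluster_qtl(c("S1_1", "S1_5000002"))), 2L)
  expect_equal(nrow(cluster_qtl(c("S1_1", "S1_5000001"))), 1L)
  expect_equal(nrow(cluster_qtl("S2_123")), 1L)
  # order invariance
  shuf <- c(ids[2], ids[3], ids[1])
  expect_equal(cluster_qtl(shuf)$members, cl$members)
  expect_error(cluster_qtl("chr1:100"), "malformed")
})

test_that("qq_data pairs uniform quantiles with sorted observations", {
  qd <- qq_data(c(0.5, 0.25, 0.75))
  expect_equal(qd$expected, -log10(c(1, 2, 3) / 4))
  expect_equal(qd$observed, -log10(c(0.25, 0.5, 0.75)))
  expect_equal(nrow(qq_data(runif(100))), 100)
  # uniform p-values hug the diagonal (DKW-style bound on the ECDF)
  withr::with_seed(23, p <- runif(10000))
  qd <- qq_data(p)
  ecdf_dev <- max(abs(10^-qd$observed - 10^-qd$expected))
  expect_lt(ecdf_dev, sqrt(log(2 / 0.001) / (2 * 10000)) + 0.01)
})

test_that("association summary counts markers once across codings", {
  scan <- data.frame(
    snp_id = rep(c("S1_100", "S1_200", "S2_300"), 2),
    chrom = rep(c(1L, 1L, 2L), 2), pos = rep(c(100, 200, 300), 2),
    coding = rep(c("additive", "1-dom-ref"), each = 3),
    trait = "EI",
    pvalue = c(5e-4, 0.2, 5e-5, 2e-3, 0.5, 0.9),
    significant = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  sm <- association_summary(scan)
  expect_equal(sm$n_p1e3, 2L)        # S1_100 (5e-4) and S2_300 (5e-5)
  expect_equal(sm$n_p1e4, 1L)        # S2_300 only
  expect_equal(sm$n_significant, 2L)
  expect_equal(sm$n_chrom, 2L)
})

test_that("scan errors are informative", {
  M <- toy_geno(20, 10, seed = 6)
  expect_error(gwas_scan(setNames(rep(1, 20), rownames(M)), M,
                         kinships = diag(20)), "zero-variance")
})
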