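# Shared in-code fixtures: tiny genotype panels and a memoized small
# simulated trial so expensive objects are built once per test run.

toy_geno <- function(n = 40, p = 30, n_chrom = 2, seed = 1,
                     freq = NULL) {
  withr::with_seed(seed, {
    pf <- freq %||% runif(p, 0.1, 0.5)
    M <- sapply(pf, function(q) rbinom(n, 2, q))
    per <- ceiling(p / n_chrom)
    chrom <- rep(seq_len(n_chrom), each = per)[seq_len(p)]
    pos <- unlist(lapply(seq_len(n_chrom), function(ch) {
      sort(sample.int(1e8, sum(chrom == ch)))
    }))
    colnames(M) <- sprintf("S%d_%d", chrom, pos)
    rownames(M) <- sprintf("CL%04d", seq_len(n))
    M
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_env <- new.env()

small_pop <- function() {
  if (is.null(.fixture_env$pop)) {
    cfg <- sim_config(n_clones = 80, n_snps = 240, n_chromosomes = 3,
                      n_qtl = 60, check_reps = 6, ld_rho = 0.4, seed = 42)
    .fixture_env$pop <- sim_population(cfg)
  }
  .fixture_env$pop
}

# additive polygenic trait on a marker panel at a target plot heritability
additive_trait <- function(M, h2 = 0.65, seed = 1, n_qtl = ncol(M)) {
  withr::with_seed(seed, {
    W <- scale(M, scale = FALSE)
    b <- numeric(ncol(M))
    qtl <- sample.int(ncol(M), n_qtl)
    b[qtl] <- rnorm(n_qtl)
    g <- drop(W %*% b)
    g <- g / sd(g)
    y <- g + rnorm(nrow(M), 0, sqrt((1 - h2) / h2))
    setNames(y, rownames(M))
  })
}
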