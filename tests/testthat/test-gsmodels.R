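test_that("RR-BLUP equals GBLUP through the kinship mixed model", {
  M <- toy_geno(30, 200, n_chrom = 2, seed = 101)
  y <- additive_trait(M, h2 = 0.6, seed = 102)
  fit <- fit_rrblup(unname(y), M)
  p <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  g <- reml_kernel(unname(y), K = K)
  gblup <- unname(drop(g$beta + g$su2 * K %*% g$Vinv_r))
  expect_equal(fit$fitted, gblup, tolerance = 1e-8)
})

test_that("infinite shrinkage collapses RR-BLUP to the fixed-effect mean", {
  M <- toy_geno(25, 60, seed = 103)
  y <- additive_trait(M, h2 = 0.6, seed = 104)
  fit <- fit_rrblup(unname(y), M, delta_fixed = 1e12)
  expect_lt(max(abs(fit$effects)), 1e-8)
  expect_equal(fit$fitted, rep(mean(y), 25), tolerance = 1e-4)
})

test_that("noise-free additive signal is recovered by RR-BLUP", {
  withr::with_seed(105, {
    M <- toy_geno(300, 80, seed = 106)
    W <- scale(M, scale = FALSE)
    b <- rnorm(80)
    y <- drop(W %*% b)
  })
  fit <- fit_rrblup(y, M)
  expect_gt(cor(fit$effects, b), 0.99)
})

test_that("Bayes A is seed-reproducible and approaches RR-BLUP at high prior df", {
  M <- toy_geno(60, 80, seed = 107)
  y <- additive_trait(M, h2 = 0.6, seed = 108)
  f1 <- fit_bayes_a(unname(y), M, n_iter = 800, burn_in = 200, seed = 9)
  f2 <- fit_bayes_a(unname(y), M, n_iter = 800, burn_in = 200, seed = 9)
  expect_identical(f1$effects, f2$effects)
  expect_true(all(is.finite(f1$chain)))
  rr <- fit_rrblup(unname(y), M)
  flim <- fit_bayes_a(unname(y), M, n_iter = 3000, burn_in = 500,
                      df_hyper = 1e6, seed = 10)
  expect_gt(cor(flim$effects, rr$effects), 0.98)
})

test_that("Bayes A concentrates on a planted sparse architecture", {
  recalls <- vapply(1:5, function(s) {
    M <- toy_geno(200, 100, seed = 110 + s)
    withr::with_seed(120 + s, {
      W <- scale(M, scale = FALSE)
      qtl <- sample.int(100, 5)
      b <- numeric(100); b[qtl] <- rnorm(5, 0, 2) + sign(rnorm(5)) * 2
      g <- drop(W %*% b)
      y <- g + rnorm(200, 0, sd(g) * 0.4)
    })
    fb <- fit_bayes_a(y, M, n_iter = 1500, burn_in = 300, seed = s)
    top5 <- order(-abs(fb$effects))[1:5]
    length(intersect(top5, qtl))
  }, 0)
  expect_gte(mean(recalls), 3)
})

test_that("RKHS kernels are PSD and the flat-kernel limit predicts the mean", {
  M <- toy_geno(40, 60, seed = 131)
  y <- additive_trait(M, h2 = 0.6, seed = 132)
  fit <- fit_rkhs(unname(y), M)
  W <- sweep(M, 2, colMeans(M))
  D <- as.matrix(dist(W))^2
  K <- exp(-D / (fit$fits[[1]]$h * fit$med))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  flat <- fit_rkhs(unname(y), M, bandwidth_grid = 1e8)
  expect_lt(max(abs(flat$fitted - mean(flat$fitted))), 0.3 * sd(y))
  dup <- M[rep(1, 10), ]
  expect_error(fit_rkhs(rnorm(10), dup), "duplicate-only")
})

test_that("RKHS is competitive with RR-BLUP on additive toys", {
  diffs <- vapply(1:5, function(s) {
    M <- toy_geno(150, 100, seed = 140 + s)
    y <- additive_trait(M, h2 = 0.6, seed = 150 + s)
    tr <- 1:100; va <- 101:150
    fr <- fit_rrblup(unname(y[tr]), M[tr, ])
    fk <- fit_rkhs(unname(y[tr]), M[tr, ])
    ar <- cor(predict(fr, M[va, ]), y[va])
    ak <- cor(predict(fk, M[va, ]), y[va])
    ar - ak
  }, 0)
  expect_lt(mean(diffs), 0.05)
})

test_that("ADE nests to RR-BLUP when dominance and epistasis are dropped", {
  M <- toy_geno(35, 80, seed = 161)
  y <- additive_trait(M, h2 = 0.6, seed = 162)
  fa <- fit_ade(unname(y), M, components = "A")
  fr <- fit_rrblup(unname(y), M)
  expect_equal(fa$fitted, fr$fitted, tolerance = 1e-8)
})

test_that("planted dominance inflates the dominance variance share", {
  ratio <- function(dom, s) {
    M <- toy_geno(250, 150, seed = 170 + s)
    withr::with_seed(180 + s, {
      W <- scale(M, scale = FALSE)
      g <- drop(W %*% rnorm(150, 0, 1))
      if (dom) {
        H <- scale((M == 1) * 1, scale = FALSE)
        g <- g + drop(H %*% rnorm(150, 0, 1.5))
      }
      g <- g / sd(g)
      y <- g + rnorm(250, 0, 0.7)
    })
    f <- fit_ade(y, M)
    f$varprop[["D"]]
  }
  with_dom <- mean(vapply(1:3, function(s) ratio(TRUE, s), 0))
  without <- mean(vapply(1:3, function(s) ratio(FALSE, s), 0))
  expect_gt(with_dom, without)
})

test_that("predictions are consistent, equivariant, and strictly aligned", {
  M <- toy_geno(50, 60, seed = 191)
  y <- additive_trait(M, h2 = 0.6, seed = 192)
  for (fit in list(fit_rrblup(unname(y), M),
                   fit_rkhs(unname(y), M),
                   fit_ade(unname(y), M))) {
    pr <- predict(fit, M)
    expect_equal(pr, fit$fitted, tolerance = 1e-10)
    perm <- c(5:1, 6:50)
    expect_equal(predict(fit, M[perm, ]), pr[perm], tolerance = 1e-10)
  }
  fit <- fit_rrblup(unname(y), M)
  M2 <- M; colnames(M2)[3] <- "S9_123"
  expect_error(predict(fit, M2), "missing from new data")
  # covariate contract
  cv <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "snp_cov"))
  fitc <- fit_rrblup(unname(y), M, covariates = cv)
  expect_error(predict(fitc, M), "supply new_covariates")
  expect_error(predict(fit, M, new_covariates = cv), "without covariates")
  expect_error(fit_rrblup(unname(y), M,
                          covariates = matrix(1, 50, 1,
                                              dimnames = list(NULL, "const"))),
               "singular fixed-effect")
})
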