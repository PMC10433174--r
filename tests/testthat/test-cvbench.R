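test_that("fold plans partition clones with balanced sizes, deterministically", {
  plan <- make_folds(10, k = 5, repeats = 2, seed = 3)
  sizes <- table(plan$fold[plan$rep == 1])
  expect_true(all(sizes == 2))
  plan432 <- make_folds(432, k = 5, repeats = 1, seed = 3)
  expect_equal(sort(as.integer(table(plan432$fold))), c(86, 86, 86, 87, 87))
  plan_b <- make_folds(10, k = 5, repeats = 2, seed = 3)
  expect_identical(plan, plan_b)
  # each repeat partitions every clone exactly once
  expect_true(all(table(plan$id, plan$rep) == 1))
  expect_error(make_folds(3, k = 5), "n < k")
})

test_that("metrics match their definitions", {
  obs <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(metric_accuracy(obs, obs), 1)
  expect_equal(metric_accuracy(-obs, obs), -1)
  expect_equal(metric_accuracy(2 * obs + 3, obs), 1)
  expect_true(is.na(metric_accuracy(rep(1, 10), obs)))
  expect_equal(metric_ci(obs, obs), 1)
  # reverse ranking: top-2 sets are disjoint
  expect_equal(metric_ci(rev(sort(obs)), sort(obs)), 0)
  b <- metric_bias(obs, obs)
  expect_equal(unname(b), c(1, 0), tolerance = 1e-12)
  b2 <- metric_bias(0.5 * obs + 2, obs)
  expect_equal(unname(b2), c(0.5, 2), tolerance = 1e-12)
})

test_that("random predictions give coincidence index near the top fraction", {
  withr::with_seed(5, {
    ci <- replicate(400, metric_ci(rnorm(100), rnorm(100)))
  })
  expect_lt(abs(mean(ci) - 0.2), 0.03)
})

test_that("top-SNP selection finds a planted QTL and breaks ties by position", {
  hits <- vapply(1:5, function(s) {
    M <- toy_geno(250, 120, n_chrom = 3, seed = 200 + s)
    withr::with_seed(210 + s, {
      W <- scale(M, scale = FALSE)
      g <- drop(W[, 25]) # QTL at marker 25
      y <- setNames(g / sd(g) + rnorm(250, 0, 1), rownames(M))
    })
    top <- select_top_snp(y, M)
    which(colnames(M) == top)
  }, 0)
  expect_gte(sum(abs(hits - 25) <= 3), 4)
  # deterministic tie-break: duplicated marker column, identical p-values
  M <- toy_geno(80, 6, n_chrom = 2, seed = 220)
  map <- parse_snp_ids(colnames(M))
  o <- order(map$chrom, map$pos)
  M2 <- M[, o]
  M2[, 4] <- M2[, 2]   # duplicate an early marker later in the map
  y <- setNames(M2[, 2] + rnorm(80, 0, 0.5), rownames(M))
  top <- select_top_snp(y, M2, kinships = diag(80))
  expect_equal(top, colnames(M2)[min(2, 4)])
})

test_that("selection uses only training clones (leakage canary)", {
  M <- toy_geno(120, 60, seed = 230)
  y <- additive_trait(M, h2 = 0.5, seed = 231)
  tr <- 1:90
  top1 <- select_top_snp(y[tr], M[tr, ])
  y2 <- y
  y2[91:120] <- rnorm(30, 100, 50)  # corrupt validation phenotypes
  top2 <- select_top_snp(y2[tr], M[tr, ])
  expect_identical(top1, top2)
})

test_that("run_cv produces complete, deterministic cells and sane summaries", {
  M <- toy_geno(90, 80, n_chrom = 2, seed = 240)
  y <- additive_trait(M, h2 = 0.65, seed = 241)
  plan <- make_folds(rownames(M), k = 5, repeats = 2, seed = 7)
  res <- run_cv(list(tA = y), M, plan, models = c("rrblup", "bayesa"),
                fixed_modes = c("none", "top_gwas_snp"),
                gs_opts = list(bayesa_n_iter = 400, bayesa_burn_in = 100),
                loco = FALSE)
  expect_equal(nrow(res$cells), 2 * 2 * 2 * 5)   # models x modes x reps x folds
  expect_true(all(!res$cells$failed))
  expect_true(all(res$cells$accuracy >= -1 & res$cells$accuracy <= 1))
  expect_true(all(res$cells$ci >= 0 & res$cells$ci <= 1))
  res2 <- run_cv(list(tA = y), M, plan, models = c("rrblup", "bayesa"),
                 fixed_modes = c("none", "top_gwas_snp"),
                 gs_opts = list(bayesa_n_iter = 400, bayesa_burn_in = 100),
                 loco = FALSE)
  expect_equal(res$cells, res2$cells)
  sm <- summarize_cv(res)
  expect_true(all(c("mean", "median", "iqr") %in% names(sm$metrics)))
  # selection frequencies conserve the number of selection events
  expect_equal(sum(sm$selection_frequency$count), 2 * 5)
  # identical cells -> zero IQR
  fake <- res
  fake$cells$accuracy <- 0.5
  smf <- summarize_cv(fake)
  expect_equal(smf$metrics$iqr[smf$metrics$metric == "accuracy"], c(0, 0, 0, 0))
})

test_that("cross-validated accuracy sits in the theory envelope at h2 = 0.65", {
  accs <- vapply(1:3, function(s) {
    M <- toy_geno(200, 150, n_chrom = 2, seed = 250 + s)
    y <- additive_trait(M, h2 = 0.65, seed = 260 + s)
    plan <- make_folds(rownames(M), k = 5, repeats = 1, seed = s)
    res <- run_cv(list(t = y), M, plan, models = "rrblup",
                  fixed_modes = "none", loco = FALSE)
    mean(res$cells$accuracy)
  }, 0)
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), sqrt(0.65) + 0.05)
})

test_that("failed fits are recorded without aborting the run", {
  M <- toy_geno(40, 30, seed = 270)
  y <- additive_trait(M, h2 = 0.6, seed = 271)
  plan <- make_folds(rownames(M), k = 5, repeats = 1, seed = 1)
  res <- run_cv(list(t = y), M, plan, models = c("rrblup", "nosuch"),
                fixed_modes = "none", loco = FALSE)
  expect_true(all(res$cells$failed[res$cells$model == "nosuch"]))
  expect_true(all(!res$cells$failed[res$cells$model == "rrblup"]))
  expect_equal(summarize_cv(res)$n_failed, 5L)
})
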