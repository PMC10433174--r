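# Repeated k-fold cross-validation of the genomic-prediction models, with an
# optional within-training-fold GWAS that carries the peak SNP into the
# model as a fixed covariate, and the four evaluation metrics (accuracy,
# coincidence index, slope, intercept).

#' Build a repeated k-fold cross-validation plan
#'
#' Fold assignment for repeat `r` is seeded deterministically from
#' `seed` and `r`, so every model/trait/fixed-effect arm evaluated against
#' the same plan shares identical training sets. Fold sizes differ by at
#' most one.
#'
#' @param n number of clones (or clone IDs; a character vector is used
#'   as-is).
#' @param k folds (default 5).
#' @param repeats repetitions (default 25).
#' @param seed base seed.
#' @return data.frame of class `cv_plan`: `rep`, `fold`, `id` (clone
#'   identifier or index).
#' @export
make_folds <- function(n, k = 5L, repeats = 25L, seed = 1L) {
  ids <- if (is.character(n)) n else as.character(seq_len(n))
  nn <- length(ids)
  if (nn < k) stop("n < k: cannot build ", k, " folds from ", nn, " clones")
  out <- lapply(seq_len(repeats), function(r) {
    f <- with_seed(derive_seed(seed, 1000L + r),
                   sample(rep_len(seq_len(k), nn)))
    data.frame(rep = r, fold = f, id = ids, stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, out)
  attr(plan, "k") <- k
  attr(plan, "repeats") <- repeats
  attr(plan, "seed") <- seed
  class(plan) <- c("cv_plan", "data.frame")
  plan
}

#' Select the top GWAS SNP from a training set
#'
#' Runs an additive-coding mixed-model scan ([gwas_scan()]) on the training
#' clones only and returns the SNP with the smallest p-value; ties are
#' broken by ascending (chromosome, position). If no p-value is defined the
#' return is `NA` (caller falls back to no fixed effect).
#'
#' @param y_train named trait values for the training clones.
#' @param geno_train genotype rows for the training clones.
#' @param kinships optional kinship list/matrix for the scan; by default
#'   LOCO kinships are built from the training genotypes.
#' @return SNP ID (character) or `NA_character_`.
#' @export
select_top_snp <- function(y_train, geno_train, kinships = NULL) {
  scan <- gwas_scan(y_train, geno_train, coding = "additive",
                    kinships = kinships)
  ok <- !scan$collinear & is.finite(scan$pvalue)
  if (!any(ok)) {
    warning("no testable marker; falling back to no fixed effect")
    return(NA_character_)
  }
  scan <- scan[ok, ]
  scan <- scan[order(scan$pvalue, scan$chrom, scan$pos), ]
  scan$snp_id[1]
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param pred,obs prediction and observation vectors (>= 3 pairs, both
#'   non-constant; `NA` returned otherwise).
#' @return Pearson r in `[-1, 1]`.
#' @export
metric_accuracy <- function(pred, obs) {
  if (length(pred) < 3 || sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Coincidence index
#'
#' Fraction of the top `top_frac` of observed values that also land in the
#' top `top_frac` of predictions. Top sets have size `ceiling(top_frac * n)`;
#' ties at the cutoff are resolved by stable order (first occurrence wins).
#'
#' @param pred,obs prediction and observation vectors (n >= 5).
#' @param top_frac top fraction (default 0.2).
#' @return CI in `[0, 1]`.
#' @export
metric_ci <- function(pred, obs, top_frac = 0.2) {
  n <- length(obs)
  if (n < 5) return(NA_real_)
  s <- ceiling(top_frac * n)
  top_obs <- order(-obs)[seq_len(s)]
  top_pred <- order(-pred)[seq_len(s)]
  length(intersect(top_obs, top_pred)) / s
}

#' Prediction bias: slope and intercept
#'
#' Ordinary least squares of predicted on observed values; an unbiased model
#' gives slope 1 and intercept 0.
#'
#' @param pred,obs prediction and observation vectors; `obs` non-constant.
#' @return named vector `c(slope, intercept)` (NA if undefined).
#' @export
metric_bias <- function(pred, obs) {
  if (length(obs) < 3 || sd(obs) == 0)
    return(c(slope = NA_real_, intercept = NA_real_))
  cf <- coef(lm(pred ~ obs))
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

# Fit one GS model by name.
fit_gs_model <- function(model, y, M, covariates, gs_opts, cell_seed) {
  switch(model,
         rrblup = fit_rrblup(y, M, covariates = covariates),
         bayesa = fit_bayes_a(y, M, covariates = covariates,
                              n_iter = gs_opts$bayesa_n_iter %||% 3000L,
                              burn_in = gs_opts$bayesa_burn_in %||% 500L,
                              df_hyper = gs_opts$bayesa_df %||% 5,
                              r2 = gs_opts$bayesa_r2 %||% 0.5,
                              seed = cell_seed),
         rkhs = fit_rkhs(y, M, covariates = covariates,
                         bandwidth_grid = gs_opts$rkhs_grid %||% c(0.2, 1, 5),
                         average = isTRUE(gs_opts$rkhs_average)),
         ade = fit_ade(y, M, covariates = covariates),
         stop("unknown model: ", model))
}

#' Run the cross-validation benchmark
#'
#' For every (trait, model, fixed-effect mode, repeat, fold) cell: fit on
#' the training folds, predict the validation fold, and score accuracy,
#' coincidence index, slope and intercept. With
#' `fixed_modes = "top_gwas_snp"` an additive GWAS is run on the training
#' clones of each repeat x fold (never the validation clones) and the peak
#' SNP's genotype column enters the model as a fixed covariate; the peak is
#' shared by all models in that cell. Failed fits are recorded, not fatal.
#'
#' @param traits named list of clone-level trait vectors (names = clone
#'   IDs), or a data.frame with `entry_id` plus one column per trait.
#' @param geno genotype matrix (rows = clones).
#' @param plan a [make_folds()] plan over the clone IDs.
#' @param models subset of `c("rrblup", "bayesa", "rkhs", "ade")`.
#' @param fixed_modes subset of `c("none", "top_gwas_snp")`.
#' @param gs_opts list of model options (Bayes A chain length, RKHS grid,
#'   ...).
#' @param loco use LOCO kinships for the within-fold GWAS (single
#'   whole-genome kinship when `FALSE`, faster).
#' @return object of class `cv_result`: `cells` (one row per cell with the
#'   four metrics, the selected SNP and a `failed` flag), `predictions`
#'   (long data.frame), `plan` attributes.
#' @export
run_cv <- function(traits, geno, plan, models = c("rrblup", "bayesa", "rkhs", "ade"),
                   fixed_modes = c("none", "top_gwas_snp"),
                   gs_opts = list(), loco = TRUE) {
  if (is.data.frame(traits)) {
    stopifnot("entry_id" %in% names(traits))
    ids <- traits$entry_id
    trait_names <- setdiff(names(traits), "entry_id")
    traits <- setNames(lapply(trait_names,
                              function(tr) setNames(traits[[tr]], ids)),
                       trait_names)
  }
  stopifnot(is.list(traits), !is.null(names(traits)))
  M <- impute_genotypes(unclass(geno))
  map <- snp_map(geno)
  cells <- list(); preds <- list()
  reps <- sort(unique(plan$rep))
  k <- attr(plan, "k") %||% max(plan$fold)
  base_seed <- attr(plan, "seed") %||% 1L
  for (tr in names(traits)) {
    yfull <- traits[[tr]]
    ids <- intersect(names(yfull), rownames(M))
    y <- yfull[ids]
    for (r in reps) {
      pr <- plan[plan$rep == r & plan$id %in% ids, ]
      fold_of <- setNames(pr$fold, pr$id)
      for (f in sort(unique(pr$fold))) {
        val_ids <- names(fold_of)[fold_of == f]
        trn_ids <- setdiff(ids, val_ids)
        top_snp <- NA_character_
        if ("top_gwas_snp" %in% fixed_modes) {
          kin <- if (loco) NULL else diag(length(trn_ids))
          top_snp <- tryCatch(
            select_top_snp(y[trn_ids], M[trn_ids, , drop = FALSE],
                           kinships = kin),
            error = function(e) NA_character_)
        }
        for (fm in fixed_modes) {
          cov_tr <- cov_va <- NULL
          fm_eff <- fm
          if (fm == "top_gwas_snp") {
            if (is.na(top_snp)) {
              fm_eff <- "none"
            } else {
              cov_tr <- matrix(M[trn_ids, top_snp], ncol = 1,
                               dimnames = list(NULL, top_snp))
              cov_va <- matrix(M[val_ids, top_snp], ncol = 1,
                               dimnames = list(NULL, top_snp))
              if (sd(cov_tr) == 0) { cov_tr <- cov_va <- NULL; fm_eff <- "none" }
            }
          }
          for (mod in models) {
            cell_seed <- derive_seed(base_seed, r * 1000L + f * 10L +
                                       match(mod, c("rrblup", "bayesa", "rkhs", "ade")))
            res <- tryCatch({
              fit <- fit_gs_model(mod, y[trn_ids], M[trn_ids, , drop = FALSE],
                                  cov_tr, gs_opts, cell_seed)
              ph <- predict(fit, M[val_ids, , drop = FALSE],
                            new_covariates = cov_va)
              list(pred = ph, failed = FALSE, msg = NA_character_)
            }, error = function(e) list(pred = NULL, failed = TRUE,
                                        msg = conditionMessage(e)))
            obs <- y[val_ids]
            if (!res$failed) {
              bias <- metric_bias(res$pred, obs)
              cells[[length(cells) + 1L]] <- data.frame(
                trait = tr, model = mod, fixed_mode = fm, rep = r, fold = f,
                top_snp = if (fm == "top_gwas_snp") top_snp else NA_character_,
                accuracy = metric_accuracy(res$pred, obs),
                ci = metric_ci(res$pred, obs),
                slope = bias[["slope"]], intercept = bias[["intercept"]],
                failed = FALSE, message = NA_character_,
                stringsAsFactors = FALSE)
              preds[[length(preds) + 1L]] <- data.frame(
                trait = tr, model = mod, fixed_mode = fm, rep = r, fold = f,
                entry_id = val_ids, observed = unname(obs),
                predicted = unname(res$pred), stringsAsFactors = FALSE)
            } else {
              cells[[length(cells) + 1L]] <- data.frame(
                trait = tr, model = mod, fixed_mode = fm, rep = r, fold = f,
                top_snp = NA_character_, accuracy = NA_real_, ci = NA_real_,
                slope = NA_real_, intercept = NA_real_, failed = TRUE,
                message = res$msg, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 predictions = do.call(rbind, preds),
                 k = k, repeats = length(reps)),
            class = "cv_result")
}

#' Summarize a cross-validation benchmark
#'
#' Mean, median, quartiles and range of each metric per (trait, model,
#' fixed-effect mode) across all repeat x fold cells (failed cells excluded,
#' counted), plus the fixed-effect SNP selection-frequency table.
#'
#' @param results a [run_cv()] result.
#' @return list: `metrics` (long summary data.frame), `selection_frequency`
#'   (`trait`, `snp_id`, `count`), `n_failed`.
#' @export
summarize_cv <- function(results) {
  cells <- results$cells
  ok <- cells[!cells$failed, , drop = FALSE]
  metrics <- c("accuracy", "ci", "slope", "intercept")
  combos <- unique(ok[, c("trait", "model", "fixed_mode")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- ok$trait == combos$trait[i] & ok$model == combos$model[i] &
      ok$fixed_mode == combos$fixed_mode[i]
    for (m in metrics) {
      v <- ok[[m]][sel]
      v <- v[is.finite(v)]
      if (!length(v)) next
      qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        combos[i, ], metric = m, mean = mean(v), median = qs[2],
        q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
        min = min(v), max = max(v), n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  sel_cells <- cells[cells$fixed_mode == "top_gwas_snp" & !cells$failed &
                       !is.na(cells$top_snp), ]
  # one selection event per repeat x fold x trait (shared across models)
  sel_unique <- unique(sel_cells[, c("trait", "rep", "fold", "top_snp")])
  freq <- if (nrow(sel_unique)) {
    ag <- aggregate(rep ~ trait + top_snp, data = sel_unique, FUN = length)
    names(ag) <- c("trait", "snp_id", "count")
    ag[order(ag$trait, -ag$count), ]
  } else {
    data.frame(trait = character(), snp_id = character(), count = integer())
  }
  list(metrics = do.call(rbind, rows), selection_frequency = freq,
       n_failed = sum(cells$failed))
}
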