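# End-to-end orchestration: simulate or ingest a clonal trial, derive
# composite traits and plot-level RA, fit the univariate and multivariate
# mixed models, scan for marker-trait associations, and benchmark the
# genomic-prediction models. All artifacts land in a run directory with a
# checksummed manifest; completed stages are skipped on rerun.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for the recognized sections
#'   (`seed`, `outdir`, `sim` or `inputs`, `traits`, `econ`, `filter`,
#'   `gwas`, `gs`, `cv`).
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs)) {
      if (!file.exists(f)) stop("configured input does not exist: ", f)
    }
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

pipe_log <- function(run, stage, event, t0 = NULL) {
  msg <- sprintf("[%s] stage=%s event=%s%s", format(Sys.time(), "%H:%M:%S"),
                 stage, event,
                 if (!is.null(t0)) sprintf(" elapsed=%.1fs",
                                           as.numeric(Sys.time()) - t0) else "")
  message(msg)
  cat(msg, "\n", file = file.path(run, "run.log"), append = TRUE)
}

# Run `fun` for a stage unless a cached result for the same config hash
# exists; cache lives under <outdir>/cache and makes reruns both fast and
# bitwise-identical downstream.
stage_cached <- function(run, stage, hash, fun) {
  cache <- file.path(run, "cache", paste0(stage, ".rds"))
  if (file.exists(cache)) {
    obj <- readRDS(cache)
    if (identical(obj$hash, hash)) {
      pipe_log(run, stage, "skipped (cached)")
      return(obj$value)
    }
  }
  t0 <- as.numeric(Sys.time())
  pipe_log(run, stage, "start")
  value <- fun()
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(hash = hash, value = value), cache)
  pipe_log(run, stage, "done", t0)
  value
}

#' Trait-by-trait Pearson correlation matrix with significance stars
#'
#' @param ra long RA table (`entry_id`, `trait`, `RA_percent`) or a wide
#'   data.frame of entries x traits.
#' @return list: `r` (correlation matrix, unit diagonal), `p` (two-sided
#'   p-values), `stars` (`***` p<=0.001, `**` p<=0.01, `*` p<=0.05), `n`.
#'   Constant traits give `NA` entries.
#' @export
correlation_matrix <- function(ra) {
  if (all(c("entry_id", "trait", "RA_percent") %in% names(ra))) {
    wide <- tapply(ra$RA_percent, list(ra$entry_id, ra$trait), identity)
  } else {
    wide <- as.matrix(ra[, !(names(ra) %in% "entry_id"), drop = FALSE])
  }
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3) stop("need >= 3 complete records")
  t_names <- colnames(wide)
  m <- length(t_names)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(t_names, t_names))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (sd(wide[, i]) == 0 || sd(wide[, j]) == 0) next
    ct <- cor.test(wide[, i], wide[, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
            ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, n = nrow(wide))
}

# Plot-level RA across cycles for every derived trait: plots are matched by
# (replicate, row, column) since ratoons regrow on the same stubble.
plot_level_ra <- function(derived, traits, cycles) {
  pc <- cycles[1]; rts <- cycles[-1]
  key <- paste(derived$replicate, derived$row, derived$column, sep = ":")
  base <- derived[derived$cycle == pc, c("replicate", "row", "column",
                                         "entry_id", "population_class")]
  kb <- paste(base$replicate, base$row, base$column, sep = ":")
  for (tr in traits) {
    wide <- tapply(derived[[tr]], list(key, factor(derived$cycle, levels = cycles)),
                   identity)
    wide <- wide[kb, , drop = FALSE]
    p <- wide[, pc]
    ra <- 100 * rowSums(wide[, rts, drop = FALSE]) / (p * length(rts))
    ra[!is.finite(ra)] <- NA
    base[[paste0("RA_", tr)]] <- ra
  }
  base
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) simulate or ingest genotypes and plot phenotypes;
#' (2) derive composite traits per plot; (3) univariate REML fits of
#' plot-level RA per trait (variance components, entry-mean heritability,
#' BLUPs); (4) multivariate multi-cycle fits per trait, per-cycle clone
#' BLUPs and the BLUP-based RA table; (5) RA trait correlation matrix;
#' (6) marker filtering, LOCO kinships and the GWAS with FDR thresholds and
#' QTL clusters; (7) the cross-validation benchmark. Artifacts are CSV/TSV/
#' JSON files in `outdir`, listed with md5 checksums in `manifest.json`;
#' completed stages are cached and skipped when rerun with an identical
#' configuration.
#'
#' @param config list (or path to a YAML file, see [read_run_config()]).
#'   Recognized entries: `seed`; `outdir`; `sim` (arguments to
#'   [sim_config()]) or `inputs` (`genotypes` TSV/VCF, `phenotypes` CSV);
#'   `traits` (default EI, SP, SW, TCH, TSH); `cycles`; `econ`; `filter`
#'   (`maf_min`, `max_genotype_frequency`); `gwas` (`codings`, `q`,
#'   `qtl_window`, `enabled`); `gs` (`models`, `fixed_modes`, model
#'   options); `cv` (`k`, `repeats`).
#' @return invisibly, a list of in-memory stage results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed %||% 1L
  run <- config$outdir %||% stop("config$outdir is required")
  dir.create(run, showWarnings = FALSE, recursive = TRUE)
  cycles <- config$cycles %||% c("PC", "FR", "SR")
  traits <- config$traits %||% c("EI", "SP", "SW", "TCH", "TSH")
  gwas_cfg <- config$gwas %||% list()
  gs_cfg <- config$gs %||% list()
  cv_cfg <- config$cv %||% list()
  want_gwas <- gwas_cfg$enabled %||% TRUE
  want_gs <- gs_cfg$enabled %||% TRUE
  if ((want_gwas || want_gs) &&
      is.null(config$sim) && is.null(config$inputs$genotypes)) {
    stop("validation error: GWAS/GS requested but no genotype source configured")
  }
  hash <- config_hash(config)
  manifest <- list(seed = seed, config_hash = hash, artifacts = list())
  add_artifact <- function(path, stage) {
    manifest$artifacts[[basename(path)]] <<-
      list(stage = stage, md5 = unname(tools::md5sum(path)))
    path
  }

  # (1) ingest / simulate -----------------------------------------------
  dat <- stage_cached(run, "01_ingest", hash, function() {
    if (!is.null(config$sim)) {
      sim_args <- config$sim
      sim_args$seed <- sim_args$seed %||% seed
      pop <- sim_population(do.call(sim_config, sim_args))
      list(geno = pop$geno, pheno = pop$pheno, truth = pop$truth)
    } else {
      gpath <- config$inputs$genotypes
      geno <- if (!is.null(gpath) && grepl("\\.vcf$", gpath))
        read_genotype_vcf(gpath)
      else if (!is.null(gpath)) read_genotype_tsv(gpath) else NULL
      list(geno = geno, pheno = read_phenotype_csv(config$inputs$phenotypes),
           truth = NULL)
    }
  })
  if (!is.null(dat$geno))
    add_artifact(write_genotype_tsv(dat$geno, file.path(run, "genotypes.tsv")),
                 "01_ingest")
  add_artifact(write_phenotype_csv(dat$pheno, file.path(run, "phenotypes.csv")),
               "01_ingest")

  # (2) derived traits ---------------------------------------------------
  derived <- stage_cached(run, "02_derive", hash, function() {
    derive_traits(dat$pheno, econ = config$econ %||%
                    list(price = 600, c_harvest = 10, c_haul = 6, c_mill = 14))
  })
  add_artifact({
    write.csv(derived[, c("entry_id", "cycle", "SC", "TCH", "CRS", "TSH", "EI")],
              file.path(run, "derived_traits.csv"), row.names = FALSE)
    file.path(run, "derived_traits.csv")
  }, "02_derive")

  # (3) univariate fits on plot-level RA ---------------------------------
  ra_plots <- plot_level_ra(derived, traits, cycles)
  uni <- stage_cached(run, "03_univariate", hash, function() {
    fits <- list()
    for (tr in traits) {
      fits[[tr]] <- fit_univariate(ra_plots, paste0("RA_", tr))
    }
    fits
  })
  h2_tab <- do.call(rbind, lapply(traits, function(tr) {
    f <- uni[[tr]]
    data.frame(trait = tr,
               blup_mean = mean(f$blups$predicted[f$blups$population_class == "clone"]),
               sigma_g2 = f$varcomp[["genotype"]],
               sigma_e2 = f$varcomp[[grep("^resid_clone", names(f$varcomp), value = TRUE)[1]]],
               H2 = f$H2, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  add_artifact({
    write.csv(h2_tab, file.path(run, "heritability.csv"), row.names = FALSE)
    file.path(run, "heritability.csv")
  }, "03_univariate")
  add_artifact({
    jsonlite::write_json(lapply(uni, function(f)
      list(varcomp = as.list(f$varcomp), H2 = f$H2, loglik = f$loglik,
           converged = f$converged, seed = seed)),
      file.path(run, "variance_components.json"), auto_unbox = TRUE,
      digits = NA)
    file.path(run, "variance_components.json")
  }, "03_univariate")

  # (4) multivariate fits and BLUP-based RA ------------------------------
  multi <- stage_cached(run, "04_multivariate", hash, function() {
    fits <- list()
    for (tr in traits) {
      fits[[tr]] <- fit_multivariate(derived, tr, cycles = cycles)
    }
    fits
  })
  blups <- do.call(rbind, lapply(multi, `[[`, "blups"))
  ra <- ra_from_blups(blups, cycles = cycles)
  add_artifact({
    write.csv(blups, file.path(run, "cycle_blups.csv"), row.names = FALSE)
    file.path(run, "cycle_blups.csv")
  }, "04_multivariate")
  add_artifact({
    write.csv(ra, file.path(run, "ra_table.csv"), row.names = FALSE)
    file.path(run, "ra_table.csv")
  }, "04_multivariate")

  # (5) RA correlation matrix -------------------------------------------
  corr <- stage_cached(run, "05_correlation", hash, function()
    correlation_matrix(ra))
  add_artifact({
    write.csv(data.frame(trait = rownames(corr$r), corr$r, check.names = FALSE),
              file.path(run, "ra_correlations.csv"), row.names = FALSE)
    file.path(run, "ra_correlations.csv")
  }, "05_correlation")

  # (6) GWAS --------------------------------------------------------------
  scan <- qtl <- NULL
  geno_f <- NULL
  if (want_gwas && !is.null(dat$geno)) {
    gwres <- stage_cached(run, "06_gwas", hash, function() {
      geno_f <- filter_markers(dat$geno,
                               maf_min = gwas_cfg$maf_min %||% 0.02,
                               max_genotype_frequency = gwas_cfg$max_genotype_frequency)
      kin <- loco_kinship(geno_f)
      codings <- gwas_cfg$codings %||% c("additive", "1-dom-ref", "1-dom-alt")
      scans <- list()
      for (tr in traits) {
        v <- ra$RA_percent[ra$trait == tr]
        names(v) <- ra$entry_id[ra$trait == tr]
        v <- v[names(v) %in% rownames(geno_f)]
        scans[[tr]] <- gwas_scan(v, geno_f, coding = codings, kinships = kin,
                                 trait_name = tr)
      }
      scan <- apply_fdr(do.call(rbind, scans), q = gwas_cfg$q %||% 0.1)
      sig <- scan[scan$significant, ]
      qtl <- if (nrow(sig)) {
        do.call(rbind, lapply(split(sig, sig$trait), function(s) {
          cl <- cluster_qtl(s$snp_id, s$pvalue,
                            window = gwas_cfg$qtl_window %||% 5e6)
          if (nrow(cl)) cbind(trait = s$trait[1], cl) else NULL
        }))
      } else cluster_qtl(character(0))
      list(scan = scan, qtl = qtl, geno_f = geno_f,
           thresholds = attr(scan, "thresholds"))
    })
    scan <- gwres$scan; qtl <- gwres$qtl; geno_f <- gwres$geno_f
    add_artifact({
      utils::write.table(scan, file.path(run, "gwas_scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      file.path(run, "gwas_scan.tsv")
    }, "06_gwas")
    add_artifact({
      jsonlite::write_json(gwres$thresholds, file.path(run, "fdr_thresholds.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      file.path(run, "fdr_thresholds.json")
    }, "06_gwas")
    add_artifact({
      utils::write.table(gwres$qtl %||% data.frame(),
                         file.path(run, "qtl_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      file.path(run, "qtl_clusters.tsv")
    }, "06_gwas")
    add_artifact({
      utils::write.table(association_summary(scan),
                         file.path(run, "association_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      file.path(run, "association_summary.tsv")
    }, "06_gwas")
    add_artifact({
      combos <- unique(scan[, c("trait", "coding")])
      qq <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        sel <- scan$trait == combos$trait[i] & scan$coding == combos$coding[i]
        cbind(trait = combos$trait[i], coding = combos$coding[i],
              qq_data(scan$pvalue[sel]))
      }))
      utils::write.table(qq, file.path(run, "qq_data.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      file.path(run, "qq_data.tsv")
    }, "06_gwas")
    add_artifact({
      pcs <- pca_population(geno_f, n_pc = 5)
      write.csv(data.frame(entry_id = rownames(pcs$scores), pcs$scores,
                           check.names = FALSE),
                file.path(run, "pca_scores.csv"), row.names = FALSE)
      file.path(run, "pca_scores.csv")
    }, "06_gwas")
  }

  # (7) CV benchmark -------------------------------------------------------
  cvres <- cvsum <- NULL
  if (want_gs && !is.null(dat$geno)) {
    cvout <- stage_cached(run, "07_cv", hash, function() {
      gmat <- geno_f %||% filter_markers(dat$geno)
      tl <- lapply(traits, function(tr) {
        v <- ra$RA_percent[ra$trait == tr]
        names(v) <- ra$entry_id[ra$trait == tr]
        v[names(v) %in% rownames(gmat)]
      })
      names(tl) <- traits
      plan <- make_folds(rownames(gmat), k = cv_cfg$k %||% 5L,
                         repeats = cv_cfg$repeats %||% 25L, seed = seed)
      res <- run_cv(tl, gmat, plan,
                    models = gs_cfg$models %||% c("rrblup", "bayesa", "rkhs", "ade"),
                    fixed_modes = gs_cfg$fixed_modes %||% c("none", "top_gwas_snp"),
                    gs_opts = gs_cfg)
      list(res = res, summary = summarize_cv(res))
    })
    cvres <- cvout$res; cvsum <- cvout$summary
    add_artifact({
      write.csv(cvres$cells, file.path(run, "cv_cells.csv"), row.names = FALSE)
      file.path(run, "cv_cells.csv")
    }, "07_cv")
    add_artifact({
      write.csv(cvsum$metrics, file.path(run, "cv_summary.csv"), row.names = FALSE)
      file.path(run, "cv_summary.csv")
    }, "07_cv")
    add_artifact({
      write.csv(cvsum$selection_frequency,
                file.path(run, "snp_selection_frequency.csv"), row.names = FALSE)
      file.path(run, "snp_selection_frequency.csv")
    }, "07_cv")
  }

  manifest_path <- file.path(run, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  pipe_log(run, "pipeline", "complete")
  invisible(list(geno = dat$geno, pheno = dat$pheno, derived = derived,
                 univariate = uni, heritability = h2_tab, multivariate = multi,
                 ra = ra, correlations = corr, scan = scan, qtl = qtl,
                 cv = cvres, cv_summary = cvsum, manifest_path = manifest_path))
}
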