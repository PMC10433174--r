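# Synthetic clonal populations: genotypes with block LD, augmented
# row-column field designs, multi-cycle true genetic values, and plot-level
# component-trait phenotypes.

#' Simulation configuration for a synthetic clonal trial
#'
#' Defaults emulate a second-stage clonal sugarcane trial: 432 test clones
#' genotyped at 10,435 biallelic pseudo-diploid SNPs on 10 chromosomes
#' (MAF >= 0.02), grown in an augmented row-column design with two replicates
#' of every test clone and two checks each repeated 17 times, over three crop
#' cycles (plant cane PC, first ratoon FR, second ratoon SR) with moderately
#' high entry-mean heritability and correlated clone effects across cycles.
#'
#' @param n_clones number of test clones.
#' @param n_checks number of check cultivars.
#' @param check_reps total plots per check across the trial.
#' @param n_snps total SNP count across all chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp physical length per chromosome (bp).
#' @param maf_range length-2 vector, range of simulated allele frequencies;
#'   must lie in (0, 0.5].
#' @param ld_block_size SNPs per linkage block (latent AR(1) copula; SNPs in
#'   a block share an allele frequency).
#' @param ld_rho target adjacent-SNP genotype correlation within a block, in
#'   `[0, 1)`; the latent copula correlation is inflated to `sin(rho*pi/2)`
#'   to offset discretization attenuation.
#' @param n_qtl number of causal SNPs.
#' @param dominance_fraction fraction of QTL carrying a dominance deviation.
#' @param cycle_h2 per-cycle target entry-mean heritability, recycled to the
#'   number of cycles.
#' @param cycle_genetic_corr K x K correlation matrix of clone genetic effects
#'   across cycles (symmetric, unit diagonal, PSD).
#' @param cycles cycle labels.
#' @param n_reps replicates of each test clone.
#' @param n_field_columns columns per replicate block in the field grid.
#' @param spatial_sd scale of replicate/row/column effects, in units of the
#'   per-trait genetic standard deviation.
#' @param check_shift per-check fixed mean shift, genetic-sd units.
#' @param resid_class_mult named residual-variance multipliers per population
#'   class; values other than 1 make the residual structure heterogeneous.
#' @param sp_sw_genetic_corr genetic correlation between stalk population and
#'   stalk weight (negative by default: heavy-stalk clones tiller less).
#' @param trait_params data.frame with one row per component trait (`trait`,
#'   `mean`, `g_sd`, `l1`, `l2`): trait mean on its natural scale, genetic SD,
#'   and loadings on the two latent marker-based genetic factors.
#' @param seed integer seed driving all randomness.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_clones = 432L,
                       n_checks = 2L,
                       check_reps = 17L,
                       n_snps = 10435L,
                       n_chromosomes = 10L,
                       chrom_length_bp = 6e7,
                       maf_range = c(0.02, 0.5),
                       ld_block_size = 10L,
                       ld_rho = 0.6,
                       n_qtl = 200L,
                       dominance_fraction = 0.2,
                       cycle_h2 = c(0.65, 0.65, 0.65),
                       cycle_genetic_corr = NULL,
                       cycles = c("PC", "FR", "SR"),
                       n_reps = 2L,
                       n_field_columns = 25L,
                       spatial_sd = 0.3,
                       check_shift = c(0.3, -0.3),
                       resid_class_mult = c(clone = 1, check = 0.75),
                       sp_sw_genetic_corr = -0.13,
                       trait_params = NULL,
                       seed = 1L) {
  K <- length(cycles)
  if (is.null(cycle_genetic_corr)) {
    cycle_genetic_corr <- matrix(0.7, K, K)
    diag(cycle_genetic_corr) <- 1
  }
  cycle_h2 <- rep_len(cycle_h2, K)
  if (is.null(trait_params)) {
    r <- sp_sw_genetic_corr
    trait_params <- data.frame(
      trait = c("SP", "SW", "brix", "pol", "fiber", "moisture"),
      mean  = c(95000, 1.10, 18.0, 15.5, 11.0, 70.0),
      g_sd  = c(12000, 0.16, 1.10, 1.20, 0.90, 1.50),
      l1    = c(1, r, 0.15, 0.15, 0.10, 0.10),
      l2    = c(0, sqrt(1 - r^2), 0.99, 0.99, -0.99, -0.99),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(
    n_clones = as.integer(n_clones), n_checks = as.integer(n_checks),
    check_reps = as.integer(check_reps), n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp, maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    n_qtl = as.integer(n_qtl), dominance_fraction = dominance_fraction,
    cycle_h2 = cycle_h2, cycle_genetic_corr = cycle_genetic_corr,
    cycles = cycles, n_reps = as.integer(n_reps),
    n_field_columns = as.integer(n_field_columns),
    spatial_sd = spatial_sd, check_shift = check_shift,
    resid_class_mult = resid_class_mult,
    sp_sw_genetic_corr = sp_sw_genetic_corr,
    trait_params = trait_params, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_clones, n_checks, n_snps, n_chromosomes, n_reps) < 1L))
      stop("configuration error: all counts must be positive")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("configuration error: maf_range must lie within (0, 0.5]")
    if (ld_rho < 0 || ld_rho >= 1)
      stop("configuration error: ld_rho must be in [0, 1)")
    if (n_qtl > n_snps)
      stop("configuration error: n_qtl exceeds n_snps")
    if (any(cycle_h2 <= 0) || any(cycle_h2 > 1))
      stop("configuration error: cycle_h2 must be in (0, 1]")
    C <- cycle_genetic_corr
    if (!isSymmetric(unname(C)) || any(abs(diag(C) - 1) > 1e-8))
      stop("configuration error: cycle_genetic_corr must be symmetric with unit diagonal")
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("configuration error: cycle_genetic_corr is not positive semidefinite")
    if (ld_rho > 0 && ld_block_size > ceiling(n_snps / n_chromosomes))
      stop("configuration error: ld_block_size exceeds per-chromosome SNP count")
  })
  invisible(cfg)
}

# Split n_snps across chromosomes as evenly as possible.
snps_per_chrom <- function(n_snps, n_chrom) {
  base <- n_snps %/% n_chrom
  extra <- n_snps %% n_chrom
  base + (seq_len(n_chrom) <= extra)
}

#' Simulate a pseudo-diploid genotype matrix with block LD
#'
#' Genotypes are drawn from a Gaussian copula: a latent AR(1) process with
#' correlation `ld_rho` within blocks of `ld_block_size` consecutive SNPs is
#' thresholded into Hardy-Weinberg genotype classes at each SNP's allele
#' frequency. SNPs whose realized minor-allele frequency falls below
#' `maf_range[1]` are redrawn (and, as a last resort, minimally edited) so the
#' returned panel contains no monomorphic or sub-threshold marker.
#'
#' @param cfg a [sim_config()].
#' @return clones x SNPs integer matrix in \{0,1,2\} of class
#'   `genotype_matrix`; SNP names are `"S{chr}_{pos}"` with strictly
#'   increasing positions per chromosome, and the map is attached as
#'   attribute `"map"`.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_clones
    per_chr <- snps_per_chrom(cfg$n_snps, cfg$n_chromosomes)
    cols <- vector("list", cfg$n_chromosomes)
    maps <- vector("list", cfg$n_chromosomes)
    for (chr in seq_len(cfg$n_chromosomes)) {
      m <- per_chr[chr]
      if (m == 0L) next
      pos <- sort(sample.int(cfg$chrom_length_bp, m))
      # SNPs in an LD block share one allele frequency (haplotype-block
      # reading): thresholds then line up and the latent correlation carries
      # through to the genotype scale with little attenuation
      blk <- if (cfg$ld_rho > 0) (seq_len(m) - 1L) %/% cfg$ld_block_size
             else seq_len(m) - 1L
      p_blk <- runif(max(blk) + 1L, cfg$maf_range[1], cfg$maf_range[2])
      p <- p_blk[blk + 1L]
      # latent AR(1) within blocks, independent across blocks; the latent
      # parameter is inflated as sin(rho*pi/2) so that after Hardy-Weinberg
      # thresholding the *genotype*-scale adjacent correlation comes out
      # close to ld_rho
      z <- matrix(rnorm(n * m), n, m)
      if (cfg$ld_rho > 0 && m > 1) {
        rl <- sin(cfg$ld_rho * pi / 2)
        for (j in 2:m) {
          if (blk[j] == blk[j - 1L]) {
            z[, j] <- rl * z[, j - 1L] + sqrt(1 - rl^2) * z[, j]
          }
        }
      }
      G <- threshold_hwe(z, p)
      G <- enforce_maf(G, p, cfg$maf_range)
      colnames(G) <- sprintf("S%d_%d", chr, pos)
      cols[[chr]] <- G
      maps[[chr]] <- data.frame(snp_id = colnames(G), chrom = chr, pos = pos,
                                stringsAsFactors = FALSE)
    }
    geno <- do.call(cbind, cols)
    rownames(geno) <- sprintf("CL%04d", seq_len(n))
    structure(geno, map = do.call(rbind, maps), class = "genotype_matrix")
  })
}

# Threshold latent normals into HWE genotype classes 0/1/2 at frequency p
# (p = alternate-allele frequency).
threshold_hwe <- function(z, p) {
  u <- pnorm(z)
  q0 <- rep((1 - p)^2, each = nrow(z))
  q1 <- rep((1 - p)^2 + 2 * p * (1 - p), each = nrow(z))
  G <- matrix(0L, nrow(z), ncol(z))
  G[u >= q0] <- 1L
  G[u >= q1] <- 2L
  G
}

# Redraw or minimally edit columns whose realized MAF is below the floor.
enforce_maf <- function(G, p, maf_range) {
  n <- nrow(G)
  need <- ceiling(maf_range[1] * 2 * n)
  for (try in 1:25) {
    af <- colMeans(G) / 2
    maf <- pmin(af, 1 - af)
    bad <- which(maf < maf_range[1] | maf == 0)
    if (!length(bad)) return(G)
    p2 <- runif(length(bad), max(maf_range[1] * 2, 0.05),
                max(maf_range[2], 0.1))
    G[, bad] <- threshold_hwe(matrix(rnorm(n * length(bad)), n), p2)
  }
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  for (j in which(maf < maf_range[1] | maf == 0)) {
    # deterministic fix: promote the first `need` reference-homozygotes
    idx <- which(G[, j] == (if (mean(G[, j]) / 2 > 0.5) 2L else 0L))[seq_len(need)]
    G[idx, j] <- 1L
  }
  G
}

#' SNP map of a genotype matrix
#'
#' @param geno genotype matrix; if no `"map"` attribute is present the map is
#'   parsed from column names.
#' @return data.frame with `snp_id`, `chrom`, `pos`.
#' @export
snp_map <- function(geno) {
  attr(geno, "map") %||% parse_snp_ids(colnames(geno))
}

#' Simulate an augmented row-column field design
#'
#' Every test clone appears once in each of `n_reps` replicates; each check
#' cultivar is repeated `check_reps` times in total, split as evenly as
#' possible across replicates. Plots are laid out on a grid of
#' `n_field_columns` columns per replicate and randomized within replicate.
#'
#' @param cfg a [sim_config()].
#' @return data.frame (class `field_design`) with columns `replicate`, `row`,
#'   `column`, `entry_id`, `population_class`.
#' @export
simulate_field_design <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 2L), {
    clones <- sprintf("CL%04d", seq_len(cfg$n_clones))
    checks <- sprintf("CHECK%d", seq_len(cfg$n_checks))
    out <- vector("list", cfg$n_reps)
    for (r in seq_len(cfg$n_reps)) {
      # checks split across replicates: earlier replicates take the remainder
      n_chk <- vapply(seq_len(cfg$n_checks), function(i) {
        base <- cfg$check_reps %/% cfg$n_reps
        base + as.integer(r <= cfg$check_reps %% cfg$n_reps)
      }, 1L)
      entries <- c(clones, rep(checks, times = n_chk))
      cls <- c(rep("clone", length(clones)),
               rep(paste0("check", seq_len(cfg$n_checks)), times = n_chk))
      o <- sample.int(length(entries))
      entries <- entries[o]; cls <- cls[o]
      ncol_f <- min(cfg$n_field_columns, length(entries))
      idx <- seq_along(entries) - 1L
      out[[r]] <- data.frame(
        replicate = r,
        row = idx %/% ncol_f + 1L,
        column = idx %% ncol_f + 1L,
        entry_id = entries,
        population_class = cls,
        stringsAsFactors = FALSE
      )
    }
    design <- do.call(rbind, out)
    rownames(design) <- NULL
    class(design) <- c("field_design", "data.frame")
    design
  })
}

#' Simulate true multi-cycle genetic values
#'
#' Causal architecture: `n_qtl` SNPs are split between two latent genetic
#' factors. Factor scores are marker sums of centered dosages times additive
#' effects, plus dominance deviations on heterozygotes for a
#' `dominance_fraction` of QTL. Per-QTL effects are drawn jointly across
#' cycles with correlation `cycle_genetic_corr`, so clone genetic values are
#' genetically correlated across PC/FR/SR. Component-trait genetic values are
#' linear combinations of the two standardized factors scaled by each trait's
#' genetic SD (`trait_params`), which induces the configured (negative by
#' default) SP-SW genetic correlation.
#'
#' @param geno genotype matrix from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list of class `true_values`: `values` (one row per entry x cycle
#'   with factor scores and per-trait genetic values; checks get fixed draws),
#'   `qtl` (positions/effects), `genetic_var` (realized clone genetic variance
#'   per cycle x trait, used to calibrate phenotype noise).
#' @export
simulate_true_values <- function(geno, cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- nrow(geno)
    K <- length(cfg$cycles)
    C <- cfg$cycle_genetic_corr
    Lc <- chol_psd(C)
    qtl_idx <- sort(sample.int(ncol(geno), cfg$n_qtl))
    half <- ceiling(cfg$n_qtl / 2)
    fac_of <- rep(2L, cfg$n_qtl); fac_of[seq_len(half)] <- 1L
    fac_of <- fac_of[sample.int(cfg$n_qtl)]
    n_dom <- round(cfg$dominance_fraction * cfg$n_qtl)
    is_dom <- rep(FALSE, cfg$n_qtl)
    if (n_dom > 0) is_dom[sample.int(cfg$n_qtl, n_dom)] <- TRUE

    W <- scale(geno[, qtl_idx, drop = FALSE], center = TRUE, scale = FALSE)
    H <- (geno[, qtl_idx, drop = FALSE] == 1L) + 0
    H <- scale(H, center = TRUE, scale = FALSE)

    # per-QTL cycle-correlated effects: rows QTL, cols cycles
    alpha <- matrix(rnorm(cfg$n_qtl * K), cfg$n_qtl, K) %*% Lc
    delta <- matrix(rnorm(cfg$n_qtl * K), cfg$n_qtl, K) %*% Lc
    delta[!is_dom, ] <- 0

    factors <- array(0, dim = c(n, K, 2),
                     dimnames = list(rownames(geno), cfg$cycles, NULL))
    for (f in 1:2) {
      sel <- fac_of == f
      Gf <- W[, sel, drop = FALSE] %*% alpha[sel, , drop = FALSE] +
        0.6 * (H[, sel, drop = FALSE] %*% delta[sel, , drop = FALSE])
      # standardize each cycle so trait scaling is exact
      Gf <- sweep(Gf, 2, apply(Gf, 2, sd), "/")
      factors[, , f] <- Gf
    }

    tp <- cfg$trait_params
    norm <- sqrt(tp$l1^2 + tp$l2^2)
    rows <- vector("list", K)
    for (k in seq_len(K)) {
      vals <- data.frame(entry_id = rownames(geno), cycle = cfg$cycles[k],
                         population_class = "clone",
                         G1 = factors[, k, 1], G2 = factors[, k, 2],
                         stringsAsFactors = FALSE)
      for (t in seq_len(nrow(tp))) {
        vals[[tp$trait[t]]] <- tp$g_sd[t] *
          (tp$l1[t] * vals$G1 + tp$l2[t] * vals$G2) / norm[t]
      }
      rows[[k]] <- vals
    }
    values <- do.call(rbind, rows)

    # checks: fixed cultivar values, constant across replicates
    checks <- sprintf("CHECK%d", seq_len(cfg$n_checks))
    chk_fac <- array(rnorm(cfg$n_checks * K * 2), c(cfg$n_checks, K, 2))
    chk_rows <- vector("list", K)
    for (k in seq_len(K)) {
      vals <- data.frame(entry_id = checks, cycle = cfg$cycles[k],
                         population_class = paste0("check", seq_len(cfg$n_checks)),
                         G1 = chk_fac[, k, 1], G2 = chk_fac[, k, 2],
                         stringsAsFactors = FALSE)
      for (t in seq_len(nrow(tp))) {
        vals[[tp$trait[t]]] <- tp$g_sd[t] *
          (tp$l1[t] * vals$G1 + tp$l2[t] * vals$G2) / norm[t]
      }
      chk_rows[[k]] <- vals
    }
    values <- rbind(values, do.call(rbind, chk_rows))
    rownames(values) <- NULL

    gv <- sapply(tp$trait, function(tr) {
      sapply(cfg$cycles, function(cy) {
        var(values[[tr]][values$cycle == cy & values$population_class == "clone"])
      })
    })
    qtl <- data.frame(snp_id = colnames(geno)[qtl_idx], factor = fac_of,
                      dominant = is_dom, stringsAsFactors = FALSE)
    qtl <- cbind(qtl, setNames(as.data.frame(alpha),
                               paste0("alpha_", cfg$cycles)))
    structure(list(values = values, qtl = qtl, genetic_var = gv,
                   cycles = cfg$cycles),
              class = "true_values")
  })
}

chol_psd <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(v) * t(e$vectors)))
}

#' Simulate plot-level component-trait phenotypes
#'
#' Plot value = trait mean + replicate + row-within-replicate +
#' column-within-replicate effects + fixed population-class shift + entry
#' genetic value + residual. The residual variance for test clones is
#' calibrated per cycle as `n_reps * sigma_g^2 * (1 - h2) / h2`, so the
#' entry-mean heritability `sigma_g^2 / (sigma_g^2 + sigma_e^2 / n_reps)`
#' equals `cycle_h2`. Check classes get their own residual scale
#' (`resid_class_mult`), giving a heterogeneous diagonal residual structure.
#'
#' @param design from [simulate_field_design()].
#' @param truth from [simulate_true_values()].
#' @param cfg a [sim_config()].
#' @return data.frame (class `plot_phenotypes`), one row per plot per cycle:
#'   `cycle, replicate, row, column, entry_id, population_class, SP, SW,
#'   brix, pol, fiber, moisture`.
#' @export
simulate_phenotypes <- function(design, truth, cfg) {
  validate_sim_config(cfg)
  miss <- setdiff(design$entry_id, unique(truth$values$entry_id))
  if (length(miss)) {
    stop("truth does not cover design entries: ", paste(head(miss, 5), collapse = ", "))
  }
  with_seed(derive_seed(cfg$seed, 4L), {
    tp <- cfg$trait_params
    K <- length(cfg$cycles)
    out <- vector("list", K)
    for (k in seq_len(K)) {
      cy <- cfg$cycles[k]
      tv <- truth$values[truth$values$cycle == cy, ]
      d <- design
      d$cycle <- cy
      for (t in seq_len(nrow(tp))) {
        tr <- tp$trait[t]
        g <- tv[[tr]][match(d$entry_id, tv$entry_id)]
        scale_t <- tp$g_sd[t]
        # field effects: independent draws per trait, same layout
        reps <- unique(d$replicate)
        re <- setNames(rnorm(length(reps), 0, cfg$spatial_sd * scale_t), reps)
        rkey <- paste(d$replicate, d$row); ckey <- paste(d$replicate, d$column)
        rl <- unique(rkey); cl <- unique(ckey)
        rowe <- setNames(rnorm(length(rl), 0, cfg$spatial_sd * scale_t), rl)
        cole <- setNames(rnorm(length(cl), 0, cfg$spatial_sd * scale_t), cl)
        shift <- rep(0, nrow(d))
        for (i in seq_len(cfg$n_checks)) {
          shift[d$population_class == paste0("check", i)] <-
            cfg$check_shift[min(i, length(cfg$check_shift))] * scale_t
        }
        sg2 <- truth$genetic_var[cy, tr]
        h2 <- cfg$cycle_h2[k]
        se2_clone <- cfg$n_reps * sg2 * (1 - h2) / h2
        mult <- rep(1, nrow(d))
        rcm <- cfg$resid_class_mult
        for (nmc in names(rcm)) {
          if (nmc == "check") {
            mult[startsWith(d$population_class, "check")] <- rcm[[nmc]]
          } else {
            mult[d$population_class == nmc] <- rcm[[nmc]]
          }
        }
        eps <- rnorm(nrow(d), 0, sqrt(se2_clone * mult))
        d[[tr]] <- tp$mean[t] + re[as.character(d$replicate)] + rowe[rkey] +
          cole[ckey] + shift + g + eps
        if (tr %in% c("SP", "SW")) d[[tr]] <- pmax(d[[tr]], 0)
      }
      out[[k]] <- d
    }
    pheno <- do.call(rbind, out)
    pheno <- pheno[, c("cycle", "replicate", "row", "column", "entry_id",
                       "population_class", tp$trait)]
    rownames(pheno) <- NULL
    class(pheno) <- c("plot_phenotypes", "data.frame")
    pheno
  })
}

#' Simulate a complete clonal trial
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_field_design()], [simulate_true_values()] and
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @return list with `geno`, `design`, `truth`, `pheno`, `cfg`.
#' @export
sim_population <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  design <- simulate_field_design(cfg)
  truth <- simulate_true_values(geno, cfg)
  pheno <- simulate_phenotypes(design, truth, cfg)
  list(geno = geno, design = design, truth = truth, pheno = pheno, cfg = cfg)
}
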