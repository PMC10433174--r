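# Kinship-corrected single-marker association scans on clone-level traits:
# marker QC, pseudo-diploid gene-action codings, leave-one-chromosome-out
# relationship matrices, P3D mixed-model tests, Benjamini-Hochberg
# thresholds, QQ data, and QTL clustering by physical window.

#' Maximum-genotype-frequency threshold
#'
#' `1 - 5/N` for a panel of `N` clones: a marker is kept only if its most
#' frequent genotype class leaves at least five clones in the other classes.
#'
#' @param n_clones panel size N.
#' @return threshold in (0, 1).
#' @examples
#' max_genotype_freq_threshold(432)  # 0.988 (3 dp)
#' @export
max_genotype_freq_threshold <- function(n_clones) {
  stopifnot(n_clones > 5)
  1 - 5 / n_clones
}

#' Marker quality-control filter
#'
#' Retains SNPs that are (i) biallelic with exactly two observed alleles,
#' (ii) have minor-allele frequency >= `maf_min`, and (iii) whose most
#' frequent genotype class has frequency <= `max_genotype_frequency`
#' (default `1 - 5/N`). A per-rule attrition report is attached as attribute
#' `"filter_report"`.
#'
#' @param geno clones x SNPs matrix in \{0,1,2\} (NAs allowed).
#' @param maf_min minimum minor-allele frequency (default 0.02).
#' @param max_genotype_frequency cap on the most frequent genotype class;
#'   `NULL` computes `1 - 5/N` from the panel size.
#' @param biallelic_only drop markers with more than two observed alleles
#'   (values outside \{0,1,2\} are treated as a third allele).
#' @return filtered genotype matrix with the same attributes.
#' @export
filter_markers <- function(geno, maf_min = 0.02, max_genotype_frequency = NULL,
                           biallelic_only = TRUE) {
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  M <- unclass(geno)
  N <- nrow(M)
  if (is.null(max_genotype_frequency))
    max_genotype_frequency <- max_genotype_freq_threshold(N)
  if (max_genotype_frequency <= 0 || max_genotype_frequency >= 1)
    stop("max_genotype_frequency must be in (0, 1)")
  ok_domain <- apply(M, 2, function(x) all(is.na(x) | x %in% 0:2))
  if (biallelic_only && any(!ok_domain)) {
    drop_bi <- !ok_domain
  } else {
    if (any(!ok_domain)) stop("genotypes outside {0,1,2} present")
    drop_bi <- rep(FALSE, ncol(M))
  }
  af <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  gf <- apply(M, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    max(tabulate(x + 1L, nbins = 3L)) / length(x)
  })
  fail_maf <- !drop_bi & maf < maf_min
  fail_gf <- !drop_bi & gf > max_genotype_frequency
  keep <- !drop_bi & !fail_maf & !fail_gf
  report <- data.frame(
    rule = c("input", "non_biallelic", "maf_below_min",
             "genotype_frequency_above_max", "retained"),
    n = c(ncol(M), sum(drop_bi), sum(fail_maf), sum(fail_gf), sum(keep))
  )
  if (!any(keep)) {
    stop("no markers survive filtering; attrition: ",
         paste(sprintf("%s=%d", report$rule, report$n), collapse = ", "))
  }
  out <- M[, keep, drop = FALSE]
  map <- attr(geno, "map")
  if (!is.null(map)) attr(out, "map") <- map[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  class(out) <- class(geno)
  out
}

#' Encode a pseudo-diploid marker under a gene-action model
#'
#' * `additive`: dosage as-is \{0,1,2\}.
#' * `1-dom-ref`: carrier of at least one alternate allele, \{0,1,1\} — the
#'   alternate allele acts dominantly over reference.
#' * `1-dom-alt`: carrier of at least one reference allele, \{1,1,0\} — the
#'   reference allele acts dominantly over alternate.
#'
#' @param x genotype vector in \{0,1,2\}.
#' @param coding one of `"additive"`, `"1-dom-ref"`, `"1-dom-alt"`.
#' @return numeric design vector.
#' @export
encode_gene_action <- function(x, coding = c("additive", "1-dom-ref", "1-dom-alt")) {
  coding <- match.arg(coding)
  if (any(!is.na(x) & !(x %in% 0:2))) stop("genotypes outside {0,1,2}")
  switch(coding,
         "additive" = as.numeric(x),
         "1-dom-ref" = as.numeric(x >= 1),
         "1-dom-alt" = as.numeric(x <= 1))
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome, the additive relationship matrix is built from all
#' markers *not* on that chromosome, so the polygenic correction in the scan
#' never absorbs the tested marker's own signal. With a single chromosome the
#' whole-genome matrix is returned (with a warning).
#'
#' @param geno genotype matrix with parseable SNP names or a `"map"` attribute.
#' @return named list of clone x clone matrices, one per chromosome
#'   (`"1"`, `"2"`, ...).
#' @export
loco_kinship <- function(geno) {
  map <- snp_map(geno)
  chroms <- sort(unique(map$chrom))
  if (length(chroms) < 2) {
    warning("single chromosome: using the whole-genome kinship for all tests")
    K <- additive_relationship(geno)
    return(setNames(list(K), as.character(chroms)))
  }
  out <- lapply(chroms, function(ch) {
    additive_relationship(unclass(geno)[, map$chrom != ch, drop = FALSE])
  })
  names(out) <- as.character(chroms)
  out
}

#' Mixed-model single-marker scan (P3D)
#'
#' For each chromosome the null model `y = mu + g + e`,
#' `g ~ N(0, su2 K_loco)`, is fit once by REML; with those variance
#' components fixed, every marker on the chromosome is tested by generalized
#' least squares on the whitened data (a two-sided Wald/t test on the marker
#' coefficient, which with `K = I` reduces exactly to ordinary-regression
#' output). Markers collinear with the intercept after coding get `p = 1`
#' and are flagged.
#'
#' @param trait named numeric vector of clone values (names matching
#'   `rownames(geno)`).
#' @param geno genotype matrix in \{0,1,2\}.
#' @param coding gene-action coding(s) to scan; see [encode_gene_action()].
#' @param kinships optional list from [loco_kinship()] (or a single matrix
#'   used for all chromosomes, e.g. `diag(n)` for an unadjusted scan);
#'   computed from `geno` when `NULL`. Entries may also be precomputed
#'   `eigen()` results (lists with `values`/`vectors`), which saves the
#'   decomposition when many scans share kinships (permutation studies,
#'   cross-validation).
#' @param trait_name label stored in the output.
#' @return data.frame of class `gwas_scan`: `snp_id`, `chrom`, `pos`,
#'   `coding`, `trait`, `beta`, `stat`, `pvalue`, `neglog10p`, `collinear`.
#' @export
gwas_scan <- function(trait, geno, coding = "additive", kinships = NULL,
                      trait_name = "trait") {
  M <- impute_genotypes(unclass(geno))
  if (!is.null(names(trait))) {
    common <- intersect(names(trait), rownames(M))
    if (length(common) < 3) stop("trait and genotype clones do not align")
    trait <- trait[common]
    M <- M[common, , drop = FALSE]
  } else if (length(trait) != nrow(M)) {
    stop("trait and genotype clones do not align")
  }
  if (sd(trait) == 0) stop("zero-variance trait")
  map <- snp_map(geno)
  if (is.null(kinships)) kinships <- loco_kinship(M)
  as_eigenK <- function(x) {
    if (is.list(x) && !is.null(x$vectors) && !is.null(x$values)) return(x)
    eigen((x + t(x)) / 2, symmetric = TRUE)
  }
  single_K <- is.matrix(kinships) ||
    (is.list(kinships) && !is.null(kinships$vectors))
  n <- length(trait)
  X <- matrix(1, n, 1)
  out <- vector("list", 0)
  chroms <- sort(unique(map$chrom))
  eK_single <- if (single_K) as_eigenK(kinships) else NULL
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    eK <- if (single_K) eK_single else {
      Kc <- kinships[[as.character(ch)]]
      if (is.null(Kc)) stop("no kinship supplied for chromosome ", ch)
      as_eigenK(Kc)
    }
    null <- reml_kernel(trait, X = X, eK = eK)
    w <- 1 / (pmax(eK$values, 0) + null$delta)
    sw <- sqrt(w)
    U <- eK$vectors
    ys <- sw * drop(crossprod(U, trait))
    Xs <- sw * crossprod(U, X)
    for (cd in coding) {
      Menc <- apply(M[, sel, drop = FALSE], 2, encode_gene_action, coding = cd)
      Ms <- sw * crossprod(U, Menc)
      # residualize on the whitened intercept
      XtX <- crossprod(Xs)
      bX <- solve(XtX, crossprod(Xs, cbind(ys, Ms)))
      yr <- ys - drop(Xs %*% bX[, 1])
      Mr <- Ms - Xs %*% bX[, -1, drop = FALSE]
      sxx <- colSums(Mr^2)
      collinear <- sxx < 1e-10 * n
      sxx[collinear] <- NA
      bhat <- colSums(Mr * yr) / sxx
      df <- n - ncol(X) - 1L
      rss <- pmax(sum(yr^2) - bhat^2 * sxx, 0)
      se <- sqrt(rss / df / sxx)
      tt <- bhat / se
      pv <- 2 * pt(-abs(tt), df)
      pv[collinear] <- 1
      out[[length(out) + 1L]] <- data.frame(
        snp_id = map$snp_id[sel], chrom = ch, pos = map$pos[sel],
        coding = cd, trait = trait_name,
        beta = bhat, stat = tt, pvalue = pv,
        neglog10p = -log10(pmax(pv, .Machine$double.xmin)),
        collinear = collinear,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gwas_scan", "data.frame")
  res
}

#' Benjamini-Hochberg threshold and significant set
#'
#' Step-up procedure at level `q`: the p-value threshold is the largest
#' p-value declared significant (0 when nothing is).
#'
#' @param pvalues p-values in (0, 1].
#' @param q FDR level (default 0.1).
#' @return list: `p_threshold`, `significant` (logical, input order),
#'   `n_significant`.
#' @export
fdr_threshold <- function(pvalues, q = 0.1) {
  if (!length(pvalues)) stop("empty p-value set")
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must be in (0, 1]")
  sig <- p.adjust(pvalues, method = "BH") <= q
  list(p_threshold = if (any(sig)) max(pvalues[sig]) else 0,
       significant = sig,
       n_significant = sum(sig))
}

#' Flag significant markers per trait x coding at an FDR level
#'
#' Applies [fdr_threshold()] separately within every trait x coding
#' combination of a scan table.
#'
#' @param scan a [gwas_scan()] result (rows from several traits/codings may
#'   be concatenated).
#' @param q FDR level.
#' @return `scan` with a `significant` column; per-combination thresholds
#'   attached as attribute `"thresholds"` (data.frame `trait`, `coding`,
#'   `p_threshold`, `n_significant`).
#' @export
apply_fdr <- function(scan, q = 0.1) {
  scan$significant <- FALSE
  combos <- unique(scan[, c("trait", "coding")])
  thr <- cbind(combos, p_threshold = NA_real_, n_significant = 0L)
  for (i in seq_len(nrow(combos))) {
    sel <- scan$trait == combos$trait[i] & scan$coding == combos$coding[i]
    f <- fdr_threshold(scan$pvalue[sel], q = q)
    scan$significant[sel] <- f$significant
    thr$p_threshold[i] <- f$p_threshold
    thr$n_significant[i] <- f$n_significant
  }
  attr(scan, "thresholds") <- thr
  scan
}

#' Cluster significant SNPs into putative QTL by physical window
#'
#' Single-linkage within chromosome: consecutive SNPs (by position) at most
#' `window` bp apart join the same cluster; a gap strictly greater than
#' `window` starts a new one. The peak SNP is the smallest p-value, ties
#' broken by lower position.
#'
#' @param snp_ids SNP identifiers `"S{chr}_{pos}"`.
#' @param pvalues optional p-values aligned with `snp_ids` (used for peaks).
#' @param window clustering window in bp (default 5 Mb).
#' @return data.frame, one row per QTL: `chrom`, `n_snps`, `start`, `end`,
#'   `span_bp`, `peak_snp`, `peak_p`, `members` (comma-joined SNP IDs).
#' @export
cluster_qtl <- function(snp_ids, pvalues = NULL, window = 5e6) {
  if (!length(snp_ids)) {
    return(data.frame(chrom = integer(), n_snps = integer(), start = double(),
                      end = double(), span_bp = double(), peak_snp = character(),
                      peak_p = double(), members = character(),
                      stringsAsFactors = FALSE))
  }
  map <- parse_snp_ids(snp_ids)
  map$p <- if (is.null(pvalues)) NA_real_ else pvalues
  map <- map[order(map$chrom, map$pos), ]
  out <- list()
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    gap <- c(0, diff(m$pos))
    cl <- cumsum(gap > window)
    for (g in unique(cl)) {
      mm <- m[cl == g, ]
      peak <- if (all(is.na(mm$p))) mm[1, ] else {
        mm[order(mm$p, mm$pos), ][1, ]
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, n_snps = nrow(mm), start = min(mm$pos), end = max(mm$pos),
        span_bp = max(mm$pos) - min(mm$pos),
        peak_snp = peak$snp_id, peak_p = peak$p,
        members = paste(mm$snp_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate marker-trait associations by p-value tier
#'
#' Per-trait counts of associated markers at the conventional reporting
#' tiers (p <= 1e-3 and p <= 1e-4, a marker counted once across codings),
#' the number of distinct chromosomes involved, and — when significance
#' flags are present — the count of significant markers.
#'
#' @param scan a [gwas_scan()] result (optionally after [apply_fdr()]).
#' @return data.frame: `trait`, `n_p1e3`, `n_p1e4`, `n_significant`,
#'   `n_chrom`.
#' @export
association_summary <- function(scan) {
  out <- lapply(split(scan, scan$trait), function(s) {
    best <- tapply(s$pvalue, s$snp_id, min)     # best coding per marker
    hit <- names(best)[best <= 1e-3]
    chr <- unique(s$chrom[s$snp_id %in% hit])
    data.frame(
      trait = s$trait[1],
      n_p1e3 = sum(best <= 1e-3),
      n_p1e4 = sum(best <= 1e-4),
      n_significant = if ("significant" %in% names(s))
        length(unique(s$snp_id[s$significant])) else NA_integer_,
      n_chrom = length(chr),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed-vs-expected quantiles for a QQ plot
#'
#' @param pvalues non-empty p-value vector.
#' @return data.frame with `expected` and `observed` -log10(p), row i pairing
#'   the i-th smallest observed p-value with expected quantile `i/(m+1)`.
#' @export
qq_data <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value set")
  m <- length(pvalues)
  data.frame(
    expected = -log10(seq_len(m) / (m + 1)),
    observed = -log10(sort(pvalues))
  )
}
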