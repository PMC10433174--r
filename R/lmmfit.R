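# Mixed models for the clonal field trial: the univariate augmented
# row-column model (variance components, entry-mean heritability, BLUPs),
# the multivariate multi-cycle clone model (unstructured genetic and
# residual covariance across crop cycles), the genomic relationship matrix,
# and population PCA.

#' Fit the univariate field model by REML
#'
#' Model: response = intercept + population class (fixed) + replicate +
#' row-within-replicate + column-within-replicate + genotype (random,
#' `N(0, sigma_g^2)`) + residual, with one residual variance per population
#' class (heterogeneous diagonal R). Estimation uses Average-Information
#' REML with EM fallback ([reml_lvc()]).
#'
#' @param dat data.frame with columns `replicate`, `row`, `column`,
#'   `entry_id`, `population_class` and the response.
#' @param response name of the response column.
#' @param max_iter,tol passed to [reml_lvc()].
#' @return object of class `univariate_fit`: `varcomp` (named variances),
#'   `H2` (entry-mean heritability using the test-clone residual class and
#'   the realized clone replication), `blups` (data.frame `entry_id`, `blup`,
#'   `predicted` = intercept + class effect + BLUP), `loglik`, `trace`,
#'   `converged`, `n_rep`.
#' @export
fit_univariate <- function(dat, response, max_iter = 100L, tol = 1e-8) {
  req <- c("replicate", "row", "column", "entry_id", "population_class", response)
  if (!all(req %in% names(dat)))
    stop("missing columns: ", paste(setdiff(req, names(dat)), collapse = ", "))
  dat <- dat[is.finite(dat[[response]]), , drop = FALSE]
  y <- dat[[response]]
  n <- length(y)
  f_rep <- factor(dat$replicate)
  f_row <- factor(paste(dat$replicate, dat$row, sep = ":"))
  f_col <- factor(paste(dat$replicate, dat$column, sep = ":"))
  f_ent <- factor(dat$entry_id)
  f_cls <- factor(dat$population_class)
  X <- if (nlevels(f_cls) > 1) model.matrix(~f_cls) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Zs <- list(replicate = f_rep, row = f_row, col = f_col, genotype = f_ent)
  Zs <- Zs[vapply(Zs, nlevels, 1L) >= 2L]
  Zm <- lapply(Zs, function(f) model.matrix(~0 + f))
  Qs <- lapply(Zm, tcrossprod)
  q_eff <- vapply(Zs, nlevels, 1L)
  for (cl in levels(f_cls)) {
    Qs[[paste0("resid_", cl)]] <- diag(as.numeric(f_cls == cl))
    q_eff <- c(q_eff, sum(f_cls == cl))
  }
  vy <- var(y)
  init <- rep(vy / 4, length(Qs))
  names(init) <- names(Qs)
  init[grep("^resid_", names(Qs))] <- vy / 2
  fit <- reml_lvc(y, X, Qs, q_eff = q_eff, init = init,
                  max_iter = max_iter, tol = tol)
  if (!fit$converged && length(fit$trace) >= max_iter)
    warning("REML did not reach the tolerance within ", max_iter,
            " iterations (loglik trace attached)")
  theta <- fit$theta
  # BLUPs for the genotype term
  ug <- theta[["genotype"]] * crossprod(Zm[["genotype"]], fit$Py)
  blup <- setNames(drop(ug), levels(f_ent))
  # fixed-effect GLS estimates at the converged variances
  ev <- lvc_eval(theta, y, X, Qs)
  bhat <- solve(crossprod(X, ev$Vi %*% X), crossprod(X, ev$Vi %*% y))
  cls_of <- tapply(as.character(f_cls), f_ent, function(z) z[1])
  Xe <- if (nlevels(f_cls) > 1)
    model.matrix(~factor(cls_of, levels = levels(f_cls)))
  else matrix(1, nlevels(f_ent), 1)
  predicted <- drop(Xe %*% bhat) + blup
  clone_cls <- names(which.max(table(f_cls)))   # test-clone class
  n_rep <- mean(table(f_ent[f_cls == clone_cls]))
  H2 <- heritability(theta[["genotype"]], theta[[paste0("resid_", clone_cls)]],
                     n_rep = n_rep)
  structure(list(
    varcomp = theta,
    H2 = H2,
    blups = data.frame(entry_id = levels(f_ent), blup = blup,
                       predicted = predicted,
                       population_class = cls_of[levels(f_ent)],
                       stringsAsFactors = FALSE, row.names = NULL),
    fixef = setNames(drop(bhat), colnames(X)),
    loglik = fit$loglik, trace = fit$trace, converged = fit$converged,
    n_rep = n_rep, response = response
  ), class = "univariate_fit")
}

#' Entry-mean heritability
#'
#' `H2 = sigma_g2 / (sigma_g2 + sigma_e2 / n_rep)`: the fraction of
#' entry-mean variance attributable to genotype, with `n_rep` replicates per
#' entry.
#'
#' @param sigma_g2 genotypic variance (>= 0).
#' @param sigma_e2 residual variance (>= 0).
#' @param n_rep number of replications per entry (>= 1); 2 in a standard
#'   two-replicate clonal trial.
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(172.69, 210.40, n_rep = 2)  # ~0.62
#' @export
heritability <- function(sigma_g2, sigma_e2, n_rep = 2) {
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0, n_rep >= 1)
  if (sigma_g2 + sigma_e2 == 0)
    stop("heritability undefined: both variance components are zero")
  sigma_g2 / (sigma_g2 + sigma_e2 / n_rep)
}

#' Fit the multivariate multi-cycle clone model
#'
#' Stacked model `y = X b + Z u + e` across K crop cycles: per-cycle fixed
#' effects (intercept, or intercept + population class), clone effects
#' `u ~ N(0, U (x) I_c)` with unstructured K x K genetic covariance `U`, and
#' plot residuals correlated across cycles, `e_plot ~ N(0, E)` with
#' unstructured K x K `E` (ratoon crops regrow from the same stubble, so a
#' plot is the repeated unit across cycles). Estimated by an EM algorithm on
#' the exact marginal likelihood; the trace is monotone non-decreasing.
#' Final `U`/`E` are projected to the nearest PSD matrix (with a warning) if
#' numerically indefinite.
#'
#' @param dat long data.frame: `cycle`, `replicate`, `row`, `column`,
#'   `entry_id`, `population_class`, and the response column.
#' @param response response column name.
#' @param cycles cycle labels in order (plant cane first).
#' @param fixed `"class"` (per-cycle intercept + population class, default)
#'   or `"intercept"`.
#' @param max_iter,tol EM controls.
#' @return object of class `multivariate_fit`: `U`, `E`,
#'   `genetic_correlation`, `blups` (long data.frame `entry_id`, `cycle`,
#'   `trait`, `value` of predicted clone values = fixed part + BLUP),
#'   `u` (entry x cycle BLUP matrix), `trace`, `converged`.
#' @export
fit_multivariate <- function(dat, response, cycles = c("PC", "FR", "SR"),
                             fixed = c("class", "intercept"),
                             max_iter = 1000L, tol = 1e-8) {
  fixed <- match.arg(fixed)
  K <- length(cycles)
  if (K < 2) stop("need at least two cycles")
  req <- c("cycle", "replicate", "row", "column", "entry_id",
           "population_class", response)
  if (!all(req %in% names(dat)))
    stop("missing columns: ", paste(setdiff(req, names(dat)), collapse = ", "))
  dat <- dat[dat$cycle %in% cycles, , drop = FALSE]
  key <- paste(dat$replicate, dat$row, dat$column, sep = ":")
  Y <- tapply(dat[[response]], list(key, factor(dat$cycle, levels = cycles)),
              identity)
  meta <- dat[!duplicated(key), c("entry_id", "population_class")]
  rownames(meta) <- key[!duplicated(key)]
  meta <- meta[rownames(Y), ]
  keep <- complete.cases(Y)
  if (!all(keep)) {
    warning(sum(!keep), " plot(s) without all ", K, " cycles dropped")
    Y <- Y[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  ent <- factor(meta$entry_id)
  cls <- factor(meta$population_class)
  Xp <- if (fixed == "class" && nlevels(cls) > 1) model.matrix(~cls)
        else matrix(1, nrow(Y), 1)
  p <- ncol(Xp)
  n_plot <- nrow(Y)
  ents <- levels(ent)
  c_n <- length(ents)
  idx_of <- split(seq_len(n_plot), ent)

  # initial values from between/within clone mean decomposition
  cm <- apply(Y, 2, function(col) tapply(col, ent, mean))
  U <- cov(cm) * 0.5
  E <- cov(Y - cm[as.integer(ent), , drop = FALSE]) + diag(1e-6 * mean(diag(cov(Y))), K)
  U <- nearest_psd(U, 1e-8)
  B <- matrix(0, p, K)   # fixed effects, column per cycle

  # clones grouped by replication count: all clones with the same number of
  # plots share the posterior gain and covariance matrices, so the E-step is
  # a handful of matrix products per group instead of a per-clone loop
  na_of <- lengths(idx_of)
  groups <- sort(unique(na_of))
  ent_i <- as.integer(ent)

  prev_ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Einv <- solve(E)
    W <- Y - Xp %*% B                        # residuals from fixed part
    RS <- rowsum(W, ent_i)                   # per-clone residual sums R_a
    Uhat <- matrix(0, c_n, K)
    ldE <- as.numeric(determinant(E, logarithm = TRUE)$modulus)
    ll <- -0.5 * sum((W %*% Einv) * W)
    Osum_U <- Osum_E <- matrix(0, K, K)
    for (na in groups) {
      ga <- which(na_of == na)
      Minv <- solve(E / na + U)
      G <- U %*% Minv                        # posterior gain
      Om <- U - G %*% U                      # posterior covariance Omega
      A <- Einv %*% Om %*% Einv
      Rg <- RS[ga, , drop = FALSE]
      Uhat[ga, ] <- (Rg / na) %*% t(G)
      # marginal loglik: quadratic = sum_j w'E^-1 w - R'E^-1 Omega E^-1 R,
      # with Omega = (U^-1 + na E^-1)^-1 = U - U(E/na+U)^-1 U
      ll <- ll + 0.5 * sum((Rg %*% A) * Rg)
      ld <- (na - 1) * ldE +
        as.numeric(determinant(E + na * U, logarithm = TRUE)$modulus)
      ll <- ll - 0.5 * length(ga) * ld
      Osum_U <- Osum_U + length(ga) * Om
      Osum_E <- Osum_E + length(ga) * na * Om
    }
    trace <- c(trace, ll)
    # M-step: U, E, B
    Unew <- (crossprod(Uhat) + Osum_U) / c_n
    Rmat <- W - Uhat[ent_i, , drop = FALSE]
    Enew <- (crossprod(Rmat) + Osum_E) / n_plot
    # fixed effects given posterior means (ECM step): E^-1 factors out of the
    # normal equations, so B = (X'X)^-1 X'(Y - U_rows)
    Bnew <- solve(crossprod(Xp), crossprod(Xp, Y - Uhat[ent_i, , drop = FALSE]))
    U <- nearest_psd(Unew, 0)
    E <- Enew
    B <- Bnew
    if (it > 1 && abs(ll - prev_ll) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  if (!converged)
    warning("multivariate EM did not reach the tolerance within ", max_iter,
            " iterations")
  if (min(eigen(U, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    warning("genetic covariance projected to nearest PSD")
    U <- nearest_psd(U)
  }
  if (min(eigen(E, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    warning("residual covariance projected to nearest PSD")
    E <- nearest_psd(E)
  }
  dimnames(U) <- dimnames(E) <- list(cycles, cycles)
  sdU <- sqrt(pmax(diag(U), 1e-300))
  genetic_correlation <- U / tcrossprod(sdU)
  rownames(Uhat) <- ents
  colnames(Uhat) <- cycles
  # predicted clone values: per-cycle fixed part for the entry's class + BLUP
  cls_of <- tapply(as.character(cls), ent, function(z) z[1])
  Xe <- if (ncol(Xp) > 1)
    model.matrix(~factor(cls_of, levels = levels(cls))) else matrix(1, c_n, 1)
  Fit <- Xe %*% B + Uhat
  blups <- data.frame(
    entry_id = rep(ents, K),
    cycle = rep(cycles, each = c_n),
    trait = response,
    value = as.vector(Fit),
    stringsAsFactors = FALSE
  )
  structure(list(U = U, E = E, genetic_correlation = genetic_correlation,
                 blups = blups, u = Uhat, fixef = B, trace = trace,
                 converged = converged, cycles = cycles, response = response),
            class = "multivariate_fit")
}

#' Genomic additive relationship matrix (VanRaden method 1)
#'
#' Centers each SNP column by twice its allele frequency and scales by
#' `2 * sum(p(1-p))`: `K = W W' / c`. Pseudo-diploid dosages \{0,1,2\} are
#' expected; missing entries are imputed with the column mean; monomorphic
#' SNPs are excluded from both numerator and denominator with a warning.
#'
#' @param geno clones x SNPs matrix in \{0,1,2\} (NAs allowed).
#' @return clone x clone relationship matrix with attribute `"allele_freq"`.
#' @export
additive_relationship <- function(geno) {
  M <- impute_genotypes(unclass(geno))
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the relationship matrix")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
  }
  W <- sweep(M, 2, 2 * p)
  c0 <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / c0
  attr(K, "allele_freq") <- p
  K
}

#' Principal components of the marker panel
#'
#' For a genotype matrix, columns are centered and the SVD taken; scores are
#' `U d` and percent variance explained is the squared-singular-value share.
#' For a (square, symmetric) relationship matrix, the eigendecomposition of
#' the doubly-centered matrix is used instead.
#'
#' @param x genotype matrix (clones x SNPs) or symmetric kinship matrix.
#' @param n_pc number of components to return.
#' @return list: `scores` (clones x n_pc), `pct_var` (length n_pc,
#'   non-increasing, sums to <= 100).
#' @export
pca_population <- function(x, n_pc = 10L) {
  x <- unclass(x)
  if (nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8)) {
    n <- nrow(x)
    Cmat <- diag(n) - matrix(1 / n, n, n)
    e <- eigen(Cmat %*% x %*% Cmat, symmetric = TRUE)
    v <- pmax(e$values, 0)
    n_pc <- min(n_pc, sum(v > 1e-12))
    scores <- e$vectors[, seq_len(n_pc), drop = FALSE] %*%
      diag(sqrt(v[seq_len(n_pc)]), n_pc)
    pct <- 100 * v[seq_len(n_pc)] / sum(v)
  } else {
    W <- scale(x, center = TRUE, scale = FALSE)
    s <- svd(W, nu = min(n_pc, min(dim(W)) - 1), nv = 0)
    n_pc <- min(n_pc, length(s$d), ncol(s$u))
    scores <- s$u[, seq_len(n_pc), drop = FALSE] %*%
      diag(s$d[seq_len(n_pc)], n_pc)
    pct <- 100 * s$d[seq_len(n_pc)]^2 / sum(s$d^2)
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  list(scores = scores, pct_var = pct)
}
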