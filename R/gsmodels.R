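# Genomic-prediction models: RR-BLUP (via its GBLUP dual), Bayes A (Gibbs,
# compiled sampler), RKHS regression with a Gaussian kernel, and the
# additive + dominance + (additive x additive) epistasis kernel model.
# Every model accepts optional unpenalized fixed covariates and returns a
# `gs_fit` with a common predict() method.

# Build the fixed-effect design (intercept + covariates) and fail loudly on
# collinear or constant covariate columns.
build_fixed <- function(n, covariates) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("covariate rows do not match observations")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  X <- cbind("(Intercept)" = 1, covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed-effect block; collinear/constant column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

new_gs_fit <- function(model, ...) {
  structure(c(list(model = model), list(...)), class = "gs_fit")
}

#' Ridge-regression BLUP
#'
#' Solves the ridge marker model `y = X b + W beta + e`,
#' `beta ~ N(0, sb2 I)`, through its exact GBLUP dual: one REML fit of the
#' VanRaden kernel `K = W W' / c` gives the shrinkage `lambda = se2/sb2`,
#' and marker effects are back-transformed from the kernel solution.
#'
#' @param y response vector (no missing values).
#' @param M clones x markers dosage matrix \{0,1,2\}; centered internally
#'   by training column means.
#' @param covariates optional fixed covariate matrix (unpenalized).
#' @param delta_fixed optional fixed `se2/su2` ratio on the kernel scale
#'   (e.g. very large to study the full-shrinkage limit).
#' @return a `gs_fit` with marker `effects`, fixed effects `beta`, variance
#'   components, and `fitted`.
#' @export
fit_rrblup <- function(y, M, covariates = NULL, delta_fixed = NULL) {
  M <- impute_genotypes(as.matrix(M))
  n <- length(y)
  stopifnot(nrow(M) == n)
  X <- build_fixed(n, covariates)
  cm <- colMeans(M)
  W <- sweep(M, 2, cm)
  p <- cm / 2
  c0 <- 2 * sum(p * (1 - p))
  if (c0 <= 0) stop("all markers monomorphic")
  K <- tcrossprod(W) / c0
  fit <- reml_kernel(y, X = X, K = K, delta_fixed = delta_fixed)
  effects <- drop((fit$su2 / c0) * crossprod(W, fit$Vinv_r))
  fitted <- unname(drop(X %*% fit$beta + W %*% effects))
  new_gs_fit("rrblup",
             beta = setNames(fit$beta, colnames(X)), effects = effects,
             col_means = cm, snp_ids = colnames(M), su2 = fit$su2,
             se2 = fit$se2, delta = fit$delta, loglik = fit$loglik,
             n_cov = ncol(X) - 1L, fitted = fitted, y = y)
}

#' Bayes A
#'
#' Gibbs sampler with per-marker normal effects and marker-specific
#' scaled-inverse-chi-squared variances. By default the prior scale is
#' solved so the prior-mode total marker variance equals `r2 * var(y)`
#' (genetic-variance share `r2`); fixed effects carry a flat prior. The
#' sampler uses R's RNG, so runs are reproducible under `seed`.
#'
#' @inheritParams fit_rrblup
#' @param n_iter,burn_in chain length and burn-in (`n_iter > burn_in >= 0`).
#' @param df_hyper prior degrees of freedom for marker variances.
#' @param scale_hyper prior scale; `NULL` solves it from `r2`.
#' @param r2 assumed genetic-variance share used to set default scales.
#' @param thin thinning interval for the stored diagnostic chain.
#' @param seed RNG seed.
#' @return a `gs_fit` with posterior-mean `effects` and `beta`, the thinned
#'   `chain` (residual and mean marker variance), and `fitted`.
#' @export
fit_bayes_a <- function(y, M, covariates = NULL, n_iter = 5000L,
                        burn_in = 1000L, df_hyper = 5, scale_hyper = NULL,
                        r2 = 0.5, thin = 10L, seed = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  M <- impute_genotypes(as.matrix(M))
  n <- length(y)
  X <- build_fixed(n, covariates)
  cm <- colMeans(M)
  W <- sweep(M, 2, cm)
  vy <- var(y)
  msx <- sum(apply(W, 2, var))
  if (msx <= 0) stop("all markers monomorphic")
  if (is.null(scale_hyper))
    scale_hyper <- r2 * vy * (df_hyper + 2) / (df_hyper * msx)
  df_e <- 5
  scale_e <- (1 - r2) * vy * (df_e + 2) / df_e
  res <- with_seed(seed, bayes_a_gibbs(y, X, W, as.integer(n_iter),
                                       as.integer(burn_in), df_hyper,
                                       scale_hyper, df_e, scale_e,
                                       as.integer(thin)))
  effects <- drop(res$beta)
  beta <- setNames(drop(res$b), colnames(X))
  fitted <- unname(drop(X %*% beta + W %*% effects))
  new_gs_fit("bayesa",
             beta = beta, effects = effects, col_means = cm,
             snp_ids = colnames(M), chain = res$chain,
             hyper = list(n_iter = n_iter, burn_in = burn_in,
                          df_hyper = df_hyper, scale_hyper = scale_hyper,
                          r2 = r2, seed = seed),
             n_cov = ncol(X) - 1L, fitted = fitted, y = y)
}

#' RKHS regression with a Gaussian kernel
#'
#' Kernel `K_h = exp(-D / (h * median(D)))` on squared Euclidean marker
#' distances `D`. The bandwidth is selected from `bandwidth_grid` by REML
#' log-likelihood; alternatively (`average = TRUE`) predictions are averaged
#' across the grid with likelihood-proportional weights.
#'
#' @inheritParams fit_rrblup
#' @param bandwidth_grid candidate bandwidth multipliers of the median
#'   squared distance.
#' @param average average over the grid instead of picking the best.
#' @return a `gs_fit`; `bandwidth` is the selected multiplier (or the grid
#'   when averaging) and `grid_loglik` the per-bandwidth REML log-likelihoods.
#' @export
fit_rkhs <- function(y, M, covariates = NULL, bandwidth_grid = c(0.2, 1, 5),
                     average = FALSE) {
  M <- impute_genotypes(as.matrix(M))
  n <- length(y)
  X <- build_fixed(n, covariates)
  cm <- colMeans(M)
  W <- sweep(M, 2, cm)
  D <- as.matrix(dist(W))^2
  med <- median(D[upper.tri(D)])
  if (!is.finite(med) || med <= 0)
    stop("zero median marker distance: panel is duplicate-only")
  fits <- lapply(bandwidth_grid, function(h) {
    K <- exp(-D / (h * med))
    f <- reml_kernel(y, X = X, K = K)
    list(h = h, fit = f, alpha = f$su2 * f$Vinv_r)
  })
  ll <- vapply(fits, function(f) f$fit$loglik, 0)
  if (average) {
    wts <- exp(ll - max(ll)); wts <- wts / sum(wts)
  } else {
    keep <- which.max(ll)
    fits <- fits[keep]
    wts <- 1
  }
  fitted <- unname(Reduce(`+`, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    Kh <- exp(-D / (f$h * med))
    wts[i] * drop(X %*% f$fit$beta + Kh %*% f$alpha)
  })))
  new_gs_fit("rkhs",
             fits = lapply(fits, function(f)
               list(h = f$h, beta = f$fit$beta, alpha = f$alpha,
                    su2 = f$fit$su2, se2 = f$fit$se2)),
             weights = wts, med = med, col_means = cm, W_train = W,
             snp_ids = colnames(M),
             bandwidth = if (average) bandwidth_grid else fits[[1]]$h,
             grid_loglik = setNames(ll, bandwidth_grid),
             n_cov = ncol(X) - 1L, fitted = fitted, y = y)
}

# Kernels for the ADE model from a dosage matrix and training allele
# frequencies: additive (VanRaden), dominance (heterozygosity centered at
# 2pq), epistasis = A o A.
ade_kernels <- function(M, p = NULL) {
  if (is.null(p)) p <- colMeans(M) / 2
  W <- sweep(M, 2, 2 * p)
  cA <- 2 * sum(p * (1 - p))
  H <- sweep((M == 1) * 1, 2, 2 * p * (1 - p))
  cD <- sum((2 * p * (1 - p)) * (1 - 2 * p * (1 - p)))
  A <- tcrossprod(W) / cA
  list(A = A, D = tcrossprod(H) / cD, E = A * A,
       p = p, cA = cA, cD = cD)
}

#' Additive-dominance-epistasis kernel model
#'
#' Three-variance-component model: additive VanRaden kernel `A`, dominance
#' kernel `D` from heterozygosity indicators centered at `2pq`, and an
#' additive-by-additive epistasis kernel `E = A o A` (Hadamard). Variance
#' components by AI/EM-REML ([reml_lvc()]); prediction sums the component
#' BLUPs through the corresponding cross-kernels. With
#' `components = "A"` the model collapses exactly to GBLUP/RR-BLUP.
#'
#' @inheritParams fit_rrblup
#' @param components subset of `c("A", "D", "E")` to include.
#' @return a `gs_fit` with `varcomp` (named variances incl. residual),
#'   component BLUP machinery, and `fitted`.
#' @export
fit_ade <- function(y, M, covariates = NULL, components = c("A", "D", "E")) {
  components <- match.arg(components, several.ok = TRUE)
  M <- impute_genotypes(as.matrix(M))
  n <- length(y)
  X <- build_fixed(n, covariates)
  kern <- ade_kernels(M)
  if (identical(components, "A")) {
    fit <- reml_kernel(y, X = X, K = kern$A)
    Py <- fit$Vinv_r
    theta <- c(A = fit$su2, resid = fit$se2)
    beta <- fit$beta
    fitted <- unname(drop(X %*% beta + fit$su2 * kern$A %*% Py))
  } else {
    Qs <- c(kern[components], list(resid = diag(n)))
    fit <- reml_lvc(y, X, Qs, q_eff = rep(n, length(Qs)),
                    init = rep(var(y) / (length(Qs)), length(Qs)))
    theta <- fit$theta
    Py <- fit$Py
    ev <- lvc_eval(theta, y, X, Qs)
    beta <- drop(solve(crossprod(X, ev$Vi %*% X), crossprod(X, ev$Vi %*% y)))
    fitted <- drop(X %*% beta)
    for (cc in components) fitted <- fitted + drop(theta[[cc]] * Qs[[cc]] %*% Py)
    fitted <- unname(fitted)
  }
  gvar <- sum(theta[setdiff(names(theta), "resid")])
  new_gs_fit("ade",
             beta = setNames(beta, colnames(X)), varcomp = theta,
             varprop = theta[setdiff(names(theta), "resid")] / max(gvar, 1e-300),
             components = components, Py = Py,
             p = kern$p, cA = kern$cA, cD = kern$cD,
             W_train = sweep(M, 2, 2 * kern$p),
             H_train = sweep((M == 1) * 1, 2, 2 * kern$p * (1 - kern$p)),
             snp_ids = colnames(M), n_cov = ncol(X) - 1L,
             fitted = fitted, y = y)
}

# Align a new marker matrix with the training columns; error listing
# offending SNP IDs.
align_markers <- function(new_markers, snp_ids) {
  Mn <- impute_genotypes(as.matrix(new_markers))
  if (is.null(colnames(Mn)) || is.null(snp_ids)) {
    if (ncol(Mn) != length(snp_ids %||% numeric(ncol(Mn))))
      stop("marker column count does not match the training set")
    return(Mn)
  }
  missing <- setdiff(snp_ids, colnames(Mn))
  if (length(missing))
    stop("marker columns missing from new data: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  Mn[, snp_ids, drop = FALSE]
}

#' Predict from a fitted genomic-prediction model
#'
#' Centering statistics (marker means, allele frequencies, kernel scalings)
#' come from the training set only; cross-kernels are computed between new
#' and training clones.
#'
#' @param object a `gs_fit`.
#' @param new_markers clones x markers matrix, columns matching training.
#' @param new_covariates covariates, required iff the model was fit with
#'   covariates.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gs_fit <- function(object, new_markers, new_covariates = NULL, ...) {
  Mn <- align_markers(new_markers, object$snp_ids)
  n <- nrow(Mn)
  if (object$n_cov > 0 && is.null(new_covariates))
    stop("model was fit with covariates; supply new_covariates")
  if (object$n_cov == 0 && !is.null(new_covariates))
    stop("model was fit without covariates")
  X <- build_fixed(n, new_covariates)
  pred <- switch(object$model,
    rrblup = ,
    bayesa = {
      W <- sweep(Mn, 2, object$col_means)
      drop(X %*% object$beta + W %*% object$effects)
    },
    rkhs = {
      W <- sweep(Mn, 2, object$col_means)
      out <- numeric(n)
      for (i in seq_along(object$fits)) {
        f <- object$fits[[i]]
        Dx <- outer(rowSums(W^2), rowSums(object$W_train^2), "+") -
          2 * tcrossprod(W, object$W_train)
        Kx <- exp(-pmax(Dx, 0) / (f$h * object$med))
        out <- out + object$weights[i] * drop(X %*% f$beta + Kx %*% f$alpha)
      }
      out
    },
    ade = {
      W <- sweep(Mn, 2, 2 * object$p)
      Across <- tcrossprod(W, object$W_train) / object$cA
      g <- drop(X %*% object$beta)
      th <- object$varcomp
      if ("A" %in% object$components)
        g <- g + drop(th[["A"]] * Across %*% object$Py)
      if ("D" %in% object$components) {
        H <- sweep((Mn == 1) * 1, 2, 2 * object$p * (1 - object$p))
        Dcross <- tcrossprod(H, object$H_train) / object$cD
        g <- g + drop(th[["D"]] * Dcross %*% object$Py)
      }
      if ("E" %in% object$components)
        g <- g + drop(th[["E"]] * (Across * Across) %*% object$Py)
      g
    },
    stop("unknown model: ", object$model))
  if (any(!is.finite(pred))) stop("non-finite predictions")
  unname(pred)
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit>", x$model, "| n =", length(x$y),
      "| markers =", length(x$snp_ids %||% x$effects), "\n")
  invisible(x)
}
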