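# REML machinery.
#
# Two engines:
#  * reml_lvc(): general linear variance-component model
#      V = sum_i theta_i * Q_i  (Q_i PSD; residual classes are components
#      with diagonal indicator Q). Average-Information updates with
#      step-halving and an EM fallback that guarantees a non-decreasing
#      REML log-likelihood; variances floored just inside the parameter
#      space.
#  * reml_kernel(): single-kernel model V = su2*K + se2*I via one
#      eigendecomposition and 1-D profile REML on the variance ratio
#      (EMMA-style); used by the GWAS null fits and RR-BLUP/GBLUP/RKHS.

# REML log-likelihood (constant terms dropped) and derived quantities for a
# parameter vector theta. Returns NULL if V is not positive definite.
lvc_eval <- function(theta, y, X, Qs) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Qs)) V <- V + theta[i] * Qs[[i]]
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  Vi <- chol2inv(cv)
  XtViX <- crossprod(X, Vi %*% X)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(NULL)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% chol2inv(cx) %*% t(ViX)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py, Vi = Vi)
}

#' REML for linear variance-component models (AI with EM fallback)
#'
#' Fits `y = X b + e` with `Var(y) = sum_i theta_i Q_i` by restricted maximum
#' likelihood. Updates use the Average-Information algorithm; any AI step
#' that leaves the parameter space or decreases the REML log-likelihood is
#' halved and ultimately replaced by an EM step, so the log-likelihood trace
#' is non-decreasing.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Qs named list of n x n PSD covariance structure matrices; at least
#'   one must span the diagonal (a residual term).
#' @param q_eff effective number of effects per component (used by the EM
#'   step); defaults to `n` per component, override with the number of levels
#'   for design-matrix terms.
#' @param init optional initial variances.
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @return list: `theta` (named variances), `loglik`, `trace` (per-iteration
#'   log-likelihood), `converged`, `P`, `Py`, plus `y`, `X`.
#' @export
reml_lvc <- function(y, X, Qs, q_eff = NULL, init = NULL,
                     max_iter = 200L, tol = 1e-8) {
  n <- length(y)
  m <- length(Qs)
  if (is.null(names(Qs))) names(Qs) <- paste0("vc", seq_len(m))
  if (is.null(q_eff)) q_eff <- rep(n, m)
  vy <- var(y)
  floor_v <- 1e-8 * vy
  theta <- init %||% rep(vy / m, m)
  theta <- pmax(theta, floor_v)
  ev <- lvc_eval(theta, y, X, Qs)
  if (is.null(ev)) stop("initial variance parameters give a singular model")
  trace <- ev$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Py <- ev$Py; P <- ev$P
    tvec <- lapply(Qs, function(Q) Q %*% Py)     # Q_i P y
    Pt <- lapply(tvec, function(ti) P %*% ti)    # P Q_i P y
    score <- numeric(m); AI <- matrix(0, m, m)
    for (i in seq_len(m)) {
      trPQ <- sum(P * Qs[[i]])                    # tr(P Q_i), Q symmetric
      yPQPy <- sum(Py * tvec[[i]])
      score[i] <- -0.5 * (trPQ - yPQPy)
      for (j in i:m) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(tvec[[i]] * Pt[[j]])
      }
    }
    # EM update (used as fallback): theta + theta^2/q * (y'PQPy - tr(PQ))
    em <- pmax(theta + theta^2 / q_eff * (2 * score), floor_v)
    step <- tryCatch(solve(AI + diag(1e-10 * max(diag(AI)) + 1e-300, m), score),
                     error = function(e) NULL)
    new_ev <- NULL; new_theta <- NULL
    if (!is.null(step)) {
      fac <- 1
      for (h in 1:4) {
        cand <- theta + fac * step
        if (all(cand > 0)) {
          cand <- pmax(cand, floor_v)
          ce <- lvc_eval(cand, y, X, Qs)
          if (!is.null(ce) && ce$ll >= ev$ll - 1e-10) {
            new_ev <- ce; new_theta <- cand
            break
          }
        }
        fac <- fac / 2
      }
    }
    if (is.null(new_ev)) {
      ce <- lvc_eval(em, y, X, Qs)
      if (is.null(ce)) break
      new_ev <- ce; new_theta <- em
    }
    rel <- abs(new_ev$ll - ev$ll) / (1 + abs(ev$ll))
    theta <- new_theta; ev <- new_ev
    trace <- c(trace, ev$ll)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  names(theta) <- names(Qs)
  list(theta = theta, loglik = ev$ll, trace = trace, converged = converged,
       P = ev$P, Py = ev$Py, y = y, X = X)
}

# Profile REML log-likelihood for V = su2 * K + se2 * I on the eigenbasis of
# K. `d` eigenvalues, `yt`/`Xt` rotated data, delta = se2/su2.
kernel_profile_ll <- function(log_delta, d, yt, Xt) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, w * Xt)
  cx <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(cx)) return(-1e300)
  beta <- backsolve(cx, forwardsolve(t(cx), crossprod(Xt, w * yt)))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  np <- length(yt) - ncol(Xt)
  -0.5 * (np * log(rss / np) + sum(log(d + delta)) + 2 * sum(log(diag(cx))) + np)
}

#' Single-kernel REML (eigendecomposition + 1-D profile likelihood)
#'
#' Fits `y = X b + g + e`, `g ~ N(0, su2 K)`, `e ~ N(0, se2 I)` by REML,
#' profiling out `su2` and optimizing the variance ratio on the eigenbasis
#' of `K`.
#'
#' @param y response; `X` fixed-effect design (defaults to intercept);
#'   `K` PSD kernel/relationship matrix, or a precomputed `eigen()` result
#'   passed via `eK`.
#' @param eK optional `eigen(K, symmetric = TRUE)` to reuse across fits.
#' @param interval search interval for `log(se2/su2)`.
#' @param delta_fixed optional fixed variance ratio `se2/su2` (skips the
#'   1-D optimization; used e.g. to study the heavy-shrinkage limit).
#' @return list: `su2`, `se2`, `delta`, `beta`, `loglik`, `eK`, and `Vinv_r`
#'   (the V-inverse-weighted residual, the workhorse for BLUP).
#' @export
reml_kernel <- function(y, X = NULL, K = NULL, eK = NULL,
                        interval = c(-12, 12), delta_fixed = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eK)) {
    stopifnot(!is.null(K))
    eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  }
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  if (is.null(delta_fixed)) {
    opt <- optimize(kernel_profile_ll, interval = interval, d = d, yt = yt,
                    Xt = Xt, maximum = TRUE, tol = 1e-8)
    delta <- exp(opt$maximum)
    ll <- opt$objective
  } else {
    delta <- delta_fixed
    ll <- kernel_profile_ll(log(delta), d, yt, Xt)
  }
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, w * Xt)
  beta <- solve(XtWX, crossprod(Xt, w * yt))
  r <- yt - Xt %*% beta
  np <- n - ncol(X)
  su2 <- sum(w * r^2) / np
  se2 <- su2 * delta
  # V^{-1}(y - Xb) back in the original basis: U diag(w)/su2 U' r
  Vinv_r <- U %*% (w * r) / su2
  list(su2 = su2, se2 = se2, delta = delta, beta = drop(beta),
       loglik = ll, eK = eK, Vinv_r = Vinv_r, X = X)
}
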