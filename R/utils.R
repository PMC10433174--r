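#' @keywords internal
"_PACKAGE"

#' @useDynLib ratoonGS, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cor.test lm coef median optimize pchisq pnorm pt
#'   qnorm rbinom rnorm runif sd setNames var complete.cases p.adjust quantile
#'   aggregate dist model.matrix
#' @importFrom utils head read.csv read.delim write.csv
NULL

# Derive a stage-specific seed from a global seed.  Stages are numbered so
# reruns of a single stage reproduce the full-pipeline stream.  Result kept
# below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.double(seed) * 1000003 + 7919 * stage) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parse SNP identifiers of the form "S{chr}_{pos}"
#'
#' SNP names carry their map location: chromosome number (optionally
#' zero-padded, e.g. `"S03_8476715"` or `"S3_8476715"`) and 1-based physical
#' position.
#'
#' @param ids character vector of SNP identifiers.
#' @return data.frame with columns `snp_id`, `chrom` (integer), `pos`
#'   (double, base pairs).
#' @examples
#' parse_snp_ids(c("S10_53811870", "S03_8476715"))
#' @export
parse_snp_ids <- function(ids) {
  m <- regmatches(ids, regexec("^S0*([0-9]+)_([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed SNP ID(s): ", paste(head(ids[bad], 5), collapse = ", "))
  }
  data.frame(
    snp_id = ids,
    chrom = as.integer(vapply(m, `[`, "", 2L)),
    pos = as.double(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

# Column-mean imputation for a clones x SNPs dosage matrix.
impute_genotypes <- function(M) {
  if (!anyNA(M)) return(M)
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- cm[idx[, 2]]
  M
}

# Nearest PSD projection by eigenvalue clipping.
nearest_psd <- function(S, eps = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= -eps)) return(S)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
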