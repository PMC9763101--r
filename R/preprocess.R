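# Covariate regression and normalization applied before correlation and QTL
# analysis: residualize on genotype/phenotype PCs and declared covariates,
# then rank-transform each feature to N(0, 1).

#' Rank-based inverse normal transform
#'
#' Non-NA entries are replaced by `qnorm((rank - 0.5) / m)` with `m` the
#' number of non-NA values. Ties are resolved deterministically by input
#' order, so the output is always strictly monotone in the ranks. NAs keep
#' their positions.
#'
#' @param values Numeric vector with at least 3 non-NA values.
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  obs <- !is.na(values)
  m <- sum(obs)
  if (m < 3L) crd_stop("inverse_normal_transform needs >= 3 non-NA values")
  x <- values[obs]
  if (max(x) == min(x))
    crd_stop("inverse_normal_transform: all values equal, ranks degenerate")
  r <- rank(x, ties.method = "first")
  out <- values
  out[obs] <- qnorm((r - 0.5) / m)
  out
}

#' Principal-component scores of a samples-by-features matrix
#'
#' Columns are centered internally; scores are projections onto the top-k
#' right singular directions. The sign of each component is fixed so that the
#' feature with the largest absolute loading has a positive loading.
#'
#' @param x Numeric matrix, samples x features (NAs are mean-imputed per
#'   feature for the decomposition only).
#' @param k Number of components, `1 <= k <= min(dim(x))`.
#' @return Samples x k score matrix.
#' @export
compute_pcs <- function(x, k) {
  x <- as.matrix(x)
  if (k <= 0) crd_stop("k must be positive")
  if (k > min(dim(x))) crd_stop("k exceeds min(n_samples, n_features)")
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% diag(flip, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  scores
}

#' Covariate model for residualization
#'
#' @param covariates Samples x covariates numeric matrix (genotype PCs,
#'   phenotype PCs, declared biological/technical covariates).
#' @param n_phenotype_pcs Number of phenotype PCs included (bookkeeping).
#' @return A `CovariateModel`.
#' @export
covariate_model <- function(covariates, n_phenotype_pcs = 0L) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- sprintf("cov%d", seq_len(ncol(covariates)))
  d <- cbind(intercept = 1, covariates)
  if (qr(d)$rank < ncol(d)) {
    qd <- qr(d)
    bad <- colnames(d)[qd$pivot[-seq_len(qd$rank)]]
    crd_stop("covariate design rank-deficient; collinear column(s): %s",
             paste(bad, collapse = ", "))
  }
  obj <- list(names = colnames(covariates), matrix = covariates,
              n_phenotype_pcs = n_phenotype_pcs)
  class(obj) <- "CovariateModel"
  obj
}

#' Regress covariates out of a phenotype matrix
#'
#' Per feature, returns OLS residuals of `value ~ intercept + covariates`.
#' Features with missing values are fitted on complete cases; their NAs are
#' preserved.
#'
#' @param x Samples x features matrix, or a `PhenotypeMatrix`.
#' @param covariates A `CovariateModel`, or a samples x covariates matrix
#'   (an intercept is always added), or NULL for centering only.
#' @return Object of the same type as `x` with residual values (kind becomes
#'   `"quantified"` for a `PhenotypeMatrix`).
#' @export
regress_out <- function(x, covariates = NULL) {
  if (inherits(x, "PhenotypeMatrix")) {
    res <- regress_out(x$values, covariates)
    out <- x
    out$values <- res
    out$kind <- "quantified"
    return(out)
  }
  x <- as.matrix(x)
  cm <- if (inherits(covariates, "CovariateModel")) covariates$matrix
        else covariates
  design <- if (is.null(cm)) matrix(1, nrow(x), 1L)
            else cbind(intercept = 1, as.matrix(cm))
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[-seq_len(qd$rank)]]
    crd_stop("covariate design rank-deficient; collinear column(s): %s",
             paste(bad, collapse = ", "))
  }
  if (!anyNA(x)) return(qr.resid(qd, x))
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    out[ok, j] <- qr.resid(qr(design[ok, , drop = FALSE]), x[ok, j])
  }
  out
}

#' Residualize and rank-normalize a phenotype matrix
#'
#' Residualizes each feature on the covariates, then applies the inverse
#' normal transform; this is the QTL-mapping convention used throughout the
#' pipeline.
#'
#' @param pm A `PhenotypeMatrix`.
#' @param covariates Passed to [regress_out()].
#' @return A `PhenotypeMatrix` with `kind = "normalized"`.
#' @export
normalize_phenotypes <- function(pm, covariates = NULL) {
  stopifnot(inherits(pm, "PhenotypeMatrix"))
  res <- regress_out(pm$values, covariates)
  res <- apply(res, 2, inverse_normal_transform)
  out <- pm
  out$values <- res
  out$kind <- "normalized"
  out
}

#' Choose the number of phenotype PCs maximizing QTL discovery
#'
#' For each candidate k, the phenotype matrix is residualized on its top-k
#' PCs (plus any fixed covariates), rank-normalized, and a reduced-permutation
#' QTL pass is run; the k with the most FDR-5% discoveries wins, ties going to
#' the smallest k.
#'
#' @param phenotypes A quantified `PhenotypeMatrix`.
#' @param genotypes A `GenotypeMatrix`.
#' @param candidate_ks Ascending integer vector (0 allowed).
#' @param seed Integer seed for the permutation passes.
#' @param fixed_covariates Optional matrix always included in the design.
#' @param n_perm Permutations per pass (reduced; default 100).
#' @param window Cis window in bp.
#' @param fdr Discovery threshold.
#' @return The selected k (integer).
#' @export
select_pc_count <- function(phenotypes, genotypes, candidate_ks, seed,
                            fixed_covariates = NULL, n_perm = 100,
                            window = 1e6, fdr = 0.05) {
  stopifnot(length(candidate_ks) >= 1L, !is.unsorted(candidate_ks))
  n <- length(phenotypes$sample_ids)
  if (any(candidate_ks >= n)) crd_stop("candidate k >= n_samples")
  if (length(candidate_ks) == 1L) return(as.integer(candidate_ks))
  counts <- vapply(candidate_ks, function(k) {
    covs <- fixed_covariates
    if (k > 0) covs <- cbind(covs, compute_pcs(phenotypes$values, k))
    norm <- normalize_phenotypes(phenotypes, covs)
    qr <- permutation_pass(norm, genotypes, window = window, n_perm = n_perm,
                           seed = seed)
    sum(qr$q <= fdr, na.rm = TRUE)
  }, 0)
  as.integer(candidate_ks[which.max(counts)])
}
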