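# Negative-binomial Wald differential testing for genes and summed-count
# CRDs, plus the Storey q-value / pi0 / pi1 machinery used throughout the
# pipeline.
#
# The NB core covers exactly what the analysis needs: a two-level design
# (plus optional covariates), per-feature ML dispersion with a Cox-Reid
# adjustment, shrinkage toward a mean-dispersion trend, and a Wald test on
# the condition coefficient. No independent filtering, no fold-change
# shrinkage, no outlier replacement.

#' Median-of-ratios size factors
#'
#' Per sample, the median of count / geometric-mean ratios over features with
#' a positive geometric mean, normalized so that the size factors themselves
#' have geometric mean 1.
#'
#' @param counts Non-negative integer matrix, samples x features, or a
#'   raw-count `PhenotypeMatrix`.
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "PhenotypeMatrix")) counts <- counts$values
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    crd_stop("counts must be non-negative integers")
  loggeo <- colMeans(log(counts))            # -Inf for features with a zero
  use <- is.finite(loggeo)
  if (!any(use)) crd_stop("no feature with all-positive counts")
  lr <- log(counts[, use, drop = FALSE]) -
    matrix(loggeo[use], nrow(counts), sum(use), byrow = TRUE)
  sf <- exp(apply(lr, 1L, median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- rownames(counts)
  sf
}

# IRLS fit of an NB GLM with log link, fixed dispersion alpha and offset.
# Returns beta, mu, and the unscaled information matrix X'WX.
nb_irls <- function(y, X, offset, alpha, beta0 = NULL, max_iter = 50L,
                    tol = 1e-8) {
  if (is.null(beta0)) {
    z0 <- log(pmax(y, 0.5)) - offset
    beta0 <- qr.coef(qr(X), z0)
  }
  beta <- beta0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (anyNA(new_beta)) return(NULL)
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  list(beta = beta, mu = mu, info = crossprod(X * sqrt(w)), converged = TRUE)
}

# Cox-Reid adjusted profile log-likelihood of log-dispersion for one feature.
nb_profile_ll <- function(log_alpha, y, X, offset, beta0) {
  alpha <- exp(log_alpha)
  fit <- nb_irls(y, X, offset, alpha, beta0 = beta0)
  if (is.null(fit)) return(-Inf)
  ll <- sum(dnbinom(y, size = 1 / alpha, mu = fit$mu, log = TRUE))
  cr <- -0.5 * determinant(fit$info, logarithm = TRUE)$modulus
  ll + as.numeric(cr)
}

#' Negative-binomial Wald differential test
#'
#' Per feature: NB GLM with log link, log size-factor offset and design
#' `~ status (+ covariates)`; dispersion by Cox-Reid adjusted maximum
#' likelihood, shrunk toward a log-linear mean-dispersion trend; two-sided
#' Wald test on the status coefficient; Storey q-values.
#'
#' @param counts Raw-count `PhenotypeMatrix` or samples x features integer
#'   matrix.
#' @param status Binary vector (case = 1) or a `SampleMetadata`.
#' @param covariates Optional samples x covariates matrix.
#' @param size_factors Optional per-sample size factors; estimated with
#'   [estimate_size_factors()] when NULL.
#' @param shrink_weight Prior weight (in pseudo-samples) pulling per-feature
#'   log-dispersions toward the trend; default 10.
#' @return A `differential_results` data.frame: `feature_id`, `base_mean`,
#'   `log2_fc`, `se`, `wald_z`, `p`, `q`, `direction`.
#' @export
nb_wald_test <- function(counts, status, covariates = NULL,
                         size_factors = NULL, shrink_weight = 10) {
  ids <- NULL
  if (inherits(counts, "PhenotypeMatrix")) {
    ids <- counts$feature_ids
    counts <- counts$values
  }
  counts <- as.matrix(counts)
  if (is.null(ids)) ids <- colnames(counts) %||% sprintf("f%d", seq_len(ncol(counts)))
  if (inherits(status, "SampleMetadata")) status <- status$status_code
  status <- as.numeric(status)
  if (min(table(status)) < 5L) crd_stop("each group needs >= 5 samples")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  offset <- log(size_factors)
  X <- cbind(intercept = 1, status = status)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  n <- nrow(counts)

  keep <- colSums(counts) > 0
  if (any(!keep))
    crd_log("nb_wald_test: excluded %d all-zero feature(s)", sum(!keep))
  jj <- which(keep)
  m <- length(jj)
  base_mean <- colMeans(counts[, jj, drop = FALSE] / size_factors)

  log_alpha <- numeric(m)
  beta_init <- vector("list", m)
  for (k in seq_len(m)) {
    y <- counts[, jj[k]]
    b0 <- qr.coef(qr(X), log(pmax(y, 0.5)) - offset)
    opt <- optimize(function(la) nb_profile_ll(la, y, X, offset, b0),
                    interval = c(-11, 6), maximum = TRUE, tol = 1e-3)
    log_alpha[k] <- opt$maximum
    beta_init[[k]] <- b0
  }
  # trend: log-dispersion vs log base mean, then precision-weighted shrinkage
  lbm <- log(base_mean)
  tr_fit <- lm.fit(cbind(1, lbm), log_alpha)
  trend <- drop(cbind(1, lbm) %*% tr_fit$coefficients)
  la_shrunk <- (n * log_alpha + shrink_weight * trend) / (n + shrink_weight)

  res <- data.frame(feature_id = ids[jj], base_mean = base_mean,
                    log2_fc = NA_real_, se = NA_real_, wald_z = NA_real_,
                    p = NA_real_, q = NA_real_, direction = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    y <- counts[, jj[k]]
    fit <- nb_irls(y, X, offset, exp(la_shrunk[k]), beta0 = beta_init[[k]])
    if (is.null(fit)) next
    V <- tryCatch(solve(fit$info), error = function(e) NULL)
    if (is.null(V)) next
    b <- fit$beta["status"]
    se <- sqrt(V["status", "status"])
    res$log2_fc[k] <- b / log(2)
    res$se[k] <- se / log(2)
    res$wald_z[k] <- b / se
    res$p[k] <- 2 * pnorm(-abs(b / se))
  }
  ok <- !is.na(res$p)
  if (sum(!ok)) crd_log("nb_wald_test: %d feature(s) did not converge", sum(!ok))
  res$q[ok] <- storey_qvalue(res$p[ok])$qvalues
  res$direction <- sign(res$log2_fc)
  class(res) <- c("differential_results", "data.frame")
  res
}

#' Storey q-values and pi0 / pi1 estimation
#'
#' pi0 is estimated from the tail proportions `#{p > lambda} / (m (1 -
#' lambda))` over the lambda grid, smoothed with a cubic spline and evaluated
#' at the largest lambda; q-values are the step-up `pi0 * m * p(i) / i`
#' minima. Inputs with fewer than 20 p-values fall back to pi0 = 1
#' (Benjamini-Hochberg).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param lambda Grid for the pi0 fit (default 0.05 ... 0.95).
#' @param pi0 Optional: force pi0 (e.g. 1 for exact BH).
#' @return A `PiStatistics` list: `pi0`, `pi1`, `lambda`, `qvalues` (input
#'   order), `pvalues`.
#' @export
storey_qvalue <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  p <- pvalues
  if (anyNA(p)) crd_stop("NA p-values not allowed")
  if (any(p < 0 | p > 1)) crd_stop("p-values outside [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- suppressWarnings(smooth.spline(lambda, pi0_l, df = 3))
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  obj <- list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda, qvalues = q,
              pvalues = p)
  class(obj) <- "PiStatistics"
  obj
}

#' @export
print.PiStatistics <- function(x, ...) {
  cat(sprintf("PiStatistics: m = %d, pi0 = %.3f, pi1 = %.3f\n",
              length(x$pvalues), x$pi0, x$pi1))
  invisible(x)
}

#' Screen covariates for inclusion in differential designs
#'
#' A covariate is flagged for inclusion if it associates with disease status
#' (Mann-Whitney U test) or with many features: per covariate, features are
#' regressed on it and the pi1 of the resulting p-values is compared to a
#' threshold.
#'
#' @param covariates Samples x covariates matrix.
#' @param status Binary status vector (case = 1) or `SampleMetadata`.
#' @param phenotypes Samples x features matrix used for the pi1 screen.
#' @param status_alpha Mann-Whitney threshold (default 0.05).
#' @param pi1_threshold pi1 threshold for inclusion (default 0.05).
#' @return Data frame: covariate, mw_p, pi1, include.
#' @export
screen_covariates <- function(covariates, status, phenotypes,
                              status_alpha = 0.05, pi1_threshold = 0.05) {
  if (inherits(status, "SampleMetadata")) status <- status$status_code
  covariates <- as.matrix(covariates)
  phenotypes <- as.matrix(phenotypes)
  out <- data.frame(covariate = colnames(covariates) %||%
                      sprintf("cov%d", seq_len(ncol(covariates))),
                    mw_p = NA_real_, pi1 = NA_real_, include = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(covariates))) {
    cv <- covariates[, j]
    out$mw_p[j] <- suppressWarnings(
      wilcox.test(cv[status == 1], cv[status == 0])$p.value)
    ps <- apply(phenotypes, 2, function(y) {
      ok <- complete.cases(y, cv)
      if (sum(ok) < 3L || sd(cv[ok]) == 0) return(NA_real_)
      r <- cor(y[ok], cv[ok])
      tt <- r * sqrt((sum(ok) - 2) / (1 - r^2))
      2 * pt(-abs(tt), df = sum(ok) - 2)
    })
    ps <- ps[!is.na(ps)]
    out$pi1[j] <- if (length(ps) >= 20L) storey_qvalue(ps)$pi1 else NA_real_
    out$include[j] <- (out$mw_p[j] < status_alpha) ||
      (!is.na(out$pi1[j]) && out$pi1[j] > pi1_threshold)
  }
  out
}
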