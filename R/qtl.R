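# Cis-QTL mapping: nominal pass, permutation pass with beta approximation,
# forward-backward conditional scan, genotype x disease interaction QTLs,
# regulatory trait concordance (RTC), and cross-condition sharing via pi1.
#
# Phenotype anchors for the +/- window: gene TSS (strand-aware: start for
# "+", end for "-"), domain/peak start otherwise. Permutations shuffle
# phenotype values across samples with genotypes fixed, preserving cis LD.

anchor_pos <- function(pm) ifelse(pm$strand == "-", pm$end, pm$start)

# Per-feature list of cis variant indices within the window of the anchor.
cis_variant_index <- function(pm, gm, window) {
  anchors <- anchor_pos(pm)
  lapply(seq_along(pm$feature_ids), function(j) {
    which(gm$chrom == pm$chrom[j] & abs(gm$pos - anchors[j]) <= window)
  })
}

r_to_p <- function(r, df) {
  r2 <- pmin(r^2, 1 - 1e-15)
  2 * pt(-abs(r) * sqrt(df / (1 - r2)), df)
}

#' Fit a Beta distribution to permutation p-value minima by ML
#'
#' Method-of-moments initialization refined by L-BFGS-B on the
#' log-parameters.
#'
#' @param p Vector of permutation best p-values in (0, 1).
#' @return Named vector `c(a, b)`.
#' @export
fit_beta_mle <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  m <- mean(p); v <- var(p)
  common <- max(m * (1 - m) / max(v, 1e-12) - 1, 0.1)
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(lp) -sum(dbeta(p, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(optim(start, nll, method = "L-BFGS-B", lower = log(1e-3),
                        upper = log(1e6)),
                  error = function(e) NULL)
  par <- if (is.null(fit)) start else fit$par
  c(a = exp(par[1]), b = exp(par[2]))
}

#' Nominal cis association pass
#'
#' Per phenotype x cis-variant pair: OLS slope and two-sided t-test p of
#' phenotype ~ dosage.
#'
#' @param phenotypes A normalized `PhenotypeMatrix`.
#' @param genotypes A `GenotypeMatrix` (samples aligned with the phenotypes).
#' @param window Cis window in bp around the phenotype anchor (default 1 Mb).
#' @param min_maf Variants below this MAF are excluded (default 0.05).
#' @param min_samples Pairs with fewer complete samples are skipped.
#' @return A `nominal_records` data.frame: phenotype_id, variant_id,
#'   distance, slope, p.
#' @export
nominal_pass <- function(phenotypes, genotypes, window = 1e6, min_maf = 0.05,
                         min_samples = 3L) {
  stopifnot(inherits(phenotypes, "PhenotypeMatrix"),
            inherits(genotypes, "GenotypeMatrix"))
  if (!identical(phenotypes$sample_ids, genotypes$sample_ids))
    crd_stop("sample ids of phenotypes and genotypes differ")
  gm <- if (min_maf > 0) subset_variants(genotypes, genotypes$maf >= min_maf)
        else genotypes
  cis <- cis_variant_index(phenotypes, gm, window)
  anchors <- anchor_pos(phenotypes)
  out <- vector("list", length(cis))
  skipped <- 0L
  for (j in seq_along(cis)) {
    idx <- cis[[j]]
    if (!length(idx)) next
    y <- phenotypes$values[, j]
    ok <- !is.na(y)
    if (sum(ok) < min_samples) { skipped <- skipped + 1L; next }
    X <- gm$dosages[ok, idx, drop = FALSE]
    yv <- y[ok]
    sdx <- apply(X, 2, sd)
    use <- sdx > 0
    if (!any(use)) next
    r <- drop(cor(yv, X[, use, drop = FALSE]))
    df <- sum(ok) - 2L
    out[[j]] <- data.frame(
      phenotype_id = phenotypes$feature_ids[j],
      variant_id = gm$variant_ids[idx[use]],
      distance = gm$pos[idx[use]] - anchors[j],
      slope = r * sd(yv) / sdx[use],
      p = r_to_p(r, df), stringsAsFactors = FALSE)
  }
  if (skipped) crd_log("nominal_pass: %d phenotype(s) skipped (< %d samples)",
                       skipped, min_samples)
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- data.frame(phenotype_id = character(0),
                                      variant_id = character(0),
                                      distance = numeric(0),
                                      slope = numeric(0), p = numeric(0))
  class(res) <- c("nominal_records", "data.frame")
  res
}

# Internal engine shared by the genotype permutation pass and the gene-CRD
# association pass: best association per phenotype against a predictor
# matrix, permutation minima, beta-approximated adjusted p.
perm_pass_engine <- function(values, feature_ids, predictor_fetch, n_perm,
                             seed, fdr_method = "storey") {
  set.seed(seed)
  m <- length(feature_ids)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    pf <- predictor_fetch(j)
    if (is.null(pf) || ncol(pf$X) == 0L) next
    y <- values[, j]
    ok <- !is.na(y)
    n <- sum(ok)
    if (n < 10L) next
    X <- pf$X[ok, , drop = FALSE]
    sdx <- apply(X, 2, sd)
    use <- sdx > 0
    if (!any(use)) next
    X <- X[, use, drop = FALSE]
    Xs <- scale(X)
    ys <- drop(scale(y[ok]))
    df <- n - 2L
    r_nom <- drop(crossprod(ys, Xs)) / (n - 1)
    best <- which.max(abs(r_nom))
    p_nom <- r_to_p(r_nom[best], df)
    perm_idx <- vapply(seq_len(n_perm), function(i) sample.int(n),
                       integer(n))
    Yp <- matrix(ys[perm_idx], n, n_perm)
    Rp <- crossprod(Yp, Xs) / (n - 1)
    best_r <- apply(abs(Rp), 1L, max)
    p_perm <- r_to_p(best_r, df)
    ab <- fit_beta_mle(p_perm)
    rows[[j]] <- data.frame(
      phenotype_id = feature_ids[j],
      variant_id = pf$ids[use][best],
      n_variants = sum(use),
      distance = pf$distance[use][best],
      slope = r_nom[best] * sd(y[ok]) / sdx[use][best],
      p_nominal = p_nom,
      beta_a = ab[["a"]], beta_b = ab[["b"]],
      p_adjusted = pbeta(p_nom, ab[["a"]], ab[["b"]]),
      p_empirical = (1 + sum(p_perm <= p_nom)) / (n_perm + 1),
      stringsAsFactors = FALSE)
  }
  null_rows <- vapply(rows, is.null, TRUE)
  if (any(null_rows))
    crd_log("permutation pass: %d phenotype(s) skipped (no usable predictors)",
            sum(null_rows))
  res <- do.call(rbind, rows[!null_rows])
  if (is.null(res)) crd_stop("permutation pass: no phenotype had predictors")
  res$q <- storey_qvalue(res$p_adjusted)$qvalues
  res$rank <- 0L
  rownames(res) <- NULL
  res
}

#' Permutation cis-QTL pass with beta approximation
#'
#' Per phenotype: best nominal association over cis variants; `n_perm`
#' whole-phenotype permutations recording each permutation's best p; a
#' Beta(a, b) ML fit to the permutation minima; adjusted p =
#' BetaCDF(best nominal p); Storey q across phenotypes.
#'
#' @inheritParams nominal_pass
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `qtl_records` data.frame: phenotype_id, variant_id, n_variants,
#'   distance, slope, p_nominal, beta_a, beta_b, p_adjusted, p_empirical, q,
#'   rank (0 = primary).
#' @export
permutation_pass <- function(phenotypes, genotypes, window = 1e6,
                             n_perm = 1000L, seed = 1L, min_maf = 0.05) {
  stopifnot(inherits(phenotypes, "PhenotypeMatrix"),
            inherits(genotypes, "GenotypeMatrix"))
  if (!identical(phenotypes$sample_ids, genotypes$sample_ids))
    crd_stop("sample ids of phenotypes and genotypes differ")
  gm <- if (min_maf > 0) subset_variants(genotypes, genotypes$maf >= min_maf)
        else genotypes
  cis <- cis_variant_index(phenotypes, gm, window)
  anchors <- anchor_pos(phenotypes)
  fetch <- function(j) {
    idx <- cis[[j]]
    if (!length(idx)) return(NULL)
    list(X = gm$dosages[, idx, drop = FALSE], ids = gm$variant_ids[idx],
         distance = gm$pos[idx] - anchors[j])
  }
  res <- perm_pass_engine(phenotypes$values, phenotypes$feature_ids, fetch,
                          n_perm, seed)
  class(res) <- c("qtl_records", "data.frame")
  res
}

# Residualize y (and columns of X) on covariate matrix Z (with intercept).
resid_on <- function(v, Z) {
  qz <- qr(cbind(1, Z))
  qr.resid(qz, v)
}

#' Forward-backward conditional scan for independent cis signals
#'
#' Phenotypes significant in the permutation pass (q <= `fdr`) are re-scanned:
#' the per-phenotype nominal threshold is the Beta quantile of the
#' genome-wide adjusted-p significance bound. Forward: repeatedly add the
#' best variant passing the threshold conditional on those already selected.
#' Backward: re-test each candidate conditional on all others and drop
#' non-significant ones. Survivors are ranked by forward selection order.
#'
#' @inheritParams permutation_pass
#' @param qtl_records Output of [permutation_pass()].
#' @param fdr Significance level on q (default 0.05).
#' @param max_signals Safety cap on signals per phenotype.
#' @return A `qtl_records` data.frame with conditional slope/p and dense
#'   `rank` from 0.
#' @export
conditional_pass <- function(phenotypes, genotypes, qtl_records, fdr = 0.05,
                             window = 1e6, min_maf = 0.05,
                             max_signals = 10L) {
  sig <- qtl_records[qtl_records$q <= fdr, , drop = FALSE]
  if (nrow(sig) == 0L) {
    crd_log("conditional_pass: no significant phenotypes")
    return(qtl_records[0, , drop = FALSE])
  }
  nonsig <- qtl_records$p_adjusted[qtl_records$q > fdr]
  # adjusted-p significance bound: midpoint of the q <= fdr boundary; when
  # every phenotype is significant the bound is the fdr level itself
  p_bound <- if (length(nonsig))
    (max(sig$p_adjusted) + min(nonsig)) / 2
  else max(fdr, max(sig$p_adjusted))
  gm <- if (min_maf > 0) subset_variants(genotypes, genotypes$maf >= min_maf)
        else genotypes
  pm_idx <- match(sig$phenotype_id, phenotypes$feature_ids)
  cis_all <- cis_variant_index(phenotypes, gm, window)
  anchors <- anchor_pos(phenotypes)
  out <- list()
  for (s in seq_len(nrow(sig))) {
    j <- pm_idx[s]
    idx <- cis_all[[j]]
    y <- phenotypes$values[, j]
    ok <- !is.na(y)
    X <- gm$dosages[ok, idx, drop = FALSE]
    yv <- y[ok]
    n <- length(yv)
    p_t <- qbeta(p_bound, sig$beta_a[s], sig$beta_b[s])
    cond_test <- function(sel_cols, cand_cols) {
      Z <- if (length(sel_cols)) X[, sel_cols, drop = FALSE] else NULL
      ry <- if (is.null(Z)) yv - mean(yv) else resid_on(yv, Z)
      df <- n - 2L - length(sel_cols)
      vapply(cand_cols, function(cc) {
        rx <- if (is.null(Z)) X[, cc] - mean(X[, cc])
              else resid_on(X[, cc], Z)
        if (sd(rx) < 1e-10) return(c(NA_real_, NA_real_))
        r <- cor(ry, rx)
        c(r_to_p(r, df), r * sd(ry) / sd(rx))
      }, numeric(2))
    }
    selected <- integer(0)
    cand <- which(apply(X, 2, sd) > 0)
    repeat {
      if (!length(cand) || length(selected) >= max_signals) break
      tst <- cond_test(selected, cand)
      collinear <- is.na(tst[1L, ])
      if (any(collinear)) {
        crd_log("conditional_pass: %d collinear candidate(s) dropped",
                sum(collinear))
        cand <- cand[!collinear]
        tst <- tst[, !collinear, drop = FALSE]
        if (!length(cand)) break
      }
      b <- which.min(tst[1L, ])
      if (tst[1L, b] >= p_t) break
      selected <- c(selected, cand[b])
      cand <- cand[-b]
    }
    if (!length(selected)) next
    # backward: re-test each conditional on all others
    keep <- rep(TRUE, length(selected))
    stats <- matrix(NA_real_, 2, length(selected))
    for (k in seq_along(selected)) {
      tst <- cond_test(selected[-k], selected[k])
      stats[, k] <- tst[, 1L]
      if (is.na(tst[1L, 1L]) || tst[1L, 1L] >= p_t) keep[k] <- FALSE
    }
    selected <- selected[keep]
    stats <- stats[, keep, drop = FALSE]
    if (!length(selected)) next
    out[[length(out) + 1L]] <- data.frame(
      phenotype_id = sig$phenotype_id[s],
      variant_id = gm$variant_ids[idx[selected]],
      n_variants = sig$n_variants[s],
      distance = gm$pos[idx[selected]] - anchors[j],
      slope = stats[2L, ], p_nominal = stats[1L, ],
      beta_a = sig$beta_a[s], beta_b = sig$beta_b[s],
      p_adjusted = sig$p_adjusted[s], p_empirical = sig$p_empirical[s],
      q = sig$q[s], rank = seq_along(selected) - 1L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- qtl_records[0, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("qtl_records", "data.frame")
  res
}

#' Genotype-by-disease-status interaction test for discovered QTLs
#'
#' For each QTL (discovered in the case set, per the study design), fits
#' phenotype ~ genotype + status + covariates + genotype x status and tests
#' the interaction term (two-sided t), with Storey FDR over the tested QTLs.
#'
#' @param phenotypes Normalized `PhenotypeMatrix` over *all* samples.
#' @param genotypes `GenotypeMatrix` over all samples.
#' @param metadata `SampleMetadata` (both groups must be present).
#' @param qtl_records QTL set to test (e.g. case-set permutation pass hits).
#' @param covariates Optional samples x covariates matrix.
#' @return An `interaction_records` data.frame: phenotype_id, variant_id,
#'   slope_interaction, p_interaction, q, slope_case, slope_control.
#' @export
interaction_qtl <- function(phenotypes, genotypes, metadata, qtl_records,
                            covariates = NULL) {
  stopifnot(inherits(metadata, "SampleMetadata"))
  s <- metadata$status_code
  if (length(unique(s)) < 2L)
    crd_stop("interaction_qtl requires both cases and controls")
  rows <- vector("list", nrow(qtl_records))
  for (i in seq_len(nrow(qtl_records))) {
    j <- match(qtl_records$phenotype_id[i], phenotypes$feature_ids)
    v <- match(qtl_records$variant_id[i], genotypes$variant_ids)
    if (is.na(j) || is.na(v)) next
    y <- phenotypes$values[, j]
    g <- genotypes$dosages[, v]
    ok <- complete.cases(y, g)
    X <- cbind(1, g, s, covariates, g * s)[ok, , drop = FALSE]
    yv <- y[ok]
    fit <- lm.fit(X, yv)
    k <- ncol(X)
    dfres <- sum(ok) - fit$rank
    sigma2 <- sum(fit$residuals^2) / dfres
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R)
    se <- sqrt(sigma2 * XtXinv[k, k])
    bi <- fit$coefficients[k]
    slope_in <- function(grp) {
      ii <- ok & s == grp
      if (sum(ii) < 3L || sd(g[ii]) == 0) return(NA_real_)
      cor(y[ii], g[ii]) * sd(y[ii]) / sd(g[ii])
    }
    rows[[i]] <- data.frame(
      phenotype_id = qtl_records$phenotype_id[i],
      variant_id = qtl_records$variant_id[i],
      slope_interaction = bi, p_interaction = 2 * pt(-abs(bi / se), dfres),
      slope_case = slope_in(1L), slope_control = slope_in(0L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) crd_stop("interaction_qtl: no testable QTLs")
  res$q <- storey_qvalue(res$p_interaction)$qvalues
  rownames(res) <- NULL
  class(res) <- c("interaction_records", "data.frame")
  res
}

#' Regulatory trait concordance between a QTL and a GWAS variant
#'
#' Both variants must fall in the same (recombination-hotspot-delimited)
#' interval. The phenotype is residualized on each of the N interval
#' variants in turn and the QTL variant's association is re-assessed on each
#' residual; corrections are ranked by how much QTL signal they remove
#' (rank 0 = the correction leaving the least residual association). If the
#' GWAS variant tags the same functional effect as the QTL, correcting for
#' it removes the association best, giving RTC = (N - rank_gwas) / N near 1.
#'
#' @param qtl_record One row of a `qtl_records` data.frame (phenotype_id and
#'   variant_id are used).
#' @param gwas_variant_id Variant id of the GWAS hit.
#' @param phenotypes,genotypes Aligned matrices containing the phenotype and
#'   both variants.
#' @param hotspots An `IntervalSet` of hotspot-delimited intervals.
#' @return An `rtc_records` data.frame row with `rtc` in \[0, 1\] and a
#'   `degenerate` flag set when the two variants coincide (correcting for
#'   the QTL variant itself removes its association exactly, so RTC = 1 by
#'   construction).
#' @export
rtc <- function(qtl_record, gwas_variant_id, phenotypes, genotypes,
                hotspots) {
  qv <- match(qtl_record$variant_id[1L], genotypes$variant_ids)
  gv <- match(gwas_variant_id, genotypes$variant_ids)
  j <- match(qtl_record$phenotype_id[1L], phenotypes$feature_ids)
  if (is.na(qv) || is.na(gv) || is.na(j))
    crd_stop("rtc: phenotype or variant not found")
  in_iv <- function(v) which(hotspots$chrom == genotypes$chrom[v] &
                               hotspots$start <= genotypes$pos[v] - 1L &
                               hotspots$end > genotypes$pos[v] - 1L)
  iq <- in_iv(qv); ig <- in_iv(gv)
  if (!length(iq) || !length(ig) || iq[1L] != ig[1L])
    crd_stop("rtc: QTL and GWAS variants are not in the same hotspot interval")
  iv <- iq[1L]
  vv <- which(genotypes$chrom == hotspots$chrom[iv] &
                genotypes$pos - 1L >= hotspots$start[iv] &
                genotypes$pos - 1L < hotspots$end[iv])
  y <- phenotypes$values[, j]
  dq <- genotypes$dosages[, qv]
  ok <- complete.cases(y, dq)
  # residual QTL association after correcting the phenotype for each
  # interval variant; p = 1 means the correction removed the signal fully
  p_resid <- vapply(vv, function(v) {
    x <- genotypes$dosages[ok, v]
    if (sd(x) == 0) return(0)
    ry <- resid_on(y[ok], x)
    rq <- resid_on(dq[ok], x)
    if (sd(rq) < 1e-12) return(1)
    r_to_p(cor(ry, rq), sum(ok) - 3L)
  }, 0)
  rank0 <- sum(p_resid > p_resid[match(gv, vv)])
  N <- length(vv)
  degenerate <- qv == gv
  if (degenerate)
    crd_log("rtc: QTL and GWAS variant coincide; RTC is 1 by construction")
  res <- data.frame(qtl_variant = genotypes$variant_ids[qv],
                    gwas_variant = gwas_variant_id,
                    chrom = hotspots$chrom[iv], start = hotspots$start[iv],
                    end = hotspots$end[iv], n_variants = N, rank = rank0,
                    rtc = (N - rank0) / N, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(res) <- c("rtc_records", "data.frame")
  res
}

#' Sharing of QTL effects across conditions via pi1
#'
#' Recomputes the nominal p of each discovery (phenotype, variant) pair in a
#' replication data set and reports the Storey pi1 (estimated fraction of
#' true associations).
#'
#' @param qtl_records Discovery QTLs.
#' @param phenotypes,genotypes Replication data (aligned samples).
#' @return List: `pi1`, `n_pairs`, `pvalues`.
#' @export
sharing_pi1 <- function(qtl_records, phenotypes, genotypes) {
  jj <- match(qtl_records$phenotype_id, phenotypes$feature_ids)
  vv <- match(qtl_records$variant_id, genotypes$variant_ids)
  ok_pair <- !is.na(jj) & !is.na(vv)
  if (sum(ok_pair) < 20L)
    crd_stop("sharing_pi1: needs >= 20 replicable pairs (pi0 unstable)")
  ps <- mapply(function(j, v) {
    y <- phenotypes$values[, j]
    g <- genotypes$dosages[, v]
    ok <- complete.cases(y, g)
    if (sum(ok) < 3L || sd(g[ok]) == 0) return(NA_real_)
    r_to_p(cor(y[ok], g[ok]), sum(ok) - 2L)
  }, jj[ok_pair], vv[ok_pair])
  ps <- ps[!is.na(ps)]
  st <- storey_qvalue(ps)
  list(pi1 = st$pi1, n_pairs = length(ps), pvalues = ps)
}
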