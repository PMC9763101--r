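# Gene-CRD association, PC1 pseudo-phenotypes, and Bayesian-network causal
# inference on (variant, CRD, gene) triplets.
#
# Each of the three models is a Gaussian linear network scored by
# BIC-penalized log-likelihood:
#   causal:      L(C | V) * L(G | C)     (V -> C -> G)
#   reactive:    L(G | V) * L(C | G)     (V -> G -> C)
#   independent: L(C | V) * L(G | V)     (V -> C, V -> G)
# The marginal of V is identical across models and cancels in the softmax
# normalization, so it is omitted. All three models have the same parameter
# count, so the BIC penalty also cancels; it is kept in the score for
# transparency.

#' Map gene-CRD association pairs in cis
#'
#' Per gene, all CRDs whose span overlaps the +/- window around the TSS are
#' tested by Pearson correlation; significance is assessed with the same
#' permutation + beta machinery as the QTL pass, with CRD activities playing
#' the role of the variants. Storey q across genes.
#'
#' @param expression Normalized gene `PhenotypeMatrix`.
#' @param crd_activity Normalized CRD-activity `PhenotypeMatrix`.
#' @param window Cis window around the TSS (default 1 Mb).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return A `gene_crd_pairs` data.frame: gene_id, crd_id, r, p_nominal,
#'   p_adjusted, q, distance (0 if TSS inside the CRD, else signed bp to the
#'   nearest boundary), rel_position (TSS position within the CRD span, in
#'   \[0,1\], when inside; NA otherwise).
#' @export
map_gene_crd_pairs <- function(expression, crd_activity, window = 1e6,
                               n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(expression, "PhenotypeMatrix"),
            inherits(crd_activity, "PhenotypeMatrix"))
  if (!identical(expression$sample_ids, crd_activity$sample_ids))
    crd_stop("sample ids differ between expression and CRD activity")
  tss <- anchor_pos(expression)
  fetch <- function(j) {
    idx <- which(crd_activity$chrom == expression$chrom[j] &
                   crd_activity$end > tss[j] - window &
                   crd_activity$start < tss[j] + window)
    if (!length(idx)) return(NULL)
    list(X = crd_activity$values[, idx, drop = FALSE],
         ids = crd_activity$feature_ids[idx],
         distance = ifelse(
           tss[j] >= crd_activity$start[idx] & tss[j] < crd_activity$end[idx],
           0L,
           ifelse(tss[j] < crd_activity$start[idx],
                  tss[j] - crd_activity$start[idx],
                  tss[j] - crd_activity$end[idx])))
  }
  res <- perm_pass_engine(expression$values, expression$feature_ids, fetch,
                          n_perm, seed)
  names(res)[names(res) == "phenotype_id"] <- "gene_id"
  names(res)[names(res) == "variant_id"] <- "crd_id"
  ci <- match(res$crd_id, crd_activity$feature_ids)
  gi <- match(res$gene_id, expression$feature_ids)
  res$r <- vapply(seq_len(nrow(res)), function(k) {
    ok <- complete.cases(expression$values[, gi[k]],
                         crd_activity$values[, ci[k]])
    cor(expression$values[ok, gi[k]], crd_activity$values[ok, ci[k]])
  }, 0)
  inside <- res$distance == 0
  res$rel_position <- ifelse(
    inside,
    (tss[gi] - crd_activity$start[ci]) /
      (crd_activity$end[ci] - crd_activity$start[ci]),
    NA_real_)
  res$rank <- NULL
  class(res) <- c("gene_crd_pairs", "data.frame")
  res
}

#' Cross-phenotype QTL effect sharing
#'
#' For each QTL of one phenotype class whose phenotype belongs to a gene-CRD
#' pair, tests the nominal association of the QTL variant with the partner
#' phenotype; reports the fraction at p < 0.05 and the Storey pi1.
#'
#' @param qtl_records QTLs of one class (e.g. aCRD-QTLs).
#' @param other_phenotypes Normalized `PhenotypeMatrix` of the other class.
#' @param genotypes Aligned `GenotypeMatrix`.
#' @param pairs `gene_crd_pairs` linking the two classes.
#' @return List: `table` (variant, source phenotype, partner phenotype, p),
#'   `fraction_shared` (p < 0.05), `pi1` (NA when < 20 pairs).
#' @export
cross_qtl_effect <- function(qtl_records, other_phenotypes, genotypes,
                             pairs) {
  src_col <- if (all(qtl_records$phenotype_id %in% pairs$crd_id)) "crd_id"
             else "gene_id"
  partner_col <- if (src_col == "crd_id") "gene_id" else "crd_id"
  rows <- list()
  for (i in seq_len(nrow(qtl_records))) {
    partners <- pairs[[partner_col]][pairs[[src_col]] ==
                                       qtl_records$phenotype_id[i]]
    v <- match(qtl_records$variant_id[i], genotypes$variant_ids)
    for (ph in partners) {
      j <- match(ph, other_phenotypes$feature_ids)
      if (is.na(j) || is.na(v)) next
      y <- other_phenotypes$values[, j]
      g <- genotypes$dosages[, v]
      ok <- complete.cases(y, g)
      if (sum(ok) < 3L || sd(g[ok]) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = qtl_records$variant_id[i],
        source_phenotype = qtl_records$phenotype_id[i],
        partner_phenotype = ph,
        p = r_to_p(cor(y[ok], g[ok]), sum(ok) - 2L),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    warning("cross_qtl_effect: no linkable QTLs")
    return(list(table = NULL, fraction_shared = NA_real_, pi1 = NA_real_))
  }
  pi1 <- if (nrow(tab) >= 20L) storey_qvalue(tab$p)$pi1 else NA_real_
  list(table = tab, fraction_shared = mean(tab$p < 0.05), pi1 = pi1)
}

#' Build eCRDQTL-CRD-gene triplets via PC1 pseudo-phenotypes
#'
#' For each significant gene-CRD pair, gene expression and CRD activity are
#' standardized and aggregated by PCA; the PC1 scores (sign-aligned to
#' correlate positively with the gene) become a pseudo-phenotype anchored at
#' the gene TSS and mapped with the permutation QTL pass. Pairs with a
#' significant pseudo-phenotype QTL yield triplets.
#'
#' @param pairs Significant `gene_crd_pairs` (q <= 0.05 rows are used).
#' @param expression,crd_activity Normalized matrices (aligned samples).
#' @param genotypes Aligned `GenotypeMatrix`.
#' @param window,n_perm,seed As in [permutation_pass()].
#' @param fdr Significance level for pairs and pseudo-phenotype QTLs.
#' @param min_abs_r Pairs with |r| below this are skipped (PC1 ill-defined).
#' @return A `triplet_records` data.frame: triplet_id, variant_id, crd_id,
#'   gene_id, pc1_var_explained, qtl columns of the pseudo-phenotype pass.
#' @export
build_triplets <- function(pairs, expression, crd_activity, genotypes,
                           window = 1e6, n_perm = 1000L, seed = 1L,
                           fdr = 0.05, min_abs_r = 0.05) {
  use <- pairs[pairs$q <= fdr, , drop = FALSE]
  if (!nrow(use)) crd_stop("build_triplets: no significant pairs")
  gi <- match(use$gene_id, expression$feature_ids)
  ci <- match(use$crd_id, crd_activity$feature_ids)
  n <- length(expression$sample_ids)
  pseudo <- matrix(NA_real_, n, nrow(use))
  ve <- numeric(nrow(use))
  keep <- logical(nrow(use))
  for (k in seq_len(nrow(use))) {
    g <- expression$values[, gi[k]]
    a <- crd_activity$values[, ci[k]]
    ok <- complete.cases(g, a)
    r <- cor(g[ok], a[ok])
    if (abs(r) < min_abs_r) {
      crd_log("build_triplets: pair %s-%s skipped (|r| = %.3f)",
              use$gene_id[k], use$crd_id[k], abs(r))
      next
    }
    Z <- cbind(scale(g[ok]), scale(a[ok]))
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    sc <- pc$x[, 1L]
    if (cor(sc, g[ok]) < 0) sc <- -sc
    pseudo[ok, k] <- sc
    ve[k] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    keep[k] <- TRUE
  }
  if (!any(keep)) crd_stop("build_triplets: all pairs degenerate")
  use <- use[keep, , drop = FALSE]
  pseudo <- pseudo[, keep, drop = FALSE]
  ve <- ve[keep]
  gi <- gi[keep]
  ids <- sprintf("pp_%s_%s", use$gene_id, use$crd_id)
  pp <- phenotype_matrix(pseudo, expression$chrom[gi], expression$start[gi],
                         expression$end[gi], strand = expression$strand[gi],
                         kind = "normalized",
                         sample_ids = expression$sample_ids,
                         feature_ids = ids)
  qr <- permutation_pass(pp, genotypes, window = window, n_perm = n_perm,
                         seed = seed)
  hit <- qr[qr$q <= fdr, , drop = FALSE]
  if (!nrow(hit)) {
    crd_log("build_triplets: no pseudo-phenotype QTLs at FDR %.2g", fdr)
    return(structure(data.frame(), class = c("triplet_records",
                                             "data.frame")))
  }
  k <- match(hit$phenotype_id, ids)
  res <- data.frame(triplet_id = sprintf("trip_%s", hit$phenotype_id),
                    variant_id = hit$variant_id, crd_id = use$crd_id[k],
                    gene_id = use$gene_id[k], pc1_var_explained = ve[k],
                    p_adjusted = hit$p_adjusted, q = hit$q,
                    slope = hit$slope, stringsAsFactors = FALSE)
  class(res) <- c("triplet_records", "data.frame")
  res
}

# Gaussian log-likelihood of y | X under OLS with ML variance.
gauss_ll <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / n
  if (s2 <= 0) s2 <- 1e-12
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Posterior probabilities of the three causal models for one triplet
#'
#' Scores each Gaussian linear network by BIC-penalized log-likelihood and
#' normalizes with a softmax under a uniform model prior.
#'
#' @param dosage Variant dosage vector (non-constant).
#' @param crd CRD activity vector.
#' @param gene Gene expression vector.
#' @return Named numeric vector `c(causal, reactive, independent)` summing
#'   to 1.
#' @export
bn_posteriors <- function(dosage, crd, gene) {
  ok <- complete.cases(dosage, crd, gene)
  v <- dosage[ok]; c_ <- crd[ok]; g <- gene[ok]
  n <- length(v)
  if (n < 30L) crd_stop("bn_posteriors needs >= 30 complete observations")
  if (sd(v) == 0) crd_stop("constant dosage")
  if (sd(c_) == 0 || sd(g) == 0) crd_stop("constant CRD or gene values")
  k_par <- 6                                  # 2 x (intercept, slope, var)
  pen <- 0.5 * k_par * log(n)
  scores <- c(
    causal = gauss_ll(c_, v) + gauss_ll(g, c_) - pen,
    reactive = gauss_ll(g, v) + gauss_ll(c_, g) - pen,
    independent = gauss_ll(c_, v) + gauss_ll(g, v) - pen)
  w <- exp(scores - max(scores))
  w / sum(w)
}

#' Bootstrap confidence for a triplet's model call
#'
#' B resamples of individuals with replacement; the accuracy is the fraction
#' of resamples whose top model matches the full-data top model. Resamples
#' with a constant dosage are redrawn (up to 10 retries, then counted as a
#' mismatch).
#'
#' @param dosage,crd,gene Triplet data vectors.
#' @param B Number of bootstrap runs (default 100).
#' @param threshold Pass threshold on the accuracy (default 0.55).
#' @param seed Integer seed.
#' @return List: `accuracy`, `pass`, `top_model`, `posteriors` (full data).
#' @export
bootstrap_accuracy <- function(dosage, crd, gene, B = 100L,
                               threshold = 0.55, seed = 1L) {
  post <- bn_posteriors(dosage, crd, gene)
  top <- names(post)[which.max(post)]
  ok <- complete.cases(dosage, crd, gene)
  v <- dosage[ok]; c_ <- crd[ok]; g <- gene[ok]
  n <- length(v)
  set.seed(seed)
  match_cnt <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    tries <- 0L
    while (sd(v[idx]) == 0 && tries < 10L) {
      idx <- sample.int(n, replace = TRUE)
      tries <- tries + 1L
    }
    if (sd(v[idx]) == 0) next                 # counted as mismatch
    pb <- bn_posteriors(v[idx], c_[idx], g[idx])
    if (names(pb)[which.max(pb)] == top) match_cnt <- match_cnt + 1L
  }
  acc <- match_cnt / B
  list(accuracy = acc, pass = acc >= threshold, top_model = top,
       posteriors = post)
}

#' Classify triplets and attach bootstrap confidence
#'
#' Convenience wrapper: for each triplet row, computes posteriors and
#' bootstrap accuracy on the given sample subset.
#'
#' @param triplets A `triplet_records` data.frame.
#' @param expression,crd_activity,genotypes Aligned data.
#' @param B,threshold,seed As in [bootstrap_accuracy()].
#' @return `triplet_records` with p_causal, p_reactive, p_independent,
#'   top_model, accuracy, pass columns.
#' @export
classify_triplets <- function(triplets, expression, crd_activity, genotypes,
                              B = 100L, threshold = 0.55, seed = 1L) {
  if (!nrow(triplets)) return(triplets)
  out <- triplets
  out$p_causal <- out$p_reactive <- out$p_independent <- NA_real_
  out$top_model <- NA_character_
  out$accuracy <- NA_real_
  out$pass <- NA
  for (i in seq_len(nrow(triplets))) {
    v <- genotypes$dosages[, match(triplets$variant_id[i],
                                   genotypes$variant_ids)]
    c_ <- crd_activity$values[, match(triplets$crd_id[i],
                                      crd_activity$feature_ids)]
    g <- expression$values[, match(triplets$gene_id[i],
                                   expression$feature_ids)]
    ba <- bootstrap_accuracy(v, c_, g, B = B, threshold = threshold,
                             seed = derive_seed(seed, triplets$triplet_id[i]))
    out$p_causal[i] <- ba$posteriors[["causal"]]
    out$p_reactive[i] <- ba$posteriors[["reactive"]]
    out$p_independent[i] <- ba$posteriors[["independent"]]
    out$top_model[i] <- ba$top_model
    out$accuracy[i] <- ba$accuracy
    out$pass[i] <- ba$pass
  }
  out
}

#' Compare triplet mechanisms between two conditions
#'
#' Triplets are matched by (variant, CRD, gene); only triplets passing the
#' bootstrap-accuracy filter in both conditions are compared. Changes are
#' classified relative to the causal (variant -> CRD -> gene) model:
#' `same` (same top model), `causal_to_different` (causal in condition B
#' only), `different_to_causal` (causal in condition A only), and
#' `non_causal_change` (both non-causal but different).
#'
#' @param triplets_a Classified triplets of condition A (e.g. cases).
#' @param triplets_b Classified triplets of condition B (e.g. controls).
#' @return A `mechanism_changes` data.frame: triplet key, model_a, model_b,
#'   change.
#' @export
compare_mechanisms <- function(triplets_a, triplets_b) {
  key <- function(t) paste(t$variant_id, t$crd_id, t$gene_id, sep = "|")
  a <- triplets_a[!is.na(triplets_a$pass) & triplets_a$pass, , drop = FALSE]
  b <- triplets_b[!is.na(triplets_b$pass) & triplets_b$pass, , drop = FALSE]
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  dropped <- length(ka) + length(kb) - 2L * length(common)
  if (dropped) crd_log("compare_mechanisms: %d unmatched triplet(s) excluded",
                       dropped)
  if (!length(common))
    return(structure(data.frame(), class = c("mechanism_changes",
                                             "data.frame")))
  ma <- a$top_model[match(common, ka)]
  mb <- b$top_model[match(common, kb)]
  change <- ifelse(ma == mb, "same",
            ifelse(mb == "causal" & ma != "causal", "causal_to_different",
            ifelse(ma == "causal" & mb != "causal", "different_to_causal",
                   "non_causal_change")))
  res <- data.frame(triplet_key = common, model_a = ma, model_b = mb,
                    change = change, stringsAsFactors = FALSE)
  class(res) <- c("mechanism_changes", "data.frame")
  res
}
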