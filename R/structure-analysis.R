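# Characterization of condition-specific CRDs: identification, per-peak
# differential activity (Mann-Whitney on uncorrected quantifications),
# per-CRD correlation shifts (on corrected quantifications), and
# annotation-overlap enrichment (Fisher exact).

#' Find CRDs specific to one call set
#'
#' Returns the CRDs of set A none of whose member peaks appear in any CRD of
#' set B ("composed of peaks not regrouping into any CRD" of the other
#' condition).
#'
#' @param crds_a,crds_b Two `CRDSet`s over the same peak universe.
#' @return A `CRDSet` (subset of `crds_a`).
#' @export
find_specific_crds <- function(crds_a, crds_b) {
  stopifnot(inherits(crds_a, "CRDSet"), inherits(crds_b, "CRDSet"))
  if (!setequal(crds_a$peak_universe, crds_b$peak_universe))
    crd_stop("call sets are over different peak universes")
  b_peaks <- unique(unlist(crds_b$members, use.names = FALSE))
  keep <- vapply(crds_a$members, function(m) !any(m %in% b_peaks), TRUE)
  obj <- list(table = crds_a$table[keep, , drop = FALSE],
              members = crds_a$members[keep],
              peak_universe = crds_a$peak_universe, factor = crds_a$factor)
  rownames(obj$table) <- NULL
  class(obj) <- "CRDSet"
  obj
}

#' Per-peak differential activity between cases and controls
#'
#' Two-sided Mann-Whitney U test per peak on *uncorrected* quantifications
#' (the matrix must not be of kind "normalized"), Storey q-values, and the
#' case-minus-control median difference.
#'
#' @param quantifications A `PhenotypeMatrix` of kind "raw_count" or
#'   "quantified" (covariate-corrected matrices are refused).
#' @param metadata `SampleMetadata` with >= 5 samples per group.
#' @return A `peak_differential` data.frame: peak_id, u_stat, p, q,
#'   median_diff, constant flag.
#' @export
per_peak_differential <- function(quantifications, metadata) {
  stopifnot(inherits(quantifications, "PhenotypeMatrix"),
            inherits(metadata, "SampleMetadata"))
  if (quantifications$kind == "normalized")
    crd_stop("per-peak tests use uncorrected quantifications")
  s <- metadata$status_code[match(quantifications$sample_ids,
                                  metadata$sample_id)]
  if (anyNA(s)) crd_stop("metadata is missing some samples")
  if (min(sum(s == 1), sum(s == 0)) < 5L)
    crd_stop("each group needs >= 5 samples")
  m <- length(quantifications$feature_ids)
  u <- p <- md <- numeric(m)
  const <- logical(m)
  for (j in seq_len(m)) {
    y <- quantifications$values[, j]
    a <- y[s == 1 & !is.na(y)]; b <- y[s == 0 & !is.na(y)]
    md[j] <- median(a) - median(b)
    if (max(c(a, b)) == min(c(a, b))) {
      const[j] <- TRUE; p[j] <- 1; u[j] <- length(a) * length(b) / 2
      next
    }
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
    u[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
  }
  if (any(const))
    crd_log("per_peak_differential: %d constant peak(s) flagged (p = 1)",
            sum(const))
  res <- data.frame(peak_id = quantifications$feature_ids, u_stat = u, p = p,
                    q = storey_qvalue(p)$qvalues, median_diff = md,
                    constant = const, stringsAsFactors = FALSE)
  class(res) <- c("peak_differential", "data.frame")
  res
}

# Mean pairwise Pearson correlation between member peak columns.
mean_member_cor <- function(values, min_pairs = 3L) {
  r <- suppressWarnings(cor(values, use = "pairwise.complete.obs"))
  v <- r[upper.tri(r)]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Per-CRD correlation shift between cases and controls
#'
#' For each CRD and group, the mean pairwise Pearson correlation between
#' member peak activities (covariate-corrected quantifications); globally,
#' a two-sided Mann-Whitney U test comparing the per-CRD case estimates
#' against the control estimates (two unpaired samples of estimates).
#'
#' @param corrected A covariate-corrected `PhenotypeMatrix` (kind
#'   "quantified" after [regress_out()] or "normalized").
#' @param crds A `CRDSet` (e.g. the condition-specific CRDs).
#' @param metadata `SampleMetadata` with >= 10 samples per group.
#' @return List: `per_crd` data.frame (crd_id, r_case, r_control, shift
#'   direction) and `p_global`.
#' @export
per_crd_correlation_shift <- function(corrected, crds, metadata) {
  stopifnot(inherits(corrected, "PhenotypeMatrix"), inherits(crds, "CRDSet"))
  s <- metadata$status_code[match(corrected$sample_ids, metadata$sample_id)]
  if (min(sum(s == 1), sum(s == 0)) < 10L)
    crd_stop("each group needs >= 10 samples")
  est <- function(grp, m) {
    v <- corrected$values[s == grp, m, drop = FALSE]
    mean_member_cor(v)
  }
  rc <- vapply(crds$members, est, 0, grp = 1L)
  r0 <- vapply(crds$members, est, 0, grp = 0L)
  ok <- !is.na(rc) & !is.na(r0)
  if (any(!ok))
    crd_log("per_crd_correlation_shift: %d CRD(s) dropped (undefined r)",
            sum(!ok))
  per_crd <- data.frame(crd_id = crds$table$crd_id[ok], r_case = rc[ok],
                        r_control = r0[ok],
                        direction = sign(rc[ok] - r0[ok]),
                        stringsAsFactors = FALSE)
  if (nrow(per_crd) < 2L)
    crd_stop("global correlation-shift test needs >= 2 CRDs per side")
  p_global <- suppressWarnings(
    wilcox.test(per_crd$r_case, per_crd$r_control)$p.value)
  list(per_crd = per_crd, p_global = p_global)
}

#' Annotation-overlap enrichment (Fisher exact)
#'
#' A peak overlaps the annotation iff the intersection is >= 1 bp. The 2x2
#' table of (in foreground) x (overlaps annotation) is tested two-sided; the
#' reported odds ratio is the sample OR `(a d) / (b c)`, with a
#' Haldane-corrected OR alongside when a cell is zero.
#'
#' @param foreground,background Data frames with columns chrom, start, end
#'   (e.g. peak coordinate slices); the sets must be disjoint.
#' @param annotation A non-empty `IntervalSet`.
#' @return An `EnrichmentResult` list: `table` (a, b, c, d), `odds_ratio`,
#'   `odds_ratio_haldane`, `p`, `labels`.
#' @export
annotation_overlap_enrichment <- function(foreground, background,
                                          annotation) {
  stopifnot(inherits(annotation, "IntervalSet"))
  if (!length(annotation$chrom)) crd_stop("empty annotation")
  key <- function(df) paste(df$chrom, df$start, df$end)
  if (length(intersect(key(foreground), key(background))))
    crd_stop("foreground and background overlap")
  fo <- overlaps_any(annotation, foreground$chrom, foreground$start,
                     foreground$end)
  bo <- overlaps_any(annotation, background$chrom, background$start,
                     background$end)
  a <- sum(fo); b <- sum(!fo); c_ <- sum(bo); d <- sum(!bo)
  or <- (a * d) / (b * c_)   # Inf/0/NaN sentinel when a cell is zero
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  p <- fisher.test(matrix(c(a, b, c_, d), 2L), alternative = "two.sided")$p.value
  obj <- list(table = c(a = a, b = b, c = c_, d = d), odds_ratio = or,
              odds_ratio_haldane = or_h, p = p,
              labels = c(foreground = "foreground", background = "background",
                         annotation = annotation$label %||% "annotation"))
  class(obj) <- "EnrichmentResult"
  obj
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: OR = %.3g (Haldane %.3g), p = %.3g [%s]\n",
              x$odds_ratio, x$odds_ratio_haldane, x$p,
              paste(x$table, collapse = ", ")))
  invisible(x)
}
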